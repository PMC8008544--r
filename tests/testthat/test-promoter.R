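test_that("promoter windows follow the -2000..+1 convention", {
  toy <- make_toy_gene(strand = "+", tss = 5000)
  pr <- extract_promoter(toy$genome, toy$model)
  expect_identical(c(pr$genomic_start, pr$genomic_end), c(3000L, 5000L))
  expect_identical(nchar(pr$seq), 2001L)
  expect_false(pr$truncated)
  # sequence is the literal genome slice on the + strand
  expect_identical(pr$seq, substr(toy$genome[["c1"]], 3000, 5000))

  toy_m <- make_toy_gene(strand = "-", tss = 5000, chrom_len = 10000)
  pr_m <- extract_promoter(toy_m$genome, toy_m$model)
  expect_identical(c(pr_m$genomic_start, pr_m$genomic_end),
                   c(5000L, 7000L))
  expect_identical(pr_m$seq,
                   revcomp(substr(toy_m$genome[["c1"]], 5000, 7000)))

  # clipping at the contig start
  toy_t <- make_toy_gene(strand = "+", tss = 1500)
  pr_t <- extract_promoter(toy_t$genome, toy_t$model)
  expect_identical(c(pr_t$genomic_start, pr_t$genomic_end),
                   c(1L, 1500L))
  expect_true(pr_t$truncated)
})

test_that("scan_motif reports exact hits on both strands", {
  pr <- structure(list(gene_id = "g", seq = "AAATTTCCCGCCAAA",
                       chrom = "c1", genomic_start = 1L,
                       genomic_end = 15L, strand = "+",
                       truncated = FALSE),
                  class = "promoter_region")
  h <- scan_motif(pr, E2FAT)
  expect_identical(nrow(h), 1L)
  expect_identical(h$strand_of_match, "+")
  expect_identical(h$matched_seq, E2FAT)
  # +1 = TSS base is the last base; match starts 12 before it
  expect_identical(h$tss_relative_start, -11L)  # starts 11 bases upstream

  pr$seq <- "AAAGGCGGGAAATTT"
  h <- scan_motif(pr, E2FAT)
  expect_identical(nrow(h), 1L)
  expect_identical(h$strand_of_match, "-")

  pr$seq <- paste(rep("A", 30), collapse = "")
  expect_identical(nrow(scan_motif(pr, E2FAT)), 0L)

  expect_error(scan_motif(pr, ""), "empty")
})

test_that("overlapping matches are all reported and N never matches", {
  pr <- structure(list(gene_id = "g", seq = "ATATATATA", chrom = "c1",
                       genomic_start = 1L, genomic_end = 9L,
                       strand = "+", truncated = FALSE),
                  class = "promoter_region")
  h <- scan_motif(pr, "ATAT", both_strands = FALSE)
  expect_identical(nrow(h), 3L)  # positions 1, 3, 5

  pr$seq <- "AATTTCCNGCCAA"
  expect_identical(nrow(scan_motif(pr, "TTTCCNGCC", both_strands = FALSE)),
                   0L)
  # IUPAC codes in the pattern do expand
  pr$seq <- "AATTTCCCGCCAA"
  expect_identical(nrow(scan_motif(pr, "TTTCCNGCC", both_strands = FALSE)),
                   1L)
})

test_that("strand symmetry: minus-strand hits equal plus-strand hits of the reverse complement", {
  set.seed(42)
  for (rep in 1:10) {
    seq <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                 collapse = "")
    pr <- structure(list(gene_id = "g", seq = seq, chrom = "c1",
                         genomic_start = 1L, genomic_end = 300L,
                         strand = "+", truncated = FALSE),
                    class = "promoter_region")
    pat <- paste(sample(c("A", "C", "G", "T"), 5, replace = TRUE),
                 collapse = "")
    h <- scan_motif(pr, pat)
    h_rc <- scan_motif(pr, revcomp(pat))
    minus <- h[h$strand_of_match == "-", ]
    plus_rc <- h_rc[h_rc$strand_of_match == "+", ]
    expect_setequal(minus$tss_relative_start, plus_rc$tss_relative_start)
  }
})

test_that("planted sites are recovered regardless of gene strand", {
  for (strand in c("+", "-")) {
    toy <- make_toy_gene(strand = strand, seed = 11)
    toy <- plant_in_promoter(toy, E2FAT, prom_pos = c(101, 700))
    pr <- extract_promoter(toy$genome, toy$model)
    h <- scan_motif(pr, E2FAT)
    expect_identical(h$tss_relative_start, c(-1900L, -1301L),
                     info = paste("strand", strand))
    expect_identical(h$strand_of_match, c("+", "+"))
  }
})

test_that("find_target_genes collapses hits to a gene set", {
  toys <- list(
    plant_in_promoter(make_toy_gene(seed = 1), E2FAT, 150),
    plant_in_promoter(make_toy_gene(seed = 2), E2FAT, c(200, 400)),
    make_toy_gene(seed = 3))
  promoters <- lapply(seq_along(toys), function(i) {
    toys[[i]]$model$gene_id <- paste0("g", i)
    extract_promoter(toys[[i]]$genome, toys[[i]]$model)
  })
  expect_identical(find_target_genes(promoters), c("g1", "g2"))
  expect_identical(find_target_genes(promoters[3]), character(0))
})

test_that("count_cres drops motifs at or below the retention threshold", {
  # controlled all-T background: no accidental matches for either motif
  seq <- strrep("T", 2001)
  for (p in c(100, 120, 140, 160, 180)) substr(seq, p, p + 4) <- "ACGTG"
  for (p in seq(400, 400 + 6 * 20, by = 20)) substr(seq, p, p + 8) <- E2FAT
  pr <- structure(list(gene_id = "g1", seq = seq, chrom = "c1",
                       genomic_start = 1L, genomic_end = 2001L,
                       strand = "+", truncated = FALSE),
                  class = "promoter_region")
  dict <- data.frame(motif_id = c("ABRE", "E2FAT"),
                     pattern = c("ACGTG", E2FAT),
                     category = c("hormone", "TF-binding"))
  res <- count_cres(list(pr), dict, min_total = 5)
  expect_equal(unname(res$totals), c(5, 7))
  # total of 5 with min_total = 5: excluded ("greater than five" rule)
  expect_identical(colnames(res$filtered), "E2FAT")
  expect_identical(colnames(res$counts), c("ABRE", "E2FAT"))
  expect_equal(unname(res$counts["g1", ]), c(5L, 7L))

  expect_error(count_cres(list(pr), dict[0, ]), "non-empty")
})
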