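test_that("codon_pair_alignment enforces its invariants", {
  expect_error(codon_pair_alignment("ATGAAA", "ATGAA"), "length")
  expect_error(codon_pair_alignment("ATGA", "ATGC"), "multiple of 3")
  expect_error(codon_pair_alignment("ATGTAAAAA", "ATGTAAAAA"),
               "internal stop")
  # gap columns removed codon-wise
  aln <- codon_pair_alignment("ATG---AAA", "ATGCCCAAA")
  expect_identical(aln$codons_a, c("ATG", "AAA"))
  expect_identical(aln$codons_b, c("ATG", "AAA"))
})

test_that("ng86_counts matches hand-derived single-codon cases", {
  # GGG: third-position changes GGA/GGC/GGT are all Gly -> exactly one
  # synonymous site; positions 1 and 2 fully nonsynonymous
  aln <- codon_pair_alignment("GGG", "GGG")
  cnt <- ng86_counts(aln)
  expect_equal(unname(cnt["S"]), 1.0)
  expect_equal(unname(cnt["N"]), 2.0)
  expect_equal(unname(cnt["Sd"]), 0)
  expect_equal(unname(cnt["Nd"]), 0)

  # GGG <-> GGA: one synonymous difference
  cnt <- ng86_counts(codon_pair_alignment("GGG", "GGA"))
  expect_equal(unname(cnt["Sd"]), 1)
  expect_equal(unname(cnt["Nd"]), 0)

  # identical longer pair
  cnt <- ng86_counts(codon_pair_alignment("ATGGCTTGC", "ATGGCTTGC"))
  expect_equal(unname(cnt["Sd"]), 0)
  expect_equal(unname(cnt["Nd"]), 0)
  expect_equal(unname(cnt["S"] + cnt["N"]), 9)
})

test_that("site counts exclude mutations to stop codons from the denominator", {
  # TGG (Trp), position 3: TGA is a stop (excluded), TGC/TGT are Cys ->
  # 0/2 synonymous at that position. Oracle agrees.
  cnt <- ng86_counts(codon_pair_alignment("TGG", "TGG"))
  expect_equal(unname(cnt["S"]), oracle_codon_sites("TGG"))
})

test_that("kaks applies the Jukes-Cantor correction", {
  # ten GGG codons, one third-position synonymous difference:
  # S = 10, Sd = 1, pS = 0.1
  a <- strrep("GGG", 10)
  b <- paste0("GGA", strrep("GGG", 9))
  r <- kaks(codon_pair_alignment(a, b))
  expect_equal(r$pS, 0.1)
  expect_equal(r$Ks, -0.75 * log(1 - 0.4 / 3))
  expect_equal(r$Ks, 0.10732, tolerance = 1e-4)
  expect_equal(r$Ka, 0)
  expect_true(r$ratio_defined)  # Ks > 0: ratio is 0 here
  expect_equal(r$ratio, 0)
  expect_equal(r$Nd, 0)

  # identical pair: Ka = Ks = 0, ratio undefined
  r0 <- kaks(codon_pair_alignment(a, a))
  expect_equal(r0$Ks, 0)
  expect_equal(r0$Ka, 0)
  expect_false(r0$ratio_defined)
  expect_true(is.na(r0$ratio))
})

test_that("saturated proportions are flagged, raw proportions returned", {
  # single TTT/TTC codon pair: Sd = 1 exceeds S = 1/3, so 4/3 pS >= 1
  r <- kaks(codon_pair_alignment("TTT", "TTC"))
  expect_true(r$ks_saturated)
  expect_true(is.na(r$Ks))
  expect_gt(r$pS, 0.75)
  expect_false(r$ratio_defined)
})

test_that("kaks is symmetric in its two sequences", {
  set.seed(31)
  for (i in 1:10) {
    p <- make_random_codon_pair(12)
    r_ab <- kaks(codon_pair_alignment(p$a, p$b))
    r_ba <- kaks(codon_pair_alignment(p$b, p$a))
    expect_equal(r_ab$S, r_ba$S)
    expect_equal(r_ab$Sd, r_ba$Sd)
    expect_equal(r_ab$Nd, r_ba$Nd)
    expect_equal(r_ab$Ks, r_ba$Ks)
    expect_equal(r_ab$Ka, r_ba$Ka)
  }
})

test_that("each added synonymous difference never decreases Ks", {
  base <- rep("GGG", 30)
  ks_prev <- -Inf
  for (k in 0:10) {
    b <- base
    if (k > 0) b[seq_len(k)] <- "GGA"
    r <- kaks(codon_pair_alignment(paste(base, collapse = ""),
                                   paste(b, collapse = "")))
    expect_gte(r$Ks, ks_prev)
    ks_prev <- r$Ks
  }
})

test_that("ng86_counts equals the brute-force pathway oracle on random pairs", {
  set.seed(77)
  for (i in 1:25) {
    n <- sample(3:30, 1)
    p <- make_random_codon_pair(n)
    aln <- codon_pair_alignment(p$a, p$b)
    expect_equal(unname(ng86_counts(aln)), unname(oracle_ng86(p$a, p$b)),
                 tolerance = 1e-12)
  }
})

test_that("divergence_time implements T = Ks / (2 lambda) in mya", {
  expect_equal(divergence_time(0, "monocot"), 0)
  expect_equal(divergence_time(0.13, "monocot"), 10.0)
  expect_equal(divergence_time(0.13, "dicot"), 13 / 3, tolerance = 1e-12)
  expect_equal(divergence_time(0.13, 6.5e-9), 10.0)  # numeric rate
  expect_error(divergence_time(-0.1, "monocot"), "negative")
})

test_that("kaks_table reports per-pair statistics and both dated rates", {
  set.seed(5)
  base <- random_cds(60)
  ev <- synth_evolve_paralogs(base, 0.15)
  cds <- c(a1 = ev$cds_a, b1 = ev$cds_b)
  tab <- kaks_table(cds, data.frame(id_a = "a1", id_b = "b1"))
  expect_identical(nrow(tab), 1L)
  expect_equal(tab$T_mya_monocot, divergence_time(tab$Ks, "monocot"))
  expect_equal(tab$T_mya_dicot, divergence_time(tab$Ks, "dicot"))
  expect_error(kaks_table(cds, data.frame(id_a = "a1", id_b = "zz")),
               "absent")
})
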