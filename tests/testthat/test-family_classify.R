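dom_row <- function(domain, start, end, evalue = 1e-20,
                    protein = "p1") {
  data.frame(protein_id = protein, domain_name = domain,
             start = start, end = end, evalue = evalue,
             stringsAsFactors = FALSE)
}

test_that("classify_architecture applies the rules in order", {
  # duplicated DNA-binding domain, no DP -> DEL
  del <- rbind(dom_row("E2F_TD", 5, 80), dom_row("E2F_TD", 120, 195))
  expect_identical(classify_architecture(del)$group, "DEL")

  # full four-domain architecture -> E2F
  e2f <- rbind(dom_row("E2F_TD", 10, 80), dom_row("E2F_DD", 100, 160),
               dom_row("MarkedBox", 170, 210),
               dom_row("RBR_binding", 220, 280))
  expect_identical(classify_architecture(e2f)$group, "E2F")

  # minimal E2F: DNA-binding + dimerization
  expect_identical(
    classify_architecture(rbind(dom_row("E2F_TD", 10, 80),
                                dom_row("E2F_DD", 100, 160)))$group,
    "E2F")

  # DP domain -> DP
  expect_identical(classify_architecture(dom_row("DP", 30, 120))$group,
                   "DP")

  # single truncated family hit -> partial
  expect_identical(classify_architecture(dom_row("E2F_TD", 5, 40))$group,
                   "partial")

  # nothing -> unclassified
  expect_identical(classify_architecture(dom_row("DP", 1, 10)[0, ])$group,
                   "unclassified")
})

test_that("weak hits and overlapping duplicates are not double-counted", {
  # hits above the e-value cutoff are ignored
  weak <- rbind(dom_row("E2F_TD", 5, 80, evalue = 1e-3),
                dom_row("E2F_TD", 120, 195, evalue = 1e-3))
  expect_identical(classify_architecture(weak)$group, "unclassified")
  expect_identical(classify_architecture(weak, evalue_cutoff = 0.01)$group,
                   "DEL")

  # two E2F_TD hits overlapping by most of their length collapse to one
  overlap <- rbind(dom_row("E2F_TD", 5, 80), dom_row("E2F_TD", 10, 85))
  expect_identical(classify_architecture(overlap)$group, "partial")

  # DP present blocks the DEL call even with duplicated E2F_TD
  mixed <- rbind(dom_row("E2F_TD", 5, 80), dom_row("E2F_TD", 120, 195),
                 dom_row("DP", 220, 300))
  expect_false(classify_architecture(mixed)$group == "DEL")
})

test_that("classification is invariant to hit order", {
  set.seed(9)
  archs <- list(
    rbind(dom_row("E2F_TD", 5, 80), dom_row("E2F_TD", 120, 195)),
    rbind(dom_row("E2F_TD", 10, 80), dom_row("E2F_DD", 100, 160),
          dom_row("MarkedBox", 170, 210)),
    rbind(dom_row("DP", 30, 120), dom_row("E2F_TD", 150, 220)))
  for (a in archs) {
    ref <- classify_architecture(a)$group
    for (i in 1:5) {
      perm <- a[sample(nrow(a)), , drop = FALSE]
      expect_identical(classify_architecture(perm)$group, ref)
    }
  }
})

test_that("classify_family recovers planted architectures exactly", {
  tab <- rbind(
    dom_row("E2F_TD", 5, 80, protein = "del1"),
    dom_row("E2F_TD", 120, 195, protein = "del1"),
    dom_row("E2F_TD", 10, 80, protein = "e2f1"),
    dom_row("E2F_DD", 100, 160, protein = "e2f1"),
    dom_row("RBR_binding", 200, 260, protein = "e2f1"),
    dom_row("DP", 30, 120, protein = "dp1"),
    dom_row("E2F_DD", 10, 60, protein = "part1"))
  res <- classify_family(tab)
  got <- stats::setNames(res$group, res$gene_id)
  expect_identical(got[c("del1", "e2f1", "dp1", "part1")],
                   c(del1 = "DEL", e2f1 = "E2F", dp1 = "DP",
                     part1 = "partial"))
})

test_that("intron_stats reports per-group ranges", {
  mk <- function(id, n_exons) {
    len <- 100L
    starts <- seq(1L, by = 200L, length.out = n_exons)
    gene_model(id, "c1", "+", 1, max(starts) + len,
               exons = cbind(starts, starts + len - 1L))
  }
  # planted intron counts 5..16 within one group
  models <- c(
    stats::setNames(lapply(seq(6, 17), function(k) {
      mk(sprintf("e%02d", k), k)
    }), sprintf("e%02d", seq(6, 17))),
    list(d1 = mk("d1", 7)))
  assign <- data.frame(
    gene_id = names(models),
    group = c(rep("E2F", 12), "DP"))
  st <- intron_stats(models, assign)
  e2f <- st[st$group == "E2F", ]
  expect_identical(c(e2f$min_introns, e2f$max_introns), c(5L, 16L))
  expect_identical(st[st$group == "DP", "min_introns"], 6L)

  # single-exon gene -> 0 introns; exon-less gene -> excluded with warning
  models2 <- list(a = mk("a", 1),
                  b = gene_model("b", "c1", "+", 1, 100))
  assign2 <- data.frame(gene_id = c("a", "b"), group = "E2F")
  expect_warning(st2 <- intron_stats(models2, assign2), "excluding")
  expect_identical(st2$min_introns, 0L)
  expect_identical(st2$n_genes, 1L)
})

test_that("detect_tandem applies both proximity thresholds", {
  mk <- function(id, chrom, start) {
    gene_model(id, chrom, "+", start, start + 999)
  }
  fam <- c("f1", "f2")

  # adjacent family genes 10 kb apart -> one pair
  models <- list(f1 = mk("f1", "c1", 1000), f2 = mk("f2", "c1", 11000))
  td <- detect_tandem(models, fam)
  expect_identical(nrow(td), 1L)
  expect_identical(td$intervening, 0L)

  # different chromosomes -> none
  models <- list(f1 = mk("f1", "c1", 1000), f2 = mk("f2", "c2", 11000))
  expect_identical(nrow(detect_tandem(models, fam)), 0L)

  # 12 intervening non-family genes with max_intervening = 10 -> none
  mids <- lapply(1:12, function(i) mk(sprintf("x%02d", i), "c1",
                                      2000 + i * 1000))
  names(mids) <- sprintf("x%02d", 1:12)
  models <- c(list(f1 = mk("f1", "c1", 1000)), mids,
              list(f2 = mk("f2", "c1", 20000)))
  expect_identical(nrow(detect_tandem(models, fam, max_intervening = 10)),
                   0L)
  expect_identical(nrow(detect_tandem(models, fam, max_intervening = 12)),
                   1L)

  # distance gate
  models <- list(f1 = mk("f1", "c1", 1000), f2 = mk("f2", "c1", 500000))
  expect_identical(nrow(detect_tandem(models, fam)), 0L)
  expect_identical(
    nrow(detect_tandem(models, fam, max_distance_bp = 1e6)), 1L)

  expect_error(detect_tandem(models, c("f1", "missing")), "missing")
})
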