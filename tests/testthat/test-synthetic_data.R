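small_cfg <- function(...) {
  synth_config(n_chroms = 1, n_genes = 10, n_tf = 2, n_targets = 3,
               n_planted_e2fat = 4, n_true_edges = 2, seed = 7, ...)
}

test_that("synth_config validates its counts", {
  expect_error(synth_config(n_genes = 5, n_tf = 4, n_targets = 4),
               "exceeds")
  expect_error(synth_config(n_targets = 10, n_planted_e2fat = 5),
               "n_planted_e2fat")
  expect_error(synth_config(noise_sd = -1), "noise_sd")
  expect_error(synth_config(paralog_ds_targets = 0.9), "ds_targets")
  expect_error(synth_config(n_conditions = 2), "n_conditions")
})

test_that("planted binding-site count matches an independent regex oracle", {
  cfg <- small_cfg()
  set.seed(cfg$seed)
  g <- synth_genome(cfg)
  promoters <- extract_promoters(g$genome, g$models,
                                 upstream_len = cfg$promoter_len)
  n_oracle <- sum(vapply(promoters, function(p) {
    oracle_count_word(p$seq, E2FAT)
  }, numeric(1)))
  expect_identical(n_oracle, 4)
  expect_identical(nrow(g$planted), 4L)
  # hits land in 3 distinct target promoters or fewer
  expect_lte(length(unique(g$planted$gene_id)), 3L)
  expect_identical(sort(unique(g$planted$gene_id)),
                   sort(intersect(g$target_ids,
                                  unique(g$planted$gene_id))))
})

test_that("zero planted sites means zero promoter hits genome-wide", {
  cfg <- synth_config(n_chroms = 1, n_genes = 8, n_tf = 2, n_targets = 0,
                      n_planted_e2fat = 0, n_true_edges = 0, seed = 3)
  set.seed(cfg$seed)
  g <- synth_genome(cfg)
  promoters <- extract_promoters(g$genome, g$models)
  expect_identical(sum(vapply(promoters, function(p) {
    oracle_count_word(p$seq, E2FAT)
  }, numeric(1))), 0)
})

test_that("synth_dataset is byte-identical under a fixed seed", {
  cfg <- small_cfg(paralog_ds_targets = 0.2, paralog_n_codons = 60)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  synth_dataset(cfg, d1)
  synth_dataset(cfg, d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (f in setdiff(f1, "manifest.json")) {  # manifest embeds paths
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("paralog evolution hits its divergence target", {
  set.seed(21)
  base <- random_cds(300)

  ev0 <- synth_evolve_paralogs(base, 0, 0)
  expect_identical(ev0$cds_a, ev0$cds_b)

  ev <- synth_evolve_paralogs(base, 0.2, seed = 1)
  r <- kaks(codon_pair_alignment(ev$cds_a, ev$cds_b))
  expect_lt(abs(r$Ks - 0.2) / 0.2, 0.1)

  # never creates stop codons
  code <- Biostrings::GENETIC_CODE
  codons_b <- substring(ev$cds_b, seq(1, nchar(ev$cds_b), 3),
                        seq(3, nchar(ev$cds_b), 3))
  expect_false(any(code[codons_b] == "*"))

  # the substitution list is the exact diff between the two sequences
  ca <- substring(ev$cds_a, seq(1, nchar(ev$cds_a), 3),
                  seq(3, nchar(ev$cds_a), 3))
  diff_idx <- which(ca != codons_b)
  expect_setequal(diff_idx, ev$substitutions$codon_index)

  expect_error(synth_evolve_paralogs("ATG", 0.65), "unreachable")
})

test_that("expression planting yields exact correlations at zero noise", {
  cfg <- small_cfg(noise_sd = 0)
  set.seed(cfg$seed)
  g <- synth_genome(cfg)
  edges <- synth_true_edges(cfg, g)
  ex <- synth_expression(cfg, g, edges)
  expect_equal(dim(ex$expr), c(cfg$n_genes, cfg$n_conditions))
  expect_identical(colnames(ex$expr), DEFAULT_CONDITIONS)
  for (i in seq_len(nrow(edges))) {
    r <- stats::cor(ex$expr[edges$regulator[i], ],
                    ex$expr[edges$target[i], ])
    expected <- if (edges$sign[i] == "activation") 1 else -1
    expect_equal(r, expected, tolerance = 1e-12)
  }
  # decoy targets (motif, no edge) stay below the retention threshold
  decoys <- setdiff(g$target_ids, edges$target)
  for (d in decoys) {
    for (reg in g$regulator_ids) {
      expect_lt(abs(stats::cor(ex$expr[reg, ], ex$expr[d, ])), 0.90)
    }
  }
})

test_that("GO annotation generation is deterministic and plants one term", {
  cfg <- small_cfg()
  set.seed(cfg$seed)
  g <- synth_genome(cfg)
  set.seed(99)
  a1 <- synth_go_annotation(cfg, g)
  set.seed(99)
  a2 <- synth_go_annotation(cfg, g)
  expect_identical(a1$annotation, a2$annotation)
  carriers <- unique(
    a1$annotation$gene_id[a1$annotation$term == a1$enriched_term])
  expect_gte(length(intersect(carriers, g$target_ids)),
             ceiling(0.8 * length(g$target_ids)))
})
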