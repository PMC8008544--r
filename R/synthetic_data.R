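#' Default condition panel for synthetic expression matrices
#'
#' Thirteen culm/tissue conditions mirroring a bamboo developmental
#' series: winter and growing shoots (S1-S7), mature culm control (CK),
#' seedling stems (SS1, SS2), lateral bud (L), rhizome (R) and outward
#' rhizome (O).
#' @export
DEFAULT_CONDITIONS <- c("S1", "S2", "S3", "S4", "S5", "S6", "S7",
                        "CK", "SS1", "SS2", "L", "R", "O")

#' Configuration for the synthetic-data generator
#'
#' @param n_chroms Number of chromosomes.
#' @param n_genes Number of genes (split across chromosomes).
#' @param promoter_len Upstream promoter extent in bp (default 2000; the
#'   extracted window additionally includes the TSS base).
#' @param n_tf Number of regulator (TF) genes.
#' @param n_targets Number of genes whose promoters receive planted
#'   binding sites.
#' @param n_planted_e2fat Total planted E2FAT occurrences, distributed over
#'   the target genes (must be >= `n_targets` when `n_targets > 0` so every
#'   target carries at least one site).
#' @param n_true_edges Number of planted regulator->target edges
#'   (alternating activation/repression); must be <= `n_targets`.
#' @param n_conditions Number of expression conditions (default 13).
#' @param noise_sd Gaussian noise added to edge-target profiles, on the
#'   FPKM scale (default 0.3).
#' @param paralog_ds_targets Synonymous-divergence targets for the
#'   generated paralog pairs (each in (0, 0.7)).
#' @param paralog_n_codons Length of each base CDS in codons (default 300).
#' @param seed Master seed; all randomness flows from it.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_chroms = 2, n_genes = 120, promoter_len = 2000,
                         n_tf = 5, n_targets = 30,
                         n_planted_e2fat = 40, n_true_edges = 20,
                         n_conditions = 13, noise_sd = 0.3,
                         paralog_ds_targets = c(0.1, 0.2, 0.4),
                         paralog_n_codons = 300, seed = 1) {
  cfg <- list(n_chroms = n_chroms, n_genes = n_genes,
              promoter_len = promoter_len, n_tf = n_tf,
              n_targets = n_targets, n_planted_e2fat = n_planted_e2fat,
              n_true_edges = n_true_edges, n_conditions = n_conditions,
              noise_sd = noise_sd,
              paralog_ds_targets = paralog_ds_targets,
              paralog_n_codons = paralog_n_codons, seed = seed)
  counts <- c(n_chroms, n_genes, n_tf, n_targets, n_planted_e2fat,
              n_true_edges, n_conditions)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_chroms < 1 || n_genes < 1) stop("need >= 1 chromosome and gene")
  if (n_tf + n_targets > n_genes) stop("n_tf + n_targets exceeds n_genes")
  if (n_targets > 0 && n_planted_e2fat < n_targets) {
    stop("n_planted_e2fat must be >= n_targets")
  }
  if (n_true_edges > n_targets) stop("n_true_edges exceeds n_targets")
  if (n_true_edges > 0 && n_tf == 0) stop("edges need >= 1 regulator")
  if (n_conditions < 3) stop("n_conditions must be >= 3")
  if (any(paralog_ds_targets <= 0 | paralog_ds_targets >= 0.7)) {
    stop("paralog_ds_targets must lie in (0, 0.7)")
  }
  structure(cfg, class = "synth_config")
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# all occurrence start positions of the E2FAT site in either orientation
.e2fat_occurrences <- function(seq) {
  find <- function(pat) {
    m <- gregexpr(pat, seq, fixed = TRUE)[[1]]
    m[m > 0]
  }
  sort(unique(c(find(E2FAT), find(revcomp(E2FAT)))))
}

# redraw bases at accidental occurrences until the sequence is clean
.purge_e2fat <- function(seq, max_iter = 100) {
  w <- nchar(E2FAT)
  for (iter in seq_len(max_iter)) {
    occ <- .e2fat_occurrences(seq)
    if (length(occ) == 0) return(seq)
    for (p in occ) {
      substr(seq, p, p + w - 1) <- .rand_dna(w)
    }
  }
  stop("failed to purge accidental binding sites")
}

# single attempt at a genome realization; verified by the caller
.synth_genome_once <- function(config) {
  pad <- 120L
  prom <- as.integer(config$promoter_len)
  gene_ids <- sprintf("g%03d", seq_len(config$n_genes))
  per_chrom <- split(seq_len(config$n_genes),
                     rep(seq_len(config$n_chroms),
                         length.out = config$n_genes))
  genome <- character(config$n_chroms)
  names(genome) <- sprintf("chr%02d", seq_len(config$n_chroms))
  models <- list()
  for (ci in seq_len(config$n_chroms)) {
    idx <- per_chrom[[ci]]
    cursor <- 1L
    layouts <- list()
    for (gi in idx) {
      strand <- sample(c("+", "-"), 1)
      n_exons <- sample(2:8, 1)
      exon_lens <- sample(80:200, n_exons, replace = TRUE)
      intron_lens <- if (n_exons > 1) {
        sample(50:150, n_exons - 1, replace = TRUE)
      } else integer(0)
      body <- sum(exon_lens) + sum(intron_lens)
      s <- cursor + pad
      if (strand == "+") {
        tss <- s + prom
        span <- c(tss, tss + body - 1L)
      } else {
        span <- c(s, s + body - 1L)
        tss <- span[2]
      }
      starts <- span[1] + cumsum(c(0L, utils::head(
        exon_lens + c(intron_lens, 0L), -1)))
      exons <- cbind(starts, starts + exon_lens - 1L)
      layouts[[length(layouts) + 1]] <- list(
        gene_id = gene_ids[gi], strand = strand, span = span, exons = exons)
      cursor <- cursor + pad + prom + body
    }
    clen <- cursor + 200L
    seq <- .purge_e2fat(.rand_dna(clen))
    for (ly in layouts) {
      models[[ly$gene_id]] <- gene_model(
        ly$gene_id, names(genome)[ci], ly$strand,
        ly$span[1], ly$span[2], exons = ly$exons)
    }
    genome[ci] <- seq
  }

  # plant E2FAT occurrences in the promoters of the target genes
  target_ids <- gene_ids[config$n_tf + seq_len(config$n_targets)]
  planted <- data.frame(gene_id = character(0),
                        tss_relative_pos = integer(0),
                        strand = character(0), stringsAsFactors = FALSE)
  if (config$n_targets > 0) {
    extra <- config$n_planted_e2fat - config$n_targets
    assign_ids <- c(target_ids,
                    if (extra > 0) sample(target_ids, extra, replace = TRUE))
    per_gene <- table(assign_ids)
    w <- nchar(E2FAT)
    for (gid in names(per_gene)) {
      m <- models[[gid]]
      k <- per_gene[[gid]]
      # window indices 1..prom+1; keep sites fully upstream with margin
      cand <- seq(10L, prom - 2L * w)
      pos <- integer(0)
      for (tries in 1:200) {
        pos <- sort(sample(cand, k))
        if (k == 1 || all(diff(pos) > w + 2L)) break
      }
      orient <- sample(c("+", "-"), k, replace = TRUE)
      pr <- extract_promoter(genome, m, upstream_len = prom)
      pseq <- pr$seq
      for (j in seq_len(k)) {
        ins <- if (orient[j] == "+") E2FAT else revcomp(E2FAT)
        substr(pseq, pos[j], pos[j] + w - 1L) <- ins
      }
      # write the edited promoter back into the genome
      gseq <- if (m$strand == "+") pseq else revcomp(pseq)
      chrom_seq <- genome[[m$chrom]]
      substr(chrom_seq, pr$genomic_start, pr$genomic_end) <- gseq
      genome[[m$chrom]] <- chrom_seq
      planted <- rbind(planted, data.frame(
        gene_id = gid,
        tss_relative_pos = .tss_relative(pos, prom + 1L),
        strand = orient, stringsAsFactors = FALSE))
    }
  }
  list(genome = genome, models = models, planted = planted,
       gene_ids = gene_ids, target_ids = target_ids,
       regulator_ids = gene_ids[seq_len(config$n_tf)])
}

#' Generate a synthetic genome with planted E2FAT binding sites
#'
#' Builds a multi-chromosome toy genome with genes on both strands, every
#' gene owning a full-length promoter window. Background sequence is
#' purged of accidental E2FAT occurrences (either orientation) by
#' rejection resampling before exactly `n_planted_e2fat` sites are planted
#' in the promoters of the designated target genes; the realization is
#' re-scanned and regenerated (bounded retries) until the planted count is
#' exactly the true count.
#'
#' @param config A `synth_config`. The caller is responsible for seeding
#'   ([synth_dataset()] seeds once from `config$seed`).
#' @return List with `genome` (named sequences), `models` (gene models),
#'   `planted` (data frame `gene_id`, `tss_relative_pos`, `strand`),
#'   `gene_ids`, `target_ids`, `regulator_ids`.
#' @export
synth_genome <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  prom <- config$promoter_len
  for (attempt in 1:20) {
    g <- .synth_genome_once(config)
    # verify: oracle count over all promoter windows equals planted count
    n_found <- 0L
    for (m in g$models) {
      pr <- extract_promoter(g$genome, m, upstream_len = prom)
      n_found <- n_found + length(.e2fat_occurrences(pr$seq))
    }
    if (n_found == nrow(g$planted)) return(g)
  }
  stop("could not realize a clean genome in 20 attempts")
}

#' Random stop-free coding sequence
#'
#' @param n_codons Number of codons.
#' @return A CDS string of length `3 * n_codons` with no stop codons.
#' @export
random_cds <- function(n_codons) {
  code <- .codon_table()
  sense <- names(code)[code != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# enumerate single-base synonymous / nonsynonymous change options of a
# codon, excluding changes that create a stop codon
.codon_change_options <- function(codon, code) {
  bases <- c("A", "C", "G", "T")
  aa <- code[codon]
  syn <- list()
  nonsyn <- list()
  for (pos in 1:3) {
    for (b in setdiff(bases, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (code[mut] == "*") next
      if (code[mut] == aa) {
        syn[[length(syn) + 1]] <- mut
      } else {
        nonsyn[[length(nonsyn) + 1]] <- mut
      }
    }
  }
  list(syn = unlist(syn), nonsyn = unlist(nonsyn))
}

#' Evolve a paralog pair to a target synonymous divergence
#'
#' Starting from one base CDS, introduces single-base synonymous
#' substitutions (and optionally nonsynonymous ones) into a copy until the
#' NG86 proportion of synonymous differences matches the Jukes-Cantor
#' inverse of `ds_target` (`pS = 3/4 (1 - exp(-4/3 Ks))`). At most one
#' substitution is placed per codon, so difference counting is exact, and
#' no substitution ever creates a stop codon. Substitution lists are
#' returned as ground truth.
#'
#' @param base_cds Stop-free CDS, length a multiple of 3.
#' @param ds_target Target synonymous divergence (Ks scale, in `[0, 0.7)`).
#' @param dn_target Target nonsynonymous divergence (default 0).
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return List with `cds_a` (= base), `cds_b` (evolved), `n_syn`,
#'   `n_nonsyn`, and `substitutions` (data frame `codon_index`, `from`,
#'   `to`, `type`).
#' @export
synth_evolve_paralogs <- function(base_cds, ds_target, dn_target = 0,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base_cds <- toupper(base_cds)
  if (nchar(base_cds) %% 3 != 0) stop("CDS length not a multiple of 3")
  code <- .codon_table()
  codons <- substring(base_cds, seq(1, nchar(base_cds), 3),
                      seq(3, nchar(base_cds), 3))
  if (any(code[codons] == "*")) stop("base CDS contains a stop codon")
  if (ds_target < 0 || ds_target >= 0.7) stop("ds_target out of range")
  if (dn_target < 0) stop("dn_target out of range")

  sites <- t(vapply(codons, .codon_sites, numeric(2), code = code))
  S_total <- sum(sites[, 1])
  N_total <- sum(sites[, 2])
  pS_target <- 3 / 4 * (1 - exp(-4 / 3 * ds_target))
  pN_target <- 3 / 4 * (1 - exp(-4 / 3 * dn_target))
  n_syn <- round(pS_target * S_total)
  n_nonsyn <- round(pN_target * N_total)

  opts <- lapply(codons, .codon_change_options, code = code)
  syn_ok <- which(vapply(opts, function(o) length(o$syn) > 0, logical(1)))
  if (n_syn > length(syn_ok) || (ds_target > 0 && n_syn == 0)) {
    stop("ds_target unreachable for this sequence length")
  }
  syn_idx <- if (n_syn > 0) sample(syn_ok, n_syn) else integer(0)
  nonsyn_ok <- setdiff(
    which(vapply(opts, function(o) length(o$nonsyn) > 0, logical(1))),
    syn_idx)
  if (n_nonsyn > length(nonsyn_ok)) {
    stop("dn_target unreachable for this sequence length")
  }
  nonsyn_idx <- if (n_nonsyn > 0) sample(nonsyn_ok, n_nonsyn) else integer(0)

  evolved <- codons
  subs <- list()
  for (i in syn_idx) {
    pick <- opts[[i]]$syn[sample.int(length(opts[[i]]$syn), 1)]
    subs[[length(subs) + 1]] <- data.frame(
      codon_index = i, from = codons[i], to = pick, type = "synonymous",
      stringsAsFactors = FALSE)
    evolved[i] <- pick
  }
  for (i in nonsyn_idx) {
    pick <- opts[[i]]$nonsyn[sample.int(length(opts[[i]]$nonsyn), 1)]
    subs[[length(subs) + 1]] <- data.frame(
      codon_index = i, from = codons[i], to = pick,
      type = "nonsynonymous", stringsAsFactors = FALSE)
    evolved[i] <- pick
  }
  subs <- if (length(subs) == 0) {
    data.frame(codon_index = integer(0), from = character(0),
               to = character(0), type = character(0))
  } else {
    do.call(rbind, subs)
  }
  list(cds_a = base_cds, cds_b = paste(evolved, collapse = ""),
       n_syn = n_syn, n_nonsyn = n_nonsyn, substitutions = subs)
}

#' Plant regulator->target edges
#'
#' Chooses `n_true_edges` distinct targets among the planted-motif genes,
#' assigns regulators round-robin and alternates activation/repression.
#'
#' @param config A `synth_config`.
#' @param genome_truth Output of [synth_genome()].
#' @return Data frame `regulator`, `target`, `sign`
#'   (activation/repression).
#' @export
synth_true_edges <- function(config, genome_truth) {
  if (config$n_true_edges == 0) {
    return(data.frame(regulator = character(0), target = character(0),
                      sign = character(0)))
  }
  targets <- sample(genome_truth$target_ids, config$n_true_edges)
  regs <- rep(genome_truth$regulator_ids,
              length.out = config$n_true_edges)
  data.frame(
    regulator = regs, target = targets,
    sign = rep(c("activation", "repression"),
               length.out = config$n_true_edges),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic expression matrix with planted correlations
#'
#' Regulator profiles are drawn log-normal (FPKM-like skew). Each true
#' edge's target profile is the regulator profile (activation) or its
#' reflection about its midrange (repression), plus Gaussian noise of sd
#' `noise_sd`; at `noise_sd = 0` the pairwise Pearson r is exactly +1/-1.
#' Decoy targets (motif but no edge) and all remaining genes get
#' independent log-normal profiles. Negative values arising from noise are
#' clamped at 0.
#'
#' @param config A `synth_config`.
#' @param genome_truth Output of [synth_genome()].
#' @param true_edges Output of [synth_true_edges()].
#' @return List with `expr` (matrix genes x conditions) and `tissue_max`
#'   (data frame from [tissue_max()], the planted labels).
#' @export
synth_expression <- function(config, genome_truth, true_edges) {
  conds <- if (config$n_conditions == length(DEFAULT_CONDITIONS)) {
    DEFAULT_CONDITIONS
  } else {
    sprintf("C%02d", seq_len(config$n_conditions))
  }
  ids <- genome_truth$gene_ids
  expr <- matrix(0, nrow = length(ids), ncol = length(conds),
                 dimnames = list(ids, conds))
  for (g in ids) {
    expr[g, ] <- exp(stats::rnorm(length(conds), mean = 2, sd = 1))
  }
  for (i in seq_len(nrow(true_edges))) {
    reg <- expr[true_edges$regulator[i], ]
    prof <- if (true_edges$sign[i] == "activation") {
      reg
    } else {
      (max(reg) + min(reg)) - reg
    }
    noise <- if (config$noise_sd > 0) {
      stats::rnorm(length(prof), 0, config$noise_sd)
    } else 0
    expr[true_edges$target[i], ] <- pmax(prof + noise, 0)
  }
  list(expr = expr, tissue_max = tissue_max(expr))
}

#' Generate a gene-to-GO mapping with one planted enriched term
#'
#' Background terms are assigned uniformly at random; the enriched term is
#' planted on a large fraction of the target set and at background rate
#' elsewhere.
#'
#' @param config A `synth_config`.
#' @param genome_truth Output of [synth_genome()].
#' @param enriched_term Term id to plant (default `"GO:0000278"`).
#' @param target_rate Fraction of target genes carrying the term
#'   (default 0.8).
#' @param background_rate Background carriage rate (default 0.05).
#' @param n_background_terms Number of uniform background terms
#'   (default 20).
#' @return List with `annotation` (data frame `gene_id`, `term`) and
#'   `enriched_term`.
#' @export
synth_go_annotation <- function(config, genome_truth,
                                enriched_term = "GO:0000278",
                                target_rate = 0.8,
                                background_rate = 0.05,
                                n_background_terms = 20) {
  ids <- genome_truth$gene_ids
  terms <- sprintf("GO:%07d", seq_len(n_background_terms))
  rows <- list()
  for (g in ids) {
    k <- sample(1:3, 1)
    for (t in sample(terms, k)) {
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = g, term = t, stringsAsFactors = FALSE)
    }
  }
  targets <- genome_truth$target_ids
  n_plant <- ceiling(target_rate * length(targets))
  carriers <- if (length(targets) > 0) {
    sample(targets, n_plant)
  } else character(0)
  others <- setdiff(ids, targets)
  bg_carriers <- others[stats::runif(length(others)) < background_rate]
  for (g in c(carriers, bg_carriers)) {
    rows[[length(rows) + 1]] <- data.frame(
      gene_id = g, term = enriched_term, stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, rows)
  ann <- ann[order(ann$gene_id, ann$term), , drop = FALSE]
  rownames(ann) <- NULL
  list(annotation = ann, enriched_term = enriched_term)
}

#' Write gene models as GFF3
#'
#' Emits the gene -> mRNA -> exon hierarchy [read_gff3()] expects.
#'
#' @param models Named list of `gene_model` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (m in models) {
    attr_g <- sprintf("ID=%s", m$gene_id)
    mid <- sprintf("%s.t1", m$gene_id)
    lines <- c(lines,
      sprintf("%s\tsynth\tgene\t%d\t%d\t.\t%s\t.\t%s",
              m$chrom, m$start, m$end, m$strand, attr_g),
      sprintf("%s\tsynth\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              m$chrom, m$start, m$end, m$strand, mid, m$gene_id))
    for (i in seq_len(nrow(m$exons))) {
      lines <- c(lines,
        sprintf("%s\tsynth\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                m$chrom, m$exons[i, 1], m$exons[i, 2], m$strand, mid))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

.write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Generate and write a complete synthetic dataset
#'
#' Seeds once from `config$seed`, then generates in fixed order: genome +
#' gene models + planted binding sites, true regulatory edges, expression
#' matrix, paralog CDS pairs, GO annotation. All files are written under
#' `outdir` in the exact dialects the readers in this package expect, plus
#' a `ground_truth.json` and a `manifest.json` (paths + md5 hashes). Runs
#' with the same config are byte-identical.
#'
#' @param config A `synth_config`.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory objects (`genome`,
#'   `models`, `truth`, `expr`, `paralogs`, `annotation`) and `files`
#'   (named paths).
#' @export
synth_dataset <- function(config, outdir) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  g <- synth_genome(config)
  edges <- synth_true_edges(config, g)
  ex <- synth_expression(config, g, edges)
  go <- synth_go_annotation(config, g)

  paralogs <- list()
  pair_rows <- list()
  cds <- character(0)
  for (i in seq_along(config$paralog_ds_targets)) {
    ds <- config$paralog_ds_targets[i]
    base <- random_cds(config$paralog_n_codons)
    ev <- synth_evolve_paralogs(base, ds)
    ida <- sprintf("pair%02d_a", i)
    idb <- sprintf("pair%02d_b", i)
    cds[[ida]] <- ev$cds_a
    cds[[idb]] <- ev$cds_b
    pair_rows[[i]] <- data.frame(id_a = ida, id_b = idb, ds_target = ds,
                                 stringsAsFactors = FALSE)
    paralogs[[i]] <- ev
  }
  pairs <- do.call(rbind, pair_rows)

  files <- c(
    genome = file.path(outdir, "genome.fa"),
    gff3 = file.path(outdir, "genes.gff3"),
    expression = file.path(outdir, "expression.tsv"),
    cds = file.path(outdir, "paralog_cds.fa"),
    pairs = file.path(outdir, "paralog_pairs.tsv"),
    go_map = file.path(outdir, "go_annotation.tsv"),
    truth = file.path(outdir, "ground_truth.json"))
  .write_fasta(g$genome, files[["genome"]])
  write_gff3(g$models, files[["gff3"]])
  write_expression(ex$expr, files[["expression"]])
  .write_fasta(cds, files[["cds"]])
  utils::write.table(pairs, files[["pairs"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(go$annotation, files[["go_map"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)

  truth <- list(
    planted_motif_hits = g$planted,
    true_edges = edges,
    planted_ds = stats::setNames(as.list(pairs$ds_target),
                                 paste(pairs$id_a, pairs$id_b, sep = "|")),
    enriched_term = go$enriched_term,
    tissue_max = stats::setNames(as.list(ex$tissue_max$condition),
                                 ex$tissue_max$gene_id),
    regulator_ids = g$regulator_ids,
    target_ids = g$target_ids)
  jsonlite::write_json(truth, files[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "columns")

  manifest <- list(
    config = unclass(config),
    files = as.list(files),
    md5 = as.list(tools::md5sum(unname(files))))
  names(manifest$md5) <- names(files)
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(genome = g$genome, models = g$models, truth = truth,
                 expr = ex$expr, paralogs = paralogs,
                 annotation = go$annotation, pairs = pairs,
                 files = c(files, manifest = manifest_path)))
}
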