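#' Assemble and validate a pipeline configuration
#'
#' Paths may be omitted (`NULL`) to skip the stages that need them; every
#' path that is supplied must exist. Numeric parameters are range-checked.
#'
#' @param genome Genome FASTA path (required for promoter stages).
#' @param gff3 GFF3 gene-model path (required for promoter stages).
#' @param expression FPKM TSV path (required for network / heatmap stages).
#' @param domains Domain-annotation TSV path (optional; enables the
#'   classify stage).
#' @param cds CDS FASTA path for paralog pairs (optional; enables kaks).
#' @param pairs Paralog pair-list TSV (columns `id_a`, `id_b`).
#' @param go_map Gene-to-GO TSV (optional; enables enrichment).
#' @param regulators Regulator TSV (columns `gene_id`, `pattern`; optional;
#'   enables the network stage).
#' @param ct_table Ct TSV (columns `sample`, `gene`, `ct`; optional).
#' @param reference_gene,calibrator_sample qPCR normalization settings
#'   (used when `ct_table` is given).
#' @param promoter_len Promoter upstream extent (default 2000).
#' @param threshold Network PCC threshold (default 0.90).
#' @param inclusive Threshold inclusivity (default TRUE).
#' @param lambda Divergence rate: `"monocot"`, `"dicot"` or a number.
#' @param alpha Enrichment significance level (default 0.05).
#' @param max_intervening,max_distance_bp Tandem-duplication thresholds.
#' @param min_total CRE report retention threshold (default 5).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(genome = NULL, gff3 = NULL, expression = NULL,
                            domains = NULL, cds = NULL, pairs = NULL,
                            go_map = NULL, regulators = NULL,
                            ct_table = NULL, reference_gene = "TIP41",
                            calibrator_sample = NULL,
                            promoter_len = 2000, threshold = 0.90,
                            inclusive = TRUE, lambda = "monocot",
                            alpha = 0.05, max_intervening = 10,
                            max_distance_bp = 200000, min_total = 5) {
  paths <- list(genome = genome, gff3 = gff3, expression = expression,
                domains = domains, cds = cds, pairs = pairs,
                go_map = go_map, regulators = regulators,
                ct_table = ct_table)
  for (nm in names(paths)) {
    p <- paths[[nm]]
    if (!is.null(p) && !file.exists(p)) {
      stop("config field '", nm, "': file not found: ", p)
    }
  }
  stopifnot(promoter_len >= 1, threshold > 0, threshold <= 1,
            alpha > 0, alpha < 1, max_intervening >= 0,
            max_distance_bp >= 0, min_total >= 0)
  structure(c(paths, list(
    reference_gene = reference_gene,
    calibrator_sample = calibrator_sample,
    promoter_len = promoter_len, threshold = threshold,
    inclusive = inclusive, lambda = lambda, alpha = alpha,
    max_intervening = max_intervening,
    max_distance_bp = max_distance_bp, min_total = min_total)),
    class = "pipeline_config")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

.require_field <- function(config, field, stage) {
  if (is.null(config[[field]])) {
    stop("stage '", stage, "' needs config field '", field, "'")
  }
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in fixed order (classify, promoters,
#' scan, kaks, network, enrich, qpcr), writing one or more TSV/FASTA/
#' GraphML outputs per stage under `outdir`, plus a `manifest.json`
#' listing every output with its md5 hash and every parameter used. A
#' stage failure aborts with the stage name and cause. The run is fully
#' deterministic (no randomness is consumed).
#'
#' @param config A `pipeline_config`.
#' @param outdir Output directory (created if needed).
#' @param stages Character vector of stages to run (default: all whose
#'   inputs are configured).
#' @return Invisibly, a list of in-memory stage results plus
#'   `manifest_path`.
#' @export
run_pipeline <- function(config, outdir,
                         stages = c("classify", "promoters", "scan",
                                    "kaks", "network", "enrich",
                                    "qpcr")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  results <- list()

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # stages that are configured (optional inputs present)
  want <- function(s) s %in% stages

  genome <- NULL
  models <- NULL
  promoters <- NULL
  if (any(vapply(c("promoters", "scan", "network"), want, logical(1)))) {
    .require_field(config, "genome", "promoters")
    .require_field(config, "gff3", "promoters")
    genome <- read_genome(config$genome)
    models <- read_gff3(config$gff3)
  }

  if (want("classify") && !is.null(config$domains)) {
    results$classify <- run_stage("classify", function() {
      dom <- read_domains(config$domains)
      assign <- classify_family(dom)
      out <- list(assignments = assign)
      outputs <<- c(outputs,
                    .write_tsv(assign, file.path(outdir,
                                                 "assignments.tsv")))
      if (!is.null(models)) {
        fam_ids <- assign$gene_id[assign$group %in% c("E2F", "DP", "DEL")]
        istats <- intron_stats(models, assign)
        tandem <- detect_tandem(models, intersect(fam_ids, names(models)),
                                max_intervening = config$max_intervening,
                                max_distance_bp = config$max_distance_bp)
        outputs <<- c(outputs,
                      .write_tsv(istats, file.path(outdir,
                                                   "intron_stats.tsv")),
                      .write_tsv(tandem, file.path(outdir, "tandem.tsv")))
        out$intron_stats <- istats
        out$tandem <- tandem
      }
      out
    })
  }

  if (want("promoters")) {
    results$promoters <- run_stage("promoters", function() {
      promoters <<- extract_promoters(genome, models,
                                      upstream_len = config$promoter_len)
      outputs <<- c(outputs, write_promoters_fasta(
        promoters, file.path(outdir, "promoters.fa")))
      promoters
    })
  }

  targets <- NULL
  if (want("scan")) {
    results$scan <- run_stage("scan", function() {
      if (is.null(promoters)) {
        promoters <<- extract_promoters(genome, models,
                                        upstream_len = config$promoter_len)
      }
      targets <<- find_target_genes(promoters)
      hits <- do.call(rbind, lapply(promoters, scan_motif, pattern = E2FAT,
                                    motif_id = "E2FAT"))
      rownames(hits) <- NULL
      cre <- count_cres(promoters, min_total = config$min_total)
      outputs <<- c(outputs,
        .write_tsv(data.frame(gene_id = targets),
                   file.path(outdir, "target_genes.tsv")),
        .write_tsv(hits, file.path(outdir, "e2fat_hits.tsv")),
        .write_tsv(data.frame(gene_id = rownames(cre$filtered),
                              cre$filtered, check.names = FALSE),
                   file.path(outdir, "cre_counts.tsv")))
      list(targets = targets, hits = hits, cre = cre)
    })
  }

  if (want("kaks") && !is.null(config$cds) && !is.null(config$pairs)) {
    results$kaks <- run_stage("kaks", function() {
      cds <- read_genome(config$cds)
      pairs <- utils::read.delim(config$pairs, sep = "\t",
                                 colClasses = "character")
      tab <- kaks_table(cds, pairs)
      lam <- config$lambda
      if (is.character(lam)) lam <- LAMBDA_RATES[[lam]]
      tab$T_mya <- ifelse(is.na(tab$Ks), NA_real_,
                          divergence_time(pmax(tab$Ks, 0), lam))
      outputs <<- c(outputs, .write_tsv(tab, file.path(outdir,
                                                       "kaks.tsv")))
      tab
    })
  }

  network <- NULL
  if (want("network") && !is.null(config$regulators)) {
    results$network <- run_stage("network", function() {
      .require_field(config, "expression", "network")
      expr <- read_expression(config$expression)
      regs <- utils::read.delim(config$regulators, sep = "\t",
                                colClasses = "character")
      stopifnot(all(c("gene_id", "pattern") %in% colnames(regs)))
      if (is.null(targets)) {
        if (is.null(promoters)) {
          promoters <<- extract_promoters(
            genome, models, upstream_len = config$promoter_len)
        }
        targets <<- find_target_genes(promoters)
      }
      # motif -> carriers: scan every promoter for each distinct pattern
      motif_targets <- lapply(unique(regs$pattern), function(pat) {
        find_target_genes(promoters, e2fat_pattern = pat)
      })
      names(motif_targets) <- unique(regs$pattern)
      network <<- build_network(
        expr, stats::setNames(regs$pattern, regs$gene_id), motif_targets,
        threshold = config$threshold, inclusive = config$inclusive)
      outputs <<- c(outputs,
        write_network(network, file.path(outdir, "network_edges.tsv"),
                      "tsv"),
        write_network(network, file.path(outdir, "network.graphml"),
                      "graphml"),
        .write_tsv(rank_hubs(network), file.path(outdir, "hubs.tsv")))
      network
    })
  }

  if (want("enrich") && !is.null(config$go_map)) {
    results$enrich <- run_stage("enrich", function() {
      ann <- read_go_map(config$go_map)
      if (is.null(targets)) {
        stop("enrichment needs the scan stage (target gene set)")
      }
      res <- enrich(intersect(targets, unique(ann$gene_id)), ann,
                    alpha = config$alpha)
      outputs <<- c(outputs, .write_tsv(res, file.path(outdir,
                                                       "enrichment.tsv")))
      res
    })
  }

  if (want("qpcr")) {
    results$qpcr <- run_stage("qpcr", function() {
      out <- list()
      if (!is.null(config$expression)) {
        expr <- read_expression(config$expression)
        lg <- log2_matrix(expr)
        outputs <<- c(outputs, write_expression(
          lg, file.path(outdir, "expression_log2.tsv")))
        out$log2 <- lg
      }
      if (!is.null(config$ct_table) &&
          !is.null(config$calibrator_sample)) {
        ct <- utils::read.delim(config$ct_table, sep = "\t")
        folds <- ddct(ct, config$reference_gene,
                      config$calibrator_sample)
        outputs <<- c(outputs, .write_tsv(folds, file.path(outdir,
                                                           "ddct.tsv")))
        out$ddct <- folds
      }
      out
    })
  }

  manifest <- list(
    parameters = unclass(config)[!vapply(unclass(config), is.null,
                                         logical(1))],
    stages = stages,
    outputs = as.list(stats::setNames(as.character(tools::md5sum(outputs)),
                                      basename(outputs))))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  results$manifest_path <- manifest_path
  invisible(results)
}

#' Self-contained synthetic demo run
#'
#' Generates a seeded synthetic dataset, runs the full pipeline on it, and
#' writes a ground-truth comparison report (`report.json`): binding-site
#' recall/precision, edge recall/precision and sign agreement, and Ks
#' recovery per paralog pair. With the default noise-free configuration
#' the motif and edge recoveries are exact by construction.
#'
#' @param seed Master seed.
#' @param outdir Output directory; the dataset lands in `outdir/data`, the
#'   pipeline outputs in `outdir/run`.
#' @param config Optional `synth_config`; defaults to
#'   `synth_config(seed = seed, noise_sd = 0)`.
#' @return Invisibly, the report list.
#' @export
make_demo <- function(seed, outdir,
                      config = synth_config(seed = seed, noise_sd = 0)) {
  data_dir <- file.path(outdir, "data")
  run_dir <- file.path(outdir, "run")
  ds <- synth_dataset(config, data_dir)

  reg_path <- file.path(data_dir, "regulators.tsv")
  .write_tsv(data.frame(gene_id = ds$truth$regulator_ids,
                        pattern = E2FAT, stringsAsFactors = FALSE),
             reg_path)

  pc <- pipeline_config(
    genome = ds$files[["genome"]], gff3 = ds$files[["gff3"]],
    expression = ds$files[["expression"]], cds = ds$files[["cds"]],
    pairs = ds$files[["pairs"]], go_map = ds$files[["go_map"]],
    regulators = reg_path, promoter_len = config$promoter_len)
  res <- run_pipeline(pc, run_dir)

  # binding-site recovery
  truth_hits <- ds$truth$planted_motif_hits
  found <- res$scan$hits
  key <- function(d, pos_col, strand_col) {
    paste(d$gene_id, d[[pos_col]], d[[strand_col]])
  }
  tset <- key(truth_hits, "tss_relative_pos", "strand")
  fset <- key(found, "tss_relative_start", "strand_of_match")
  motif_recall <- if (length(tset) > 0) {
    mean(tset %in% fset)
  } else 1
  motif_precision <- if (length(fset) > 0) mean(fset %in% tset) else 1

  # edge recovery
  te <- ds$truth$true_edges
  fe <- res$network$edges
  tkey <- paste(te$regulator, te$target, te$sign)
  fkey <- paste(fe$regulator, fe$target, fe$sign)
  edge_recall <- if (length(tkey) > 0) mean(tkey %in% fkey) else 1
  edge_precision <- if (length(fkey) > 0) mean(fkey %in% tkey) else 1

  # Ks recovery
  ks_rows <- lapply(seq_len(nrow(ds$pairs)), function(i) {
    list(pair = paste(ds$pairs$id_a[i], ds$pairs$id_b[i], sep = "|"),
         ds_target = as.numeric(ds$pairs$ds_target[i]),
         ks_recovered = res$kaks$Ks[i])
  })

  report <- list(
    seed = seed,
    motif = list(recall = motif_recall, precision = motif_precision,
                 n_planted = nrow(truth_hits), n_found = nrow(found)),
    edges = list(recall = edge_recall, precision = edge_precision,
                 n_true = nrow(te), n_found = nrow(fe)),
    ks_recovery = ks_rows,
    enrichment_top_term = if (nrow(res$enrich) > 0) {
      res$enrich$term[1]
    } else NA,
    enriched_term_planted = ds$truth$enriched_term)
  report_path <- file.path(outdir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(report, list(report_path = report_path,
                           results = res, dataset = ds)))
}
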