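#' Controlled vocabulary of E2F/DP family domains
#' @export
FAMILY_DOMAINS <- c("E2F_TD", "E2F_DD", "DP", "MarkedBox", "RBR_binding")

# residue overlap between two intervals as a fraction of the shorter one
.overlap_frac <- function(a, b) {
  ov <- min(a[2], b[2]) - max(a[1], b[1]) + 1
  if (ov <= 0) return(0)
  ov / min(a[2] - a[1] + 1, b[2] - b[1] + 1)
}

# collapse hits of one domain type that overlap by >= max_overlap of the
# shorter hit: keep the best e-value representative of each cluster
.collapse_hits <- function(df, max_overlap = 0.2) {
  if (nrow(df) <= 1) return(df)
  df <- df[order(df$evalue, df$start), , drop = FALSE]
  kept <- df[1, , drop = FALSE]
  for (i in seq_len(nrow(df))[-1]) {
    cand <- df[i, ]
    ov <- vapply(seq_len(nrow(kept)), function(j) {
      .overlap_frac(c(cand$start, cand$end),
                    c(kept$start[j], kept$end[j]))
    }, numeric(1))
    if (all(ov < max_overlap)) kept <- rbind(kept, cand)
  }
  kept[order(kept$start), , drop = FALSE]
}

#' Classify one protein's domain architecture into a family group
#'
#' Rule order: (1) two non-overlapping DNA-binding (E2F_TD) hits and no DP
#' domain -> `DEL` (the DEL/E2F-like proteins carry a duplicated
#' DNA-binding domain and bind DNA monomerically); (2) one E2F_TD plus a
#' dimerization domain (E2F_DD), with or without MarkedBox / RBR_binding,
#' -> `E2F`; (3) a DP domain present -> `DP`; (4) any single family-domain
#' hit -> `partial` (truncated or pseudogenized architecture); (5)
#' otherwise `unclassified`. Hits worse than `evalue_cutoff` are ignored;
#' overlapping duplicate hits of the same domain are collapsed, not
#' double-counted.
#'
#' @param domains Data frame of domain hits for one protein: columns
#'   `domain_name`, `start`, `end`, `evalue` (see [read_domains()]).
#' @param evalue_cutoff Ignore hits with `evalue` above this (default 1e-5).
#' @param min_del_separation Two E2F_TD hits count as duplicated when their
#'   residue overlap is below this fraction of the shorter hit
#'   (default 0.2).
#' @return List with `group` (one of E2F, DP, DEL, partial, unclassified)
#'   and `evidence` (domain names used).
#' @export
classify_architecture <- function(domains, evalue_cutoff = 1e-5,
                                  min_del_separation = 0.2) {
  stopifnot(evalue_cutoff > 0)
  empty <- list(group = "unclassified", evidence = character(0))
  if (is.null(domains) || nrow(domains) == 0) return(empty)
  domains <- domains[domains$evalue <= evalue_cutoff &
                       domains$domain_name %in% FAMILY_DOMAINS, ,
                     drop = FALSE]
  if (nrow(domains) == 0) return(empty)
  by_dom <- split(domains, domains$domain_name)
  by_dom <- lapply(by_dom, .collapse_hits, max_overlap = min_del_separation)
  n_td <- if ("E2F_TD" %in% names(by_dom)) nrow(by_dom$E2F_TD) else 0L
  has_dd <- "E2F_DD" %in% names(by_dom)
  has_dp <- "DP" %in% names(by_dom)
  present <- names(by_dom)
  if (n_td >= 2 && !has_dp) {
    return(list(group = "DEL", evidence = present))
  }
  if (n_td >= 1 && has_dd) {
    return(list(group = "E2F", evidence = present))
  }
  if (has_dp) {
    return(list(group = "DP", evidence = present))
  }
  list(group = "partial", evidence = present)
}

#' Classify every protein in a domain table
#'
#' @param domain_table Data frame from [read_domains()].
#' @param evalue_cutoff,min_del_separation Passed to
#'   [classify_architecture()].
#' @return Data frame with columns `gene_id`, `group`, `evidence`
#'   (comma-separated domain names), one row per protein, in order of first
#'   appearance.
#' @export
classify_family <- function(domain_table, evalue_cutoff = 1e-5,
                            min_del_separation = 0.2) {
  ids <- unique(domain_table$protein_id)
  rows <- lapply(ids, function(id) {
    a <- classify_architecture(
      domain_table[domain_table$protein_id == id, , drop = FALSE],
      evalue_cutoff = evalue_cutoff,
      min_del_separation = min_del_separation)
    data.frame(gene_id = id, group = a$group,
               evidence = paste(a$evidence, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-group intron statistics
#'
#' Intron count per gene = exon count - 1. Genes without exon annotation
#' are excluded with a warning.
#'
#' @param models Named list of `gene_model` objects.
#' @param assignments Data frame with `gene_id` and `group` (from
#'   [classify_family()]).
#' @return Data frame per group: `group`, `n_genes`, `min_introns`,
#'   `max_introns`, `mean_introns`.
#' @export
intron_stats <- function(models, assignments) {
  counts <- vapply(models, intron_count, integer(1))
  ids <- names(models)
  bad <- is.na(counts)
  if (any(bad)) {
    warning("excluding gene(s) without exon annotation: ",
            paste(ids[bad], collapse = ", "))
    counts <- counts[!bad]
    ids <- ids[!bad]
  }
  grp <- assignments$group[match(ids, assignments$gene_id)]
  keep <- !is.na(grp)
  df <- data.frame(group = grp[keep], introns = counts[keep])
  out <- do.call(rbind, lapply(split(df, df$group), function(d) {
    data.frame(group = d$group[1], n_genes = nrow(d),
               min_introns = min(d$introns),
               max_introns = max(d$introns),
               mean_introns = mean(d$introns))
  }))
  rownames(out) <- NULL
  out[order(out$group), , drop = FALSE]
}

#' Screen family members for tandem duplications
#'
#' Two family genes form a tandem pair when they lie on the same
#' chromosome separated by at most `max_intervening` non-family genes and
#' at most `max_distance_bp` (span-start to span-start). Neither threshold
#' is universal in the literature, so both are exposed.
#'
#' @param models Named list of `gene_model` objects covering all genes on
#'   the relevant chromosomes (family and non-family; supplies gene order).
#' @param family_ids Character vector of family gene ids.
#' @param max_intervening Maximum non-family genes between the pair
#'   (default 10).
#' @param max_distance_bp Maximum genomic distance in bp (default 2e5).
#' @return Data frame with columns `gene_a`, `gene_b`, `chrom`,
#'   `intervening`, `distance_bp`; zero rows when no tandem pairs exist.
#' @export
detect_tandem <- function(models, family_ids, max_intervening = 10,
                          max_distance_bp = 200000) {
  missing <- setdiff(family_ids, names(models))
  if (length(missing) > 0) {
    stop("family gene(s) missing from gene order: ",
         paste(missing, collapse = ", "))
  }
  info <- data.frame(
    gene_id = names(models),
    chrom = vapply(models, `[[`, "", "chrom"),
    start = vapply(models, function(m) m$start, integer(1)),
    stringsAsFactors = FALSE)
  out <- list()
  for (ch in unique(info$chrom)) {
    d <- info[info$chrom == ch, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    fam_idx <- which(d$gene_id %in% family_ids)
    if (length(fam_idx) < 2) next
    for (k in seq_len(length(fam_idx) - 1)) {
      i <- fam_idx[k]
      j <- fam_idx[k + 1]
      intervening <- j - i - 1L
      dist_bp <- d$start[j] - d$start[i]
      if (intervening <= max_intervening && dist_bp <= max_distance_bp) {
        out[[length(out) + 1]] <- data.frame(
          gene_a = d$gene_id[i], gene_b = d$gene_id[j], chrom = ch,
          intervening = intervening, distance_bp = dist_bp,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      chrom = character(0), intervening = integer(0),
                      distance_bp = integer(0)))
  }
  do.call(rbind, out)
}
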