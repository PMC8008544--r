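#' Relative expression by the 2^-ddCt method
#'
#' Per sample, `dCt = mean Ct(gene) - mean Ct(reference)`; then
#' `ddCt = dCt(sample) - dCt(calibrator)` and the fold change is
#' `2^(-ddCt)`. Replicate Ct values are averaged on the Ct scale before
#' differencing. A constant shift of all Ct values within a sample cancels
#' in dCt.
#'
#' @param ct_table Data frame with columns `sample`, `gene`, `ct`
#'   (one row per replicate measurement; Ct > 0).
#' @param reference_gene Internal-control gene (e.g. TIP41), measured in
#'   every sample.
#' @param calibrator_sample Sample against which fold changes are
#'   expressed (fold = 1 for the calibrator itself).
#' @return Data frame `sample`, `gene`, `dct`, `ddct`, `fold` for every
#'   non-reference gene.
#' @export
ddct <- function(ct_table, reference_gene, calibrator_sample) {
  need <- c("sample", "gene", "ct")
  stopifnot(all(need %in% colnames(ct_table)))
  if (any(ct_table$ct <= 0)) stop("Ct values must be positive")
  if (!calibrator_sample %in% ct_table$sample) {
    stop("calibrator sample not present: ", calibrator_sample)
  }
  samples <- unique(ct_table$sample)
  mean_ct <- function(s, g) {
    v <- ct_table$ct[ct_table$sample == s & ct_table$gene == g]
    if (length(v) == 0) return(NA_real_)
    mean(v)
  }
  ref <- vapply(samples, mean_ct, numeric(1), g = reference_gene)
  if (anyNA(ref)) {
    stop("reference gene ", reference_gene,
         " not measured in sample(s): ",
         paste(samples[is.na(ref)], collapse = ", "))
  }
  names(ref) <- samples
  genes <- setdiff(unique(ct_table$gene), reference_gene)
  rows <- list()
  for (g in genes) {
    dct <- vapply(samples, function(s) mean_ct(s, g) - ref[[s]],
                  numeric(1))
    names(dct) <- samples
    if (is.na(dct[[calibrator_sample]])) {
      stop("gene ", g, " not measured in calibrator sample")
    }
    measured <- samples[!is.na(dct)]
    ddct_v <- dct[measured] - dct[[calibrator_sample]]
    rows[[g]] <- data.frame(
      sample = measured, gene = g,
      dct = unname(dct[measured]), ddct = unname(ddct_v),
      fold = unname(2 ^ (-ddct_v)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' log2-transform an FPKM matrix for heatmap display
#'
#' Elementwise `log2(value + pseudocount)`; shape and dimnames preserved.
#'
#' @param expr Non-negative numeric matrix (genes x conditions).
#' @param pseudocount Added before the log (default 1.0; must be > 0).
#' @return Transformed matrix.
#' @export
log2_matrix <- function(expr, pseudocount = 1.0) {
  stopifnot(is.matrix(expr), pseudocount > 0)
  if (any(expr < 0)) stop("negative expression value")
  log2(expr + pseudocount)
}
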