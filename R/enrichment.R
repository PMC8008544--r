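#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the chance of drawing at
#' least `k` annotated genes when sampling `n` genes without replacement
#' from a background of `N` genes of which `K` carry the term.
#'
#' @param k Observed annotated genes in the target set.
#' @param K Background genes carrying the term.
#' @param n Target-set size.
#' @param N Background size.
#' @return The upper-tail probability.
#' @export
hypergeom_upper <- function(k, K, n, N) {
  if (!(k >= 0 && k <= n && n <= N && K >= 0 && K <= N)) {
    stop("hypergeometric bounds violated (need 0 <= k <= n <= N, K <= N)")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted values
#'
#' Standard step-up FDR adjustment with monotonicity enforcement; output
#' order matches input order.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Hypergeometric GO over-representation with BH FDR
#'
#' One test per term present in the background; over-representation only
#' (upper tail). Results are sorted by q then p; `significant` marks
#' `q < alpha`.
#'
#' @param target_set Character vector of gene ids (must be a subset of
#'   `background`).
#' @param annotation Data frame `gene_id`, `term` (a gene may carry many
#'   terms; see [read_go_map()]).
#' @param background Character vector of background gene ids. Defaults to
#'   all genes with at least one annotation.
#' @param alpha Significance level on q (default 0.05).
#' @return Data frame with columns `term`, `k`, `K`, `n`, `N`, `p`, `q`,
#'   `significant`.
#' @export
enrich <- function(target_set, annotation,
                   background = unique(annotation$gene_id),
                   alpha = 0.05) {
  background <- unique(background)
  if (length(background) == 0) stop("empty background")
  extra <- setdiff(target_set, background)
  if (length(extra) > 0) {
    stop("target gene(s) not in background: ",
         paste(utils::head(extra, 5), collapse = ", "))
  }
  ann <- unique(annotation[annotation$gene_id %in% background,
                           c("gene_id", "term")])
  N <- length(background)
  n <- length(unique(target_set))
  terms <- sort(unique(ann$term))
  if (length(terms) == 0) {
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0), significant = logical(0)))
  }
  K <- vapply(terms, function(t) {
    length(unique(ann$gene_id[ann$term == t]))
  }, integer(1))
  k <- vapply(terms, function(t) {
    length(intersect(target_set, ann$gene_id[ann$term == t]))
  }, integer(1))
  p <- vapply(seq_along(terms), function(i) {
    hypergeom_upper(k[i], K[i], n, N)
  }, numeric(1))
  q <- bh_fdr(p)
  out <- data.frame(term = terms, k = k, K = K, n = n, N = N,
                    p = p, q = q, significant = q < alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$q, out$p, out$term), , drop = FALSE]
}
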