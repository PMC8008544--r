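#' Pearson correlation between two expression profiles
#'
#' Plain Pearson r on raw FPKM values. Profiles must have equal length
#' >= 3; a zero-variance profile makes the correlation undefined and
#' returns `NA` with a warning (callers skip the edge).
#'
#' @param x,y Numeric vectors of equal length.
#' @return Pearson r, or `NA` when undefined.
#' @export
pcc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant profile: correlation undefined, edge skipped")
    return(NA_real_)
  }
  stats::cor(x, y, method = "pearson")
}

#' Build the evidence-gated regulatory network
#'
#' An edge regulator -> target is emitted iff (a) the target's promoter
#' carries the regulator family's binding motif, and (b) the Pearson
#' correlation of their expression profiles passes the threshold
#' (`r >= +threshold` for an activation edge, `r <= -threshold` for a
#' repression edge; inclusive on both sides by default). Self-edges are
#' never emitted. Motif evidence is supplied as a map from motif pattern to
#' the set of genes carrying it, so E2F/DP genes can appear both as
#' regulators and as targets of other TF families (e.g. MYB sites in E2F/DP
#' promoters).
#'
#' @param expr Expression matrix (genes x conditions) covering all
#'   regulators and targets.
#' @param regulator_patterns Named character vector: regulator gene id ->
#'   binding-motif pattern of its family.
#' @param motif_targets Named list: motif pattern -> character vector of
#'   genes whose promoter carries that motif (e.g. from
#'   [find_target_genes()] / [scan_motif()]).
#' @param threshold Correlation threshold (default 0.90).
#' @param inclusive Keep edges at exactly +/- threshold (default TRUE).
#' @param node_groups Optional named character vector gene -> group label
#'   (family assignment); genes absent from it are labelled `"target"`.
#' @return Object of class `reg_network`: list with `edges` (data frame
#'   `regulator`, `target`, `r`, `sign`) and `nodes` (data frame `gene_id`,
#'   `group`, `tissue_max`).
#' @export
build_network <- function(expr, regulator_patterns, motif_targets,
                          threshold = 0.90, inclusive = TRUE,
                          node_groups = NULL) {
  stopifnot(is.matrix(expr), threshold > 0, threshold <= 1)
  regs <- names(regulator_patterns)
  missing <- setdiff(regs, rownames(expr))
  if (length(missing) > 0) {
    stop("regulator(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  }
  edges <- list()
  for (reg in regs) {
    pat <- regulator_patterns[[reg]]
    targets <- motif_targets[[pat]]
    targets <- setdiff(intersect(targets, rownames(expr)), reg)
    for (tg in targets) {
      r <- suppressWarnings(pcc(expr[reg, ], expr[tg, ]))
      if (is.na(r)) next
      keep <- if (inclusive) abs(r) >= threshold else abs(r) > threshold
      if (!keep) next
      edges[[length(edges) + 1]] <- data.frame(
        regulator = reg, target = tg, r = r,
        sign = if (r > 0) "activation" else "repression",
        stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges) == 0) {
    data.frame(regulator = character(0), target = character(0),
               r = numeric(0), sign = character(0))
  } else {
    do.call(rbind, edges)
  }
  edges <- edges[order(edges$regulator, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  node_ids <- sort(unique(c(edges$regulator, edges$target, regs)))
  tmax <- tissue_max(expr)
  groups <- rep("target", length(node_ids))
  names(groups) <- node_ids
  if (!is.null(node_groups)) {
    hit <- intersect(node_ids, names(node_groups))
    groups[hit] <- node_groups[hit]
  }
  nodes <- data.frame(
    gene_id = node_ids,
    group = unname(groups),
    tissue_max = tmax$condition[match(node_ids, tmax$gene_id)],
    stringsAsFactors = FALSE)
  structure(list(edges = edges, nodes = nodes,
                 threshold = threshold, inclusive = inclusive),
            class = "reg_network")
}

#' @export
print.reg_network <- function(x, ...) {
  cat(sprintf("<reg_network> %d nodes, %d edges (|r| >%s %.2f)\n",
              nrow(x$nodes), nrow(x$edges),
              if (x$inclusive) "=" else "", x$threshold))
  invisible(x)
}

#' Convert a reg_network to an igraph object
#'
#' Node attributes `group` and `tissue_max`, edge attributes `r` and
#' `sign`, are carried over; used for GraphML export.
#'
#' @param network A `reg_network`.
#' @return A directed `igraph` graph.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "reg_network"))
  igraph::graph_from_data_frame(network$edges, directed = TRUE,
                                vertices = network$nodes)
}

#' Rank network hubs by degree
#'
#' Total (in + out) degree, sorted descending; ties broken
#' lexicographically by gene id.
#'
#' @param network A `reg_network`.
#' @return Data frame `gene_id`, `degree`, best-connected first.
#' @export
rank_hubs <- function(network) {
  stopifnot(inherits(network, "reg_network"))
  ids <- network$nodes$gene_id
  if (length(ids) == 0) {
    return(data.frame(gene_id = character(0), degree = integer(0)))
  }
  deg <- vapply(ids, function(g) {
    sum(network$edges$regulator == g) + sum(network$edges$target == g)
  }, integer(1))
  o <- order(-deg, ids)
  data.frame(gene_id = ids[o], degree = unname(deg[o]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Condition of maximum expression per gene
#'
#' Argmax over conditions; ties broken by column order in the matrix
#' header. All-zero genes are flagged (their argmax is the first
#' condition by the tie rule but carries no signal).
#'
#' @param expr Expression matrix (genes x conditions).
#' @return Data frame `gene_id`, `condition`, `all_zero`.
#' @export
tissue_max <- function(expr) {
  stopifnot(is.matrix(expr), nrow(expr) > 0, ncol(expr) > 0)
  idx <- apply(expr, 1, which.max)
  data.frame(
    gene_id = rownames(expr),
    condition = colnames(expr)[idx],
    all_zero = apply(expr, 1, function(v) all(v == 0)),
    row.names = NULL, stringsAsFactors = FALSE)
}
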