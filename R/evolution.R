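#' Per-site substitution rates used for divergence dating
#'
#' Synonymous substitutions per site per year: `monocot` = 6.5e-9,
#' `dicot` = 1.5e-8.
#' @export
LAMBDA_RATES <- c(monocot = 6.5e-9, dicot = 1.5e-8)

.GENETIC_CODE <- NULL

.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- toupper(names(gc))
  gc
}

.translate_codon <- function(codon, code) {
  aa <- code[codon]
  if (is.na(aa)) stop("unrecognized codon: ", codon)
  unname(aa)
}

#' Build a validated codon pair alignment
#'
#' Both sequences must have equal length, a multiple of 3, contain only
#' A/C/G/T, and translate without internal stop codons in frame 0. Gap
#' columns (positions where either sequence has `-`) are removed before
#' validation; removal is done codon-wise, dropping any codon containing a
#' gap in either sequence.
#'
#' @param seq_a,seq_b Coding sequences (frame 0, same length after gap
#'   removal).
#' @param ids Character vector of length 2 naming the pair.
#' @return An object of class `codon_pair_alignment`.
#' @export
codon_pair_alignment <- function(seq_a, seq_b, ids = c("a", "b")) {
  seq_a <- toupper(seq_a)
  seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) stop("aligned sequences differ in length")
  if (nchar(seq_a) %% 3 != 0) stop("alignment length not a multiple of 3")
  ca <- substring(seq_a, seq(1, nchar(seq_a), 3), seq(3, nchar(seq_a), 3))
  cb <- substring(seq_b, seq(1, nchar(seq_b), 3), seq(3, nchar(seq_b), 3))
  gap <- grepl("-", ca) | grepl("-", cb)
  ca <- ca[!gap]
  cb <- cb[!gap]
  if (length(ca) == 0) stop("no ungapped codons left")
  if (any(grepl("[^ACGT]", c(ca, cb)))) {
    stop("codon pair alignment must be unambiguous A/C/G/T")
  }
  code <- .codon_table()
  aa_a <- code[ca]
  aa_b <- code[cb]
  n <- length(ca)
  if (any(aa_a[-n] == "*") || any(aa_b[-n] == "*")) {
    stop("internal stop codon in alignment")
  }
  if (aa_a[n] == "*" || aa_b[n] == "*") {
    # trailing stop codons are not informative for Ka/Ks; drop the column
    ca <- ca[-n]
    cb <- cb[-n]
    if (length(ca) == 0) stop("no sense codons left")
  }
  structure(list(codons_a = ca, codons_b = cb, ids = ids),
            class = "codon_pair_alignment")
}

# Synonymous site fraction of one codon: for each position, the fraction
# of the three single-base changes that are synonymous, with changes to
# stop codons removed from the denominator (they are counted as neither
# synonymous nor nonsynonymous sites). Returns c(S, N) with S + N = 3.
.codon_sites <- function(codon, code) {
  bases <- c("A", "C", "G", "T")
  aa <- .translate_codon(codon, code)
  s <- 0
  for (pos in 1:3) {
    orig <- substr(codon, pos, pos)
    alt_aas <- vapply(setdiff(bases, orig), function(b) {
      mut <- codon
      substr(mut, pos, pos) <- b
      unname(code[mut])
    }, "")
    non_stop <- alt_aas[alt_aas != "*"]
    if (length(non_stop) > 0) {
      s <- s + sum(non_stop == aa) / length(non_stop)
    }
  }
  c(S = s, N = 3 - s)
}

# Pathway-averaged synonymous/nonsynonymous difference counts between two
# codons. All orderings of the differing positions are walked; pathways
# passing through a stop codon are discarded (classic NG86 as implemented
# by DnaSP-style counters). If every pathway hits a stop, all pathways are
# used. Returns c(Sd, Nd).
.codon_diffs <- function(c1, c2, code) {
  if (c1 == c2) return(c(Sd = 0, Nd = 0))
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  perms <- .permutations(pos)
  walk <- function(order_) {
    cur <- c1
    sd <- 0
    nd <- 0
    ok <- TRUE
    for (p in order_) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (code[nxt] == "*") ok <- FALSE
      if (code[cur] == code[nxt]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd, as.numeric(ok))
  }
  res <- t(vapply(perms, walk, numeric(3)))
  valid <- res[, 3] == 1
  if (any(valid)) res <- res[valid, , drop = FALSE]
  c(Sd = mean(res[, 1]), Nd = mean(res[, 2]))
}

.permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in .permutations(x[-i])) {
      out[[length(out) + 1]] <- c(x[i], rest)
    }
  }
  out
}

#' Nei-Gojobori (1986) site and difference counts
#'
#' Synonymous (S) and nonsynonymous (N) site counts are computed per codon
#' by enumerating the nine single-base changes under the standard nuclear
#' code, excluding mutations to stop codons from each position's
#' denominator, and are averaged over the two sequences. Differences (Sd,
#' Nd) between unequal codons are averaged over all substitution pathways
#' that avoid stop codons, each pathway step classified synonymous or
#' nonsynonymous.
#'
#' @param aln A `codon_pair_alignment`.
#' @return Named numeric vector `c(S, N, Sd, Nd)`.
#' @export
ng86_counts <- function(aln) {
  stopifnot(inherits(aln, "codon_pair_alignment"))
  code <- .codon_table()
  sites_cache <- new.env(parent = emptyenv())
  get_sites <- function(codon) {
    v <- sites_cache[[codon]]
    if (is.null(v)) {
      v <- .codon_sites(codon, code)
      sites_cache[[codon]] <- v
    }
    v
  }
  diffs_cache <- new.env(parent = emptyenv())
  get_diffs <- function(c1, c2) {
    key <- paste0(c1, c2)
    v <- diffs_cache[[key]]
    if (is.null(v)) {
      v <- .codon_diffs(c1, c2, code)
      diffs_cache[[key]] <- v
    }
    v
  }
  S <- 0
  N <- 0
  Sd <- 0
  Nd <- 0
  for (i in seq_along(aln$codons_a)) {
    sa <- get_sites(aln$codons_a[i])
    sb <- get_sites(aln$codons_b[i])
    S <- S + (sa["S"] + sb["S"]) / 2
    N <- N + (sa["N"] + sb["N"]) / 2
    d <- get_diffs(aln$codons_a[i], aln$codons_b[i])
    Sd <- Sd + d["Sd"]
    Nd <- Nd + d["Nd"]
  }
  c(S = unname(S), N = unname(N), Sd = unname(Sd), Nd = unname(Nd))
}

.jc_correct <- function(p) {
  if (is.nan(p)) return(c(value = NaN, saturated = 0))
  if (4 / 3 * p >= 1) return(c(value = NA_real_, saturated = 1))
  # + 0 normalizes the negative zero that -x * log(1) would produce
  c(value = -3 / 4 * log(1 - 4 / 3 * p) + 0, saturated = 0)
}

#' Ka/Ks for a codon pair alignment
#'
#' NG86 counting followed by Jukes-Cantor correction:
#' `Ks = -(3/4) ln(1 - (4/3) pS)` and likewise for Ka. Saturated
#' proportions (`4/3 p >= 1`) leave the corrected value `NA` with a flag;
#' the raw proportions are always returned. The ratio is `NA`-flagged when
#' Ks is zero or undefined.
#'
#' @param aln A `codon_pair_alignment`.
#' @return Object of class `kaks_result`: list with `S`, `N`, `Sd`, `Nd`,
#'   `pS`, `pN`, `Ks`, `Ka`, `ratio`, `ks_saturated`, `ka_saturated`,
#'   `ratio_defined`, `ids`.
#' @export
kaks <- function(aln) {
  cnt <- ng86_counts(aln)
  pS <- if (cnt["S"] > 0) cnt["Sd"] / cnt["S"] else NaN
  pN <- if (cnt["N"] > 0) cnt["Nd"] / cnt["N"] else NaN
  ks <- .jc_correct(unname(pS))
  ka <- .jc_correct(unname(pN))
  ratio_defined <- !is.na(ka["value"]) && !is.na(ks["value"]) &&
    !is.nan(ka["value"]) && !is.nan(ks["value"]) && ks["value"] > 0
  structure(
    list(S = unname(cnt["S"]), N = unname(cnt["N"]),
         Sd = unname(cnt["Sd"]), Nd = unname(cnt["Nd"]),
         pS = unname(pS), pN = unname(pN),
         Ks = unname(ks["value"]), Ka = unname(ka["value"]),
         ratio = if (ratio_defined) {
           unname(ka["value"] / ks["value"])
         } else NA_real_,
         ks_saturated = ks["saturated"] == 1,
         ka_saturated = ka["saturated"] == 1,
         ratio_defined = ratio_defined,
         ids = aln$ids),
    class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf(
    "<kaks_result> %s vs %s: Ka=%.4f Ks=%.4f Ka/Ks=%s (S=%.1f N=%.1f)\n",
    x$ids[1], x$ids[2], x$Ka, x$Ks,
    if (x$ratio_defined) sprintf("%.3f", x$ratio) else "undef",
    x$S, x$N))
  invisible(x)
}

#' Divergence time from synonymous divergence
#'
#' `T = Ks / (2 * lambda)` years, reported in millions of years (mya).
#' With the monocot rate (6.5e-9), Ks = 0.13 dates to 10.0 mya.
#'
#' @param Ks Synonymous substitutions per synonymous site (>= 0).
#' @param rate_lambda Substitution rate per site per year, or one of
#'   `"monocot"` / `"dicot"` (see [LAMBDA_RATES]).
#' @return Divergence time in mya.
#' @export
divergence_time <- function(Ks, rate_lambda = "monocot") {
  if (is.character(rate_lambda)) {
    rate_lambda <- LAMBDA_RATES[[match.arg(rate_lambda,
                                           names(LAMBDA_RATES))]]
  }
  stopifnot(rate_lambda > 0)
  if (any(Ks < 0, na.rm = TRUE)) stop("negative Ks")
  Ks / (2 * rate_lambda) / 1e6
}

#' Ka/Ks and divergence times for a list of paralog pairs
#'
#' Convenience wrapper: reads CDS from FASTA, pairs them per the pair list,
#' and reports NG86 statistics plus divergence times at both shipped rates.
#' Pairs must be equal-length ungapped CDS (near-identical paralogs); build
#' codon alignments upstream otherwise.
#'
#' @param cds Named character vector of CDS (e.g. from [read_genome()] on a
#'   CDS FASTA).
#' @param pairs Data frame with columns `id_a`, `id_b`.
#' @return Data frame, one row per pair, with S, N, Sd, Nd, pS, pN, Ka, Ks,
#'   ratio and `T_mya_monocot` / `T_mya_dicot`.
#' @export
kaks_table <- function(cds, pairs) {
  stopifnot(all(c("id_a", "id_b") %in% colnames(pairs)))
  missing <- setdiff(c(pairs$id_a, pairs$id_b), names(cds))
  if (length(missing) > 0) {
    stop("pair ids absent from CDS: ", paste(missing, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    aln <- codon_pair_alignment(cds[[pairs$id_a[i]]], cds[[pairs$id_b[i]]],
                                ids = c(pairs$id_a[i], pairs$id_b[i]))
    r <- kaks(aln)
    data.frame(
      id_a = pairs$id_a[i], id_b = pairs$id_b[i],
      S = r$S, N = r$N, Sd = r$Sd, Nd = r$Nd,
      pS = r$pS, pN = r$pN, Ka = r$Ka, Ks = r$Ks, ratio = r$ratio,
      T_mya_monocot = if (is.na(r$Ks)) NA_real_ else
        divergence_time(r$Ks, "monocot"),
      T_mya_dicot = if (is.na(r$Ks)) NA_real_ else
        divergence_time(r$Ks, "dicot"),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
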