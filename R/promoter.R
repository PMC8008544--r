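#' The E2F/DP binding-site motif (E2FAT)
#'
#' The literal promoter element bound by E2F/DP dimers in plants.
#' @export
E2FAT <- "TTTCCCGCC"

#' Extract a strand-aware promoter window
#'
#' The window runs from -`upstream_len` to +1 in TSS coordinates and
#' includes the TSS base, so a full-length promoter has
#' `upstream_len + 1` nucleotides. On the `+` strand this is the genomic
#' interval `[tss - upstream_len, tss]`; on the `-` strand it is
#' `[tss, tss + upstream_len]` reverse-complemented, so the returned
#' sequence always reads 5' to 3' relative to the gene. Windows running off
#' a contig end are clipped and flagged `truncated`.
#'
#' @param genome Named character vector from [read_genome()].
#' @param model A `gene_model`.
#' @param upstream_len Upstream extent in bp (default 2000).
#' @return A `promoter_region`: list with `gene_id`, `seq`, `chrom`,
#'   `genomic_start`, `genomic_end`, `strand`, `truncated`.
#' @export
extract_promoter <- function(genome, model, upstream_len = 2000) {
  stopifnot(inherits(model, "gene_model"), upstream_len >= 1)
  if (!model$chrom %in% names(genome)) {
    stop("chromosome ", model$chrom, " not in genome")
  }
  chrom_seq <- genome[[model$chrom]]
  clen <- nchar(chrom_seq)
  if (model$tss < 1 || model$tss > clen) {
    stop("TSS of ", model$gene_id, " outside chromosome ", model$chrom)
  }
  if (model$strand == "+") {
    gstart <- max(1L, model$tss - as.integer(upstream_len))
    gend <- model$tss
    truncated <- gstart > model$tss - upstream_len
  } else {
    gstart <- model$tss
    gend <- min(clen, model$tss + as.integer(upstream_len))
    truncated <- gend < model$tss + upstream_len
  }
  s <- substr(chrom_seq, gstart, gend)
  if (model$strand == "-") s <- revcomp(s)
  structure(
    list(gene_id = model$gene_id, seq = s, chrom = model$chrom,
         genomic_start = gstart, genomic_end = gend,
         strand = model$strand, truncated = truncated),
    class = "promoter_region")
}

#' @export
print.promoter_region <- function(x, ...) {
  cat(sprintf("<promoter_region> %s %s:%d-%d(%s) %d nt%s\n",
              x$gene_id, x$chrom, x$genomic_start, x$genomic_end,
              x$strand, nchar(x$seq),
              if (x$truncated) " [truncated]" else ""))
  invisible(x)
}

#' Extract promoters for a list of gene models
#'
#' @inheritParams extract_promoter
#' @param models Named list of `gene_model` objects.
#' @return Named list of `promoter_region` objects.
#' @export
extract_promoters <- function(genome, models, upstream_len = 2000) {
  lapply(models, extract_promoter, genome = genome,
         upstream_len = upstream_len)
}

# index within the promoter string -> TSS-relative coordinate (+1 = TSS
# base = last base of the string; there is no position 0)
.tss_relative <- function(idx, promoter_len) {
  rel <- idx - promoter_len
  ifelse(rel >= 0L, rel + 1L, rel)
}

#' Scan a promoter for a motif
#'
#' Exact IUPAC matching on the promoter strand and, by default, on its
#' reverse complement. The pattern's ambiguity codes are expanded; `N` in
#' the *subject* sequence never matches. Overlapping matches are all
#' reported. Positions are TSS-relative (`+1` = TSS base, negative
#' upstream; match start is the 5'-most base of the occurrence in promoter
#' orientation).
#'
#' @param promoter A `promoter_region`.
#' @param pattern IUPAC motif string (e.g. [E2FAT]).
#' @param motif_id Label stored on each hit (defaults to the pattern).
#' @param both_strands Also scan the reverse complement (default TRUE).
#' @return Data frame with columns `gene_id`, `motif_id`,
#'   `tss_relative_start`, `strand_of_match`, `matched_seq`.
#' @export
scan_motif <- function(promoter, pattern, motif_id = pattern,
                       both_strands = TRUE) {
  stopifnot(inherits(promoter, "promoter_region"))
  if (!nzchar(pattern)) stop("empty motif pattern")
  if (grepl(sprintf("[^%s]", .IUPAC_DNA), toupper(pattern))) {
    stop("pattern contains non-IUPAC characters: ", pattern)
  }
  plen <- nchar(promoter$seq)
  subject <- Biostrings::DNAString(promoter$seq)
  hits <- function(pat) {
    if (nchar(pat) > plen) return(integer(0))
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject,
                                  fixed = "subject")
    Biostrings::start(m)
  }
  slice <- function(at) {
    if (length(at) == 0) return(character(0))
    substring(promoter$seq, at, at + nchar(pattern) - 1L)
  }
  fw <- hits(toupper(pattern))
  res <- data.frame(
    gene_id = rep(promoter$gene_id, length(fw)),
    motif_id = rep(motif_id, length(fw)),
    tss_relative_start = .tss_relative(fw, plen),
    strand_of_match = rep("+", length(fw)),
    matched_seq = slice(fw),
    stringsAsFactors = FALSE)
  if (both_strands) {
    rc <- hits(revcomp(toupper(pattern)))
    res_rc <- data.frame(
      gene_id = rep(promoter$gene_id, length(rc)),
      motif_id = rep(motif_id, length(rc)),
      tss_relative_start = .tss_relative(rc, plen),
      strand_of_match = rep("-", length(rc)),
      matched_seq = slice(rc),
      stringsAsFactors = FALSE)
    res <- rbind(res, res_rc)
  }
  # ambiguity codes in the *subject* never match (N is not evidence)
  res <- res[grepl("^[ACGT]+$", res$matched_seq), , drop = FALSE]
  res <- res[order(res$tss_relative_start, res$strand_of_match), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Screen a gene universe for E2F/DP target genes
#'
#' A gene is a target when its promoter carries at least one E2FAT
#' occurrence on either strand.
#'
#' @param promoters Named list of `promoter_region` objects covering the
#'   gene universe.
#' @param e2fat_pattern Binding-site motif (default [E2FAT]).
#' @return Sorted character vector of target gene ids.
#' @export
find_target_genes <- function(promoters, e2fat_pattern = E2FAT) {
  hit <- vapply(promoters, function(p) {
    nrow(scan_motif(p, e2fat_pattern)) > 0
  }, logical(1))
  sort(vapply(promoters[hit], `[[`, "", "gene_id"))
}

#' Default cis-regulatory element dictionary
#'
#' Entries named after commonly surveyed plant promoter elements (ABRE,
#' TGACG-motif, TCA-element, CAT-box, P-box, GARE-motif, MYB/MYC binding
#' sites, light-responsive elements). The patterns shipped here are
#' illustrative single-sequence stand-ins, not canonical database entries;
#' replace them with your own dictionary for real screens.
#'
#' @return Data frame with columns `motif_id`, `pattern`, `category`.
#' @export
default_cre_dictionary <- function() {
  data.frame(
    motif_id = c("ABRE", "TGACG-motif", "TCA-element", "CAT-box",
                 "P-box", "GARE-motif", "MYB", "MYC",
                 "Box4", "G-box", "E2FAT"),
    pattern = c("ACGTG", "TGACG", "CCATCTTTTT", "GCCACT",
                "CCTTTTG", "TCTGTTG", "CAACTG", "CACATG",
                "ATTAAT", "CACGTG", E2FAT),
    category = c("hormone", "hormone", "hormone", "meristem",
                 "hormone", "hormone", "TF-binding", "TF-binding",
                 "light", "light", "TF-binding"),
    stringsAsFactors = FALSE)
}

#' Validate a CRE dictionary
#' @param dictionary Data frame with `motif_id`, `pattern`, `category`.
#' @return The dictionary, invisibly, after validation.
#' @export
validate_cre_dictionary <- function(dictionary) {
  if (!is.data.frame(dictionary) || nrow(dictionary) == 0) {
    stop("CRE dictionary must be a non-empty data frame")
  }
  need <- c("motif_id", "pattern", "category")
  if (!all(need %in% colnames(dictionary))) {
    stop("CRE dictionary needs columns: ", paste(need, collapse = ", "))
  }
  if (any(!nzchar(dictionary$pattern))) stop("empty pattern in dictionary")
  if (any(grepl(sprintf("[^%s]", .IUPAC_DNA),
                toupper(dictionary$pattern)))) {
    stop("non-IUPAC pattern in dictionary")
  }
  invisible(dictionary)
}

#' Count cis-regulatory elements per promoter
#'
#' Scans every promoter for every dictionary entry (both strands) and
#' tabulates per-gene per-motif hit counts. Motifs whose genome-wide total
#' does not exceed `min_total` are dropped from the filtered report; the
#' raw table is always returned alongside.
#'
#' @param promoters Named list of `promoter_region` objects.
#' @param dictionary CRE dictionary (see [default_cre_dictionary()]).
#' @param min_total Retention threshold: keep motifs with total
#'   `> min_total` (default 5).
#' @return List with `counts` (raw genes x motifs integer matrix),
#'   `filtered` (same, columns passing the threshold), and `totals`
#'   (named genome-wide totals per motif).
#' @export
count_cres <- function(promoters, dictionary = default_cre_dictionary(),
                       min_total = 5) {
  validate_cre_dictionary(dictionary)
  genes <- vapply(promoters, `[[`, "", "gene_id")
  counts <- matrix(0L, nrow = length(promoters), ncol = nrow(dictionary),
                   dimnames = list(genes, dictionary$motif_id))
  for (j in seq_len(nrow(dictionary))) {
    for (i in seq_along(promoters)) {
      counts[i, j] <- nrow(scan_motif(promoters[[i]],
                                      dictionary$pattern[j],
                                      motif_id = dictionary$motif_id[j]))
    }
  }
  totals <- colSums(counts)
  keep <- totals > min_total
  list(counts = counts,
       filtered = counts[, keep, drop = FALSE],
       totals = totals)
}

#' Write promoter sequences as FASTA
#'
#' @param promoters Named list of `promoter_region` objects.
#' @param path Output FASTA path (ids = gene ids).
#' @return `path`, invisibly.
#' @export
write_promoters_fasta <- function(promoters, path) {
  seqs <- Biostrings::DNAStringSet(
    vapply(promoters, `[[`, "", "seq"))
  names(seqs) <- vapply(promoters, `[[`, "", "gene_id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
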