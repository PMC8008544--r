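#' Read a genome FASTA into a named character vector
#'
#' Sequences are uppercased on read. Record ids must be unique and sequences
#' must use the IUPAC nucleotide alphabet (ambiguity codes and N allowed).
#'
#' @param fasta_path Path to a FASTA file.
#' @return Named character vector, one uppercase sequence per record id
#'   (id = first whitespace-delimited token of the header).
#' @export
read_genome <- function(fasta_path) {
  stopifnot(file.exists(fasta_path))
  set <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  bad <- grepl(sprintf("[^%s]", .IUPAC_DNA), seqs)
  if (any(bad)) {
    stop("non-IUPAC characters in sequence(s): ",
         paste(ids[bad], collapse = ", "))
  }
  names(seqs) <- ids
  seqs
}

.IUPAC_DNA <- "ACGTRYSWKMBDHVN"

#' Construct a gene model
#'
#' The coordinate backbone for promoter extraction and intron statistics.
#' All coordinates are 1-based inclusive genomic positions. The TSS is the
#' 5' end of the gene span by strand: the span start on `+`, the span end
#' on `-`.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome/contig id.
#' @param strand `"+"` or `"-"`.
#' @param start,end 1-based inclusive gene span.
#' @param exons Two-column matrix (start, end) of exon intervals, sorted in
#'   genomic order, non-overlapping. May have zero rows.
#' @param cds Optional CDS intervals, same layout as `exons`.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, start, end,
                       exons = matrix(numeric(0), ncol = 2),
                       cds = matrix(numeric(0), ncol = 2)) {
  stopifnot(strand %in% c("+", "-"), start <= end)
  exons <- matrix(as.integer(exons), ncol = 2)
  cds <- matrix(as.integer(cds), ncol = 2)
  if (nrow(exons) > 0) {
    if (any(exons[, 1] > exons[, 2])) stop("exon start > end")
    o <- order(exons[, 1])
    exons <- exons[o, , drop = FALSE]
    if (nrow(exons) > 1 &&
        any(exons[-1, 1] <= exons[-nrow(exons), 2])) {
      stop("overlapping exons in gene ", gene_id)
    }
    if (min(exons[, 1]) < start || max(exons[, 2]) > end) {
      stop("exon outside gene span in gene ", gene_id)
    }
  }
  structure(
    list(gene_id = gene_id, chrom = chrom, strand = strand,
         start = as.integer(start), end = as.integer(end),
         tss = if (strand == "+") as.integer(start) else as.integer(end),
         exons = exons, cds = cds),
    class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d(%s) tss=%d exons=%d\n",
              x$gene_id, x$chrom, x$start, x$end, x$strand, x$tss,
              nrow(x$exons)))
  invisible(x)
}

#' Number of introns in a gene model
#'
#' @param model A `gene_model`.
#' @return `max(exon count - 1, 0)`; `NA` for a model without exon
#'   annotation.
#' @export
intron_count <- function(model) {
  n <- nrow(model$exons)
  if (n == 0) return(NA_integer_)
  n - 1L
}

#' Read gene models from a GFF3 file
#'
#' Expects the canonical gene -> mRNA -> exon/CDS hierarchy (1-based
#' inclusive coordinates). One `gene_model` is built per gene feature; when
#' a gene carries several mRNAs the one with the lexicographically first ID
#' supplies the exon/CDS structure and the TSS is taken from the gene span.
#'
#' @param gff_path Path to a GFF3 file.
#' @return Named list of `gene_model` objects (names = gene ids), ordered as
#'   in the file.
#' @export
read_gff3 <- function(gff_path) {
  stopifnot(file.exists(gff_path))
  gr <- rtracklayer::import(gff_path, format = "gff3")
  typ <- as.character(gr$type)
  genes <- gr[typ == "gene"]
  if (length(genes) == 0) stop("no gene features in ", gff_path)
  if (any(as.character(GenomicRanges::strand(genes)) == "*")) {
    stop("gene feature without strand")
  }
  mrna <- gr[typ %in% c("mRNA", "transcript")]
  kids <- gr[typ %in% c("exon", "CDS")]
  kid_parent <- vapply(kids$Parent, function(p) as.character(p)[1], "")
  mrna_parent <- vapply(mrna$Parent, function(p) as.character(p)[1], "")

  out <- vector("list", length(genes))
  gids <- as.character(genes$ID)
  for (i in seq_along(genes)) {
    g <- genes[i]
    gid <- gids[i]
    mi <- which(mrna_parent == gid)
    exons <- matrix(numeric(0), ncol = 2)
    cds <- matrix(numeric(0), ncol = 2)
    if (length(mi) > 0) {
      mid <- sort(as.character(mrna$ID[mi]))[1]
      m <- mrna[as.character(mrna$ID) == mid]
      if (GenomicRanges::start(m) < GenomicRanges::start(g) ||
          GenomicRanges::end(m) > GenomicRanges::end(g)) {
        stop("mRNA ", mid, " outside gene span of ", gid)
      }
      take <- function(what) {
        k <- kids[kid_parent == mid & as.character(kids$type) == what]
        if (length(k) == 0) return(matrix(numeric(0), ncol = 2))
        if (any(GenomicRanges::start(k) < GenomicRanges::start(g)) ||
            any(GenomicRanges::end(k) > GenomicRanges::end(g))) {
          stop(what, " outside gene span of ", gid)
        }
        cbind(GenomicRanges::start(k), GenomicRanges::end(k))
      }
      exons <- take("exon")
      cds <- take("CDS")
    }
    out[[i]] <- gene_model(
      gene_id = gid,
      chrom = as.character(GenomicRanges::seqnames(g)),
      strand = as.character(GenomicRanges::strand(g)),
      start = GenomicRanges::start(g), end = GenomicRanges::end(g),
      exons = exons, cds = cds)
  }
  names(out) <- gids
  out
}

#' Read a genes-by-conditions FPKM matrix from TSV
#'
#' First column holds gene ids, the header row condition ids. Values must
#' parse as non-negative reals; ragged rows, duplicate gene ids and
#' duplicate condition ids are rejected.
#'
#' @param tsv_path Path to a tab-separated expression table.
#' @return Numeric matrix with gene-id rownames and condition-id colnames.
#' @export
read_expression <- function(tsv_path) {
  stopifnot(file.exists(tsv_path))
  df <- utils::read.delim(tsv_path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("expression table needs gene ids plus >= 1 condition")
  gene_ids <- df[[1]]
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene id(s): ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  cond <- colnames(df)[-1]
  if (anyDuplicated(cond)) stop("duplicate condition ids in header")
  vals <- suppressWarnings(
    vapply(df[-1], as.numeric, numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(gene_ids, cond))
  if (anyNA(vals)) stop("non-numeric or missing expression value")
  if (any(vals < 0)) stop("negative FPKM value")
  vals
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()].
#'
#' @param mat Numeric matrix (genes x conditions) with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat,
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a regulatory network
#'
#' Writes either a tab-separated edge list (columns `regulator`, `target`,
#' `r`, `sign`) or GraphML. The edge-list route round-trips exactly through
#' [read_network_edges()].
#'
#' @param network A `reg_network` (see [build_network()]).
#' @param path Output path.
#' @param format `"tsv"` (edge list) or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("tsv", "graphml")) {
  stopifnot(inherits(network, "reg_network"))
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(network$edges, path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    g <- as_igraph(network)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a network edge list written by [write_network()]
#'
#' @param path Path to the TSV edge list.
#' @return Data frame with columns `regulator`, `target`, `r`, `sign`.
#' @export
read_network_edges <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character",
                                         "numeric", "character"))
  stopifnot(identical(colnames(df),
                      c("regulator", "target", "r", "sign")))
  df
}

#' Read a per-protein domain-annotation table
#'
#' Columns: `protein_id`, `domain_name`, `start`, `end`, `evalue`
#' (hmmscan-domtblout-like, produced upstream of this package).
#'
#' @param tsv_path Path to the TSV table.
#' @return Data frame with those five columns.
#' @export
read_domains <- function(tsv_path) {
  df <- utils::read.delim(tsv_path, sep = "\t", header = TRUE)
  need <- c("protein_id", "domain_name", "start", "end", "evalue")
  if (!all(need %in% colnames(df))) {
    stop("domain table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(df$start > df$end)) stop("domain start > end")
  if (any(df$evalue < 0)) stop("negative e-value")
  df[need]
}

#' Read a gene-to-GO-term mapping
#'
#' @param tsv_path TSV with columns `gene_id` and `term` (extra columns such
#'   as a namespace are kept but unused).
#' @return Data frame with at least `gene_id` and `term`.
#' @export
read_go_map <- function(tsv_path) {
  df <- utils::read.delim(tsv_path, sep = "\t", header = TRUE,
                          colClasses = "character")
  if (!all(c("gene_id", "term") %in% colnames(df))) {
    stop("GO map must have columns gene_id, term")
  }
  df
}

#' Reverse-complement a nucleotide string
#'
#' Handles the full IUPAC alphabet; used throughout promoter extraction and
#' motif scanning.
#'
#' @param seq A single nucleotide string.
#' @return The reverse complement.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
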