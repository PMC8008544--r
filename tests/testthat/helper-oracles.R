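# Independent oracles, deliberately written apart from the package
# internals: naive recursion and exact rational arithmetic only.

ORACLE_CODE <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- toupper(names(gc))
  gc
})

# --- NG86 brute-force oracle -------------------------------------------

# Synonymous site count of one codon: walk the 9 mutations one by one.
oracle_codon_sites <- function(codon) {
  s <- 0
  for (pos in 1:3) {
    syn <- 0
    tot <- 0
    for (b in c("A", "C", "G", "T")) {
      if (b == substr(codon, pos, pos)) next
      mut <- codon
      substr(mut, pos, pos) <- b
      if (ORACLE_CODE[[mut]] == "*") next  # stops out of the denominator
      tot <- tot + 1
      if (ORACLE_CODE[[mut]] == ORACLE_CODE[[codon]]) syn <- syn + 1
    }
    if (tot > 0) s <- s + syn / tot
  }
  s
}

# All substitution orderings between two codons by explicit recursion.
# Returns a list of c(sd, nd, stop_free) per complete pathway.
oracle_pathways <- function(from, to) {
  diff_pos <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
  if (length(diff_pos) == 0) return(list(c(0, 0, 1)))
  out <- list()
  recurse <- function(cur, remaining, sd, nd, clean) {
    if (length(remaining) == 0) {
      out[[length(out) + 1]] <<- c(sd, nd, as.numeric(clean))
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(to, p, p)
      step_syn <- ORACLE_CODE[[cur]] == ORACLE_CODE[[nxt]]
      recurse(nxt, setdiff(remaining, p),
              sd + step_syn, nd + !step_syn,
              clean && ORACLE_CODE[[nxt]] != "*")
    }
  }
  recurse(from, diff_pos, 0, 0, TRUE)
  out
}

oracle_codon_diffs <- function(from, to) {
  paths <- do.call(rbind, oracle_pathways(from, to))
  keep <- paths[, 3] == 1
  if (any(keep)) paths <- paths[keep, , drop = FALSE]
  c(mean(paths[, 1]), mean(paths[, 2]))
}

oracle_ng86 <- function(seq_a, seq_b) {
  ca <- substring(seq_a, seq(1, nchar(seq_a), 3), seq(3, nchar(seq_a), 3))
  cb <- substring(seq_b, seq(1, nchar(seq_b), 3), seq(3, nchar(seq_b), 3))
  S <- 0
  Sd <- 0
  Nd <- 0
  for (i in seq_along(ca)) {
    S <- S + (oracle_codon_sites(ca[i]) + oracle_codon_sites(cb[i])) / 2
    d <- oracle_codon_diffs(ca[i], cb[i])
    Sd <- Sd + d[1]
    Nd <- Nd + d[2]
  }
  c(S = S, N = 3 * length(ca) - S, Sd = Sd, Nd = Nd)
}

# Random stop-free codon pair for oracle comparisons: start from random
# sense codons and mutate a copy with random base flips, rejecting stops.
make_random_codon_pair <- function(n_codons, n_mut = n_codons) {
  sense <- names(ORACLE_CODE)[ORACLE_CODE != "*"]
  a <- sample(sense, n_codons, replace = TRUE)
  b <- a
  for (m in seq_len(n_mut)) {
    i <- sample.int(n_codons, 1)
    pos <- sample.int(3, 1)
    cand <- b[i]
    substr(cand, pos, pos) <- sample(c("A", "C", "G", "T"), 1)
    if (ORACLE_CODE[[cand]] != "*") b[i] <- cand
  }
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}

# --- promoter motif oracle ---------------------------------------------

# Occurrence count of a literal word in either orientation, fixed = TRUE
# regex machinery only (overlap-safe via lookahead-free stepping).
oracle_count_word <- function(seq, word) {
  count_one <- function(w) {
    n <- 0
    from <- 1
    repeat {
      i <- regexpr(w, substring(seq, from), fixed = TRUE)
      if (i < 0) break
      n <- n + 1
      from <- from + i  # step one past the match start: overlaps allowed
    }
    n
  }
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(word)))
  count_one(word) + if (rc == word) 0 else count_one(rc)
}

# --- hypergeometric oracle ---------------------------------------------

# P(X >= k) by exact binomial-coefficient summation.
oracle_hyper_upper <- function(k, K, n, N) {
  hi <- min(K, n)
  if (k > hi) return(0)
  sum(vapply(k:hi, function(i) {
    choose(K, i) * choose(N - K, n - i)
  }, numeric(1))) / choose(N, n)
}

# --- small fixture builders --------------------------------------------

# A toy genome with one gene; motif occurrences can be planted at given
# TSS-relative positions (promoter coordinates, +1 = TSS base).
make_toy_gene <- function(strand = "+", chrom_len = 6000, tss = 4000,
                          body = 300, seed = 1) {
  set.seed(seed)
  seq <- paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
               collapse = "")
  # scrub accidental E2FAT occurrences
  for (w in c("TTTCCCGCC", "GGCGGGAAA")) {
    while (grepl(w, seq, fixed = TRUE)) {
      i <- regexpr(w, seq, fixed = TRUE)
      substr(seq, i, i + 8) <- paste(rep("A", 9), collapse = "")
    }
  }
  if (strand == "+") {
    model <- gene_model("gX", "c1", "+", tss, tss + body - 1)
  } else {
    model <- gene_model("gX", "c1", "-", tss - body + 1, tss)
  }
  list(genome = c(c1 = seq), model = model)
}

# Overwrite promoter-coordinate positions of a toy gene with a word and
# return the updated genome (mirrors what a planted site looks like).
plant_in_promoter <- function(toy, word, prom_pos, upstream_len = 2000) {
  pr <- extract_promoter(toy$genome, toy$model, upstream_len)
  pseq <- pr$seq
  for (p in prom_pos) {
    substr(pseq, p, p + nchar(word) - 1) <- word
  }
  gseq <- if (toy$model$strand == "+") pseq else revcomp(pseq)
  chrom <- toy$genome[["c1"]]
  substr(chrom, pr$genomic_start, pr$genomic_end) <- gseq
  toy$genome <- c(c1 = chrom)
  toy
}
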