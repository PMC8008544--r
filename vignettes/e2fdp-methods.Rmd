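---
title: "Methods and design notes for the e2fdp pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for the e2fdp pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(e2fdp)
```

This vignette documents the models, parameter choices and numerical
conventions behind each pipeline stage, and states precisely what the
synthetic-data generator does and does not establish.

## Coordinate and promoter conventions

All genomic coordinates are 1-based inclusive (GFF3 convention);
conversions happen only inside sequence slicing. The transcription start
site (TSS) of a gene is the 5′ end of its annotated span by strand —
span start on `+`, span end on `-` — and is position **+1** of the
promoter coordinate system (there is no position 0; the base immediately
upstream is −1).

The promoter window runs from −2000 to +1 and *includes* the TSS base,
so a full window is 2001 nt. This literal reading of the "−2000 bp to
+1 bp" convention is deliberate: it makes the window length an explicit,
testable contract rather than an off-by-one ambiguity. On the `-` strand
the window is the genomic interval `[tss, tss + 2000]`
reverse-complemented, so promoter sequences always read 5′→3′ relative
to their gene. Windows clipped at a contig end carry a `truncated` flag
rather than being dropped.

## Motif scanning

`scan_motif()` performs exact IUPAC matching (Biostrings) of the pattern
against the promoter and, by default, its reverse complement —
transcription-factor binding is double-stranded, so both orientations
count. Two asymmetric conventions are worth stating:

* **Pattern** ambiguity codes expand (`TTTCCNGCC` matches
  `TTTCCCGCC`), supporting degenerate cis-element dictionaries.
* **Subject** ambiguity codes never match: an `N` in the genome is
  absence of evidence, not a wildcard. Hits whose matched sequence
  contains any non-ACGT character are discarded.

The E2FAT site itself (`TTTCCCGCC`) is matched exactly, with no
degenerate positions: only one literal binding sequence is established
for plant E2F/DP, and inventing tolerance would manufacture targets.
Whether a web-service screen of real promoters would allow mismatches or
scan a single strand is unknowable from the outside; exact matching on
both strands is this package's documented convention. Overlapping
occurrences are all reported; `find_target_genes()` then collapses hits
to a gene set (a gene with two sites is one target).

The shipped `default_cre_dictionary()` carries entries named after
commonly surveyed plant elements (ABRE, TGACG-motif, TCA-element,
CAT-box, P-box, GARE-motif, MYB/MYC sites, light-responsive elements),
but the patterns are illustrative single-sequence stand-ins — replace
them for real screens. Following the convention that a counts figure
only shows abundant elements, `count_cres()` drops motifs whose
genome-wide total is not *greater than* `min_total` (default 5) from the
filtered report; the raw table is always returned.

## Family classification

`classify_architecture()` is a pure function of the hit set (input order
never matters). The rules, in order: two non-overlapping DNA-binding
(E2F_TD) hits with no DP domain → **DEL**; DNA-binding plus dimerization
(E2F_DD) → **E2F**; a DP domain → **DP**; any remaining single family
hit → **partial** (truncated architectures, e.g. candidate pseudogenes);
otherwise **unclassified**.

Numerical choices: hits with e-value above `1e-5` are ignored
(config-exposed); duplicate hits of one domain overlapping by ≥ 20% of
the shorter hit are collapsed to the best e-value representative, so
ragged domain boundaries are tolerated without double-counting, and
"duplicated DNA-binding domain" means two hits overlapping by *less*
than that fraction.

Tandem duplication has no universal definition, so `detect_tandem()`
exposes both thresholds: family genes on one chromosome separated by at
most 10 intervening non-family genes **and** at most 200 kb (defaults
chosen from common gene-family-survey practice). A negative finding —
"no tandem duplications" — is only reproducible under a stated rule,
which is why the rule is explicit and configurable.

## Ka/Ks and divergence dating

`ng86_counts()` implements Nei–Gojobori (1986) counting under the
standard nuclear code (no alternative codes):

* **Sites.** Per codon position, the fraction of the three single-base
  changes that are synonymous, with changes to stop codons excluded from
  that position's denominator (standard NG86 practice). S and N are
  averaged over the two sequences; S + N equals the aligned length.
* **Differences.** Codons differing at 2–3 positions are resolved by
  averaging, unweighted, over all substitution orderings that avoid stop
  codons, each step classified synonymous/nonsynonymous. If *every*
  pathway passes through a stop (possible in principle), all pathways
  are used rather than failing — a corner the classic description leaves
  open; it is unreachable for the near-identical paralog pairs this
  pipeline targets.
* **Correction.** Jukes–Cantor: `Ks = −(3/4)·ln(1 − (4/3)·pS)`, likewise
  Ka. When `4/3·p ≥ 1` the corrected value is undefined (saturation) and
  flagged, with raw proportions still returned; tiny alignments can even
  yield pS > 1 (one synonymous difference against a fractional site
  count), which the same flag covers. The Ka/Ks ratio is flagged
  undefined when Ks is 0 or undefined.

Divergence time is `T = Ks/(2λ)` with λ the synonymous substitution rate
per site per year: `6.5e-9` for monocots, `1.5e-8` for dicots (both
shipped as `LAMBDA_RATES`), reported in millions of years. With the
monocot rate, Ks = 0.13 dates a duplicate to 10.0 mya — squarely inside
the 7–12 mya window reported for the Moso bamboo whole-genome
duplication.

Alignment construction is an input, not a stage: the intended use is
near-identical within-genome paralogs, for which equal-length ungapped
CDS pairs (`kaks_table()`) suffice. Gapped columns, when present, are
dropped codon-wise. Maximum-likelihood (GY94-style) estimation is out of
scope.

The test suite checks the implementation against a brute-force oracle
that re-enumerates every substitution pathway by naive recursion — exact
equality on S, N, Sd, Nd over hundreds of random pairs — so the
production path (memoized, per-codon-pair) is never its own referee.

## Coexpression network

An edge `u → v` requires **two** independent pieces of evidence:

1. *Binding*: v's promoter carries u's family binding motif (for E2F/DP
   regulators, the E2FAT site; other TF families may be supplied with
   their own patterns, letting E2F/DP genes appear as targets too).
2. *Coexpression*: Pearson correlation of the raw FPKM profiles with
   `r ≥ +0.90` (activation) or `r ≤ −0.90` (repression).

The threshold is **inclusive on both sides**. Published statements of
such rules often mix `≥`/`>` across figure legends and text; the legend
form (≥ +0.90, ≤ −0.90) is the most precise one and is adopted, with
`inclusive = FALSE` exposed for the strict reading. Correlation is
computed on raw FPKM, not log-transformed values, matching the stated
input of the original screen. Constant profiles make r undefined: the
pair is skipped with a warning rather than guessed. Self-edges are
excluded even when a family member's promoter carries its own motif.

Hubs are ranked by total degree, ties broken lexicographically by gene
id — a deterministic order matters more than any particular tie
philosophy. `tissue_max()` records each gene's condition of maximal
expression (ties: first condition in header order; all-zero genes are
flagged).

## Enrichment

Over-representation only: upper-tail hypergeometric
`P(X ≥ k)` for k annotated targets among n, with K carriers in a
background of N, followed by Benjamini–Hochberg FDR (the conventional
default where the original procedure is unstated). The default
background is every gene with at least one annotation, exposed so "all
genes" can be used instead. GO terms are used exactly as mapped — no
propagation up the ontology graph, since upstream annotation pipelines
differ in whether they pre-propagate and doing it twice inflates counts.

## qRT-PCR and heatmap transforms

`ddct()` implements 2^−ΔΔCt: per sample,
ΔCt = mean Ct(gene) − mean Ct(reference); ΔΔCt subtracts the
calibrator sample's ΔCt; fold = 2^−ΔΔCt. Replicates are averaged on
the Ct scale before differencing — with three technical × three
biological replicates and an unstated aggregation order, averaging
technical replicates first and reporting biological replicates as
separate rows (mean ± sd downstream) is the defensible default, and a
constant Ct shift within a sample provably cancels. Heatmap input is
log2(FPKM + 1); the pseudocount (default 1.0, config-exposed) keeps
zero FPKM at exactly 0 on the log scale.

## The synthetic world

`synth_dataset()` generates, from one seed, a dataset in which every
downstream answer is known exactly:

* **Genome/annotation**: genes on both strands, each owning a
  full-length promoter; background sequence is *purged* of accidental
  E2FAT occurrences by rejection resampling before exactly
  `n_planted_e2fat` sites are planted (positions and orientations
  recorded), and the realization is re-scanned and regenerated if
  planting itself ever creates a junction artifact. Purging rather than
  post-hoc masking keeps the ground truth exact.
* **Expression**: 13 conditions by default, named for a bamboo culm
  developmental series (S1–S7, CK, SS1, SS2, L, R, O). Profiles are
  log-normal (meanlog 2, sdlog 1) to mimic FPKM skew. Edge targets copy
  (or reflect, for repression) their regulator's profile plus Gaussian
  noise (`noise_sd`, default 0.3 on the FPKM scale); at zero noise
  planted correlations are exactly ±1. Negative values after noise are
  clamped at 0.
* **Paralogs**: a copy of a random stop-free CDS receives single-base
  synonymous substitutions, at most one per codon, in numbers chosen by
  inverting the Jukes–Cantor curve (`pS = 3/4(1 − e^{−4Ks/3})`), so the
  NG86 estimate recovers the target Ks to within sampling error; no
  substitution ever creates a stop.
* **GO**: 20 uniform background terms; one term (`GO:0000278`) planted
  on 80% of the target set versus a 5% background rate.

What a green synthetic test **does not** establish: realistic promoter
base composition or motif clustering, linkage between duplicated
regions, read-level noise, dispersion structure of real RNA-seq,
multi-hit codons in paralogs, or annotation incompleteness. The
generator validates the *arithmetic and the gating logic* of every
stage against known truth; it does not validate biological discovery
power on real genomes, and headline counts from any real survey (family
size, target counts, network size) are functions of the genome build
and expression data used, not of this code.

## Determinism and reproducibility

All randomness flows from one seed; generation happens in a fixed order,
so equal seeds give byte-identical files (verified by hash in the
tests). Pipeline runs consume no randomness at all. Every run writes a
manifest listing parameters and the md5 of every output, which is also
how end-to-end determinism is asserted.
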