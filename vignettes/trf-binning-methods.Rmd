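---
title: "Methods: structure-anchored tRF binning and differential abundance"
author: "trfbin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-anchored tRF binning and differential abundance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

tRNA-derived fragments (tRFs) are short (13–32 nt) RNAs released from
mature tRNAs or their precursor transcripts by cleavage at specific but
usually unknown sites. Quantifying them from small RNA-seq therefore
faces a definitional problem: without known cleavage sites there is no
catalogue of fragment coordinates to count against. `trfbin` resolves
this with a *binning* model: each tRNA gene is represented by up to
seven fixed-width genomic intervals anchored on landmarks of the
clover-leaf secondary structure, and a read is attributed to the bin it
covers best. The bin then *is* the tRF unit for all downstream
statistics; no fragment-end assembly is attempted, since read pileups
cannot reliably delineate intact fragment termini.

The seven anchors per gene are:

| label | anchor rule |
|-------|-------------|
| `5-Pre` | ends exactly at the mature 5' boundary (precursor leader) |
| `5tRF` | starts exactly at the mature 5' boundary |
| `D-loop` | centered on the D-loop midpoint |
| `A-loop` | centered on the anticodon-loop midpoint |
| `T-loop` | centered on the TΨC-loop midpoint |
| `3tRF` | ends exactly at the mature 3' boundary |
| `3-Pre` | starts immediately after the mature 3' boundary (trailer) |

A bin is emitted only if it fits: precursor bins need at least one bin
width of flanking sequence inside the contig, and loop bins must not
protrude beyond the mature span. With unconstrained flanks a gene set of
size *G* yields exactly 7 *G* bins; genes near contig edges lose
individual anchors, which is why genome-scale bin counts fall slightly
short of 7 *G*.

Assumptions worth making explicit: the annotated gene span is treated as
the mature span (genomic tRNA annotations exclude the
post-transcriptionally added CCA, and the discriminator base is treated
as mature, so `3-Pre` starts at the first trailer nucleotide); introns
are not spliced (intron-containing tRNAs are excluded upstream); and
tRNA halves (30–35 nt) are outside the fragment-size regime the bins are
tuned for.

## Landmark location

When tRNAscan-SE secondary-structure strings are available, the three
loops are read directly from the string: a loop is a maximal unpaired
run enclosed by a hairpin (an opening pair character 5' of it, a closing
one 3' of it), and the three hairpin loops in 5'→3' order are D,
anticodon and T. Fewer than three resolvable loops is an error, as is an
anticodon that does not lie inside the inferred anticodon loop.

Without a structure string a canonical geometry is used (1-based mature
positions): acceptor stem of 7 bp, D-loop at 14–21, the 7-nt anticodon
loop at 33–39 holding the anticodon at 34–36, T-loop at 54–60. This is
the standard clover-leaf layout of cytosolic tRNAs of 72–76 nt; it is
exact for the synthetic genes this package generates and a serviceable
approximation for real genes of canonical length.

## Tunable parameters

| parameter | default | units | rationale |
|-----------|---------|-------|-----------|
| `window` | 15 | nt | bin width; a sweep over {15, 20, 25, 30, 35} is built in (`window_sweep()`), and 15 maximizes detections when fragments are ~15 nt |
| `flank` | 30 | nt | precursor flank searched on each side; leaders/trailers are short, and 30 nt holds a 15-nt precursor bin with margin |
| `min_overlap` | 10 | nt | read–bin assignment floor; requires a majority of a 15-nt bin to be covered, approximating fragment-of-origin assignment |
| `stranded` | TRUE | – | small-RNA libraries are stranded; antisense hits are not tRFs |
| `min_count`, `min_samples` | 100, 3 | reads, samples | the expression rule: a tRF is "expressed" with **more than** 100 reads in **at least** 3 samples (strict inequality on the count) |
| `trim_m`, `trim_a` | 0.30, 0.05 | – | the standard TMM trim constants for log-ratios and log-abundances |
| `alpha` | 0.05 | – | the significance gate for direction labels |
| `dispersion` | 0.1 | – | simulator NB dispersion (variance = μ + 0.1 μ²), the conventional overdispersion level for bulk RNA-seq-like counts |

Centering tie-break: when `window − loop length` is odd, the loop bin is
shifted one extra base toward the 5' end, so bin placement is
deterministic. All internal coordinates are 0-based half-open; GTF
output is 1-based inclusive.

## Read assignment and counting

Reads are consumed as SAM/BAM (secondary and unmapped records are
flagged and excluded from counting; library size = mapped primary
reads). Each read is assigned to at most one bin: the same-strand bin
with the largest overlap, provided the overlap is ≥ `min_overlap`; ties
go to the smaller genomic start, then the lexicographically smaller bin
id. There is no fractional counting — with near-identical isoacceptor
copies, double-counting ambiguous reads would manufacture correlated
signal. For the same reason the built-in fixture mapper
(`exact_match_map()`) discards multi-hit reads entirely rather than
placing them arbitrarily; it exists so that synthetic FASTQ can be
mapped without an external aligner and is *not* a general-purpose
aligner (exact substring matches only, both strands, unique hit
required).

## Normalization and differential abundance

TMM factors follow the standard definition: the reference sample is the
one whose upper-quartile count fraction is closest to the mean of those
fractions; per sample, bins zero in either the sample or the reference
are dropped, M = log2 ratio of count fractions and A = mean log2 count
fraction are trimmed two-sidedly (30 % on M, 5 % on A by ranks), and the
factor is 2 to the precision-weighted trimmed mean of M with inverse
asymptotic binomial variances as weights, rescaled to geometric mean 1.
The implementation is tested against an independently coded
direct-formula oracle (1e-9) and against `edgeR::calcNormFactors`.

Two-group contrasts pool counts within each group and apply a two-sided
Fisher exact test to `[[k_A, N_A − k_A], [k_B, N_B − k_B]]`, where the
pooled library sizes `N` are TMM-scaled and rounded to integers. Fold
changes use a +0.5 continuity offset on pooled counts so zero counts
produce finite log2 ratios. Benjamini–Hochberg q-values are computed
across the tested bins; direction labels (`up_in_a` / `up_in_b`) are
gated on raw p < α, with q reported alongside rather than used as the
gate, mirroring how pooled Fisher contrasts are conventionally reported
in this literature.

**Known limitation (read before trusting small p-values).** The Fisher
test models sampling noise only. Pooling replicates discards the
between-replicate component of variance, so with overdispersed counts
(NB dispersion 0.1) and deep bins (hundreds of reads) the pooled test is
strongly anticonservative: truly null tRFs frequently cross p < 0.05,
as the package's own recovery tests on simulated data measure. Pooled
Fisher p-values are therefore best read as a *ranking* of effects;
statements about error control need a dispersion-aware model (e.g. an
NB GLM), which is deliberately outside this package's scope. Power for
strong effects (≥ 4-fold at high counts) is essentially 1.

Sex-bias classification is a non-parametric consistency rule, not a
test: a tRF is "Female biased" iff its (normalized) female count
strictly exceeds the male count in *every* strain, "Male biased" in the
mirror case, "inconsistent" otherwise; cross-strain means per sex are
reported with the label. With 5 strains, a direction-consistent pattern
has probability 2·(1/2)⁵ ≈ 6 % under independent coin flips, so the
rule is a reasonable screen but not a calibrated p-value. Reported
means are raw (unrescaled) means of the supplied matrix — callers pass
normalized counts when normalization is wanted.

## Multivariate summaries

*Mutual information.* Pairwise sample dependence is estimated from the
Spearman rank correlation ρ under a Gaussian-copula model: raw MI =
−½·ln(1 − ρ²) (|ρ| clipped at 1 − 1e-12), reported on a normalized
scale 1 − exp(−2·MI) = ρ², which lies in [0, 1], equals 1 on the
diagonal, and is invariant under strictly monotone transforms of either
profile. The normalization to ρ² is this package's documented choice (a
[0, 1] range with unit diagonal admits several normalizations; this one
is the closed form consistent with the Spearman estimator and is
configurable by taking the raw value instead).

*PCA and clustering.* Counts are transformed to log2(normalized count
+ 1) first — bin abundances span about four orders of magnitude and
would otherwise let a single tRF dominate the distances. PCA centers
each bin and decomposes by SVD; component signs are fixed so each
loading vector has a non-negative sum (scores are reproducible across
BLAS implementations). Ward trees use Euclidean distance and `ward.D2`
(the Lance–Williams update on squared distances); merges are verified
against a brute-force Lance–Williams oracle, and tie handling is
deterministic given input order. Trees serialize to Newick via `ape`.
Tanglegram content is exported as two Newick trees (tRFs clustered in
males and in females) plus the numerical comparison — cophenetic
correlation and co-membership agreement at k = 2..4 cuts; graphical
untangling is out of scope.

## The synthetic-data generator

`simulate_genes()` draws tRNA genes with random mature sequences of
72–76 nt in exact canonical geometry (anticodon planted at 34–36,
matching structure strings emitted), places each gene with 30-nt flanks
on a random strand, separates gene cassettes with `N` spacers, flags a
chosen number of genes as pseudogene / selenocysteine / intron-carrying,
and — by default — redraws genes until every k-mer of the minimum read
length is unique genome-wide on both strands, so exact-match mapping is
provably unambiguous. Mature lengths start at 72 nt because the fixed
canonical landmark layout (acceptor stem through T-loop ending at
position 60, plus a 7-bp acceptor arm) needs 72 positions; extra length
becomes an unpaired 3' tail.

`simulate_reads()` draws per-sample, per-tRF counts from a negative
binomial (group mean, dispersion 0.1) and emits each read as an exact
genomic subsequence on the gene strand: 5' end uniform within ±2 nt of
the bin 5' end (imprecise biogenesis), length uniform in 15–21 nt. One
subtlety: a long read from a loop bin adjacent to a mature-end bin could
overlap the neighbour more than its source; such reads are truncated at
the 3' end (never below 15 nt) until the source bin dominates, so the
truth table's drawn counts match assigned counts exactly when background
is zero. Background reads are Poisson-distributed, uniformly placed, and
may fall in spacers or off-plan regions.

What the generator emulates: fragment-length and origin structure,
group-structured overdispersed abundances (sex / stage / treatment
designs), precursor-flank fragments, excluded-gene classes, background.
What it does **not** emulate: sequencing errors and quality variation,
adapter read-through, isoacceptor sequence similarity (unless the
uniqueness check is disabled), post-transcriptional modifications that
stall reverse transcription, and CCA tails. Passing recovery tests on
this generator therefore demonstrates the pipeline's bookkeeping and
statistical behaviour under the stated model, not robustness to real
library artefacts.

## Numerical choices and degenerate inputs

* Pooled TMM-scaled library sizes are rounded to the nearest integer
  before the Fisher test (the test needs integer margins).
* `fisher_pair` relies on the exact hypergeometric two-sided rule
  (probabilities ≤ observed, 1e-7 relative tie tolerance).
* Spearman ρ is clipped at |ρ| = 1 − 1e-12 before the MI log; constant
  profiles are an error rather than silently NA.
* TMM with a sample sharing no nonzero bins with the reference is a
  degenerate-sample error; an all-equal M vector short-circuits to
  factor 1.
* Empty inputs return empty outputs (filters, binning) or explicit
  validation errors (counting with no samples, MI with < 3 shared
  observations).
* All generator output is a deterministic function of the design,
  including its seed; gene drawing uses the seed itself and read
  drawing seed + 1, so the two stages can be regenerated independently.

## Problem sizes used by the test-suite

The shipped tests run the full chain at deliberately small scale —
gene sets of 4–20 (875 and 984 only for annotation/bin arithmetic,
without the k-mer uniqueness pass), read depths of a few hundred per
planned tRF, 20 simulation seeds for the recovery measurements and 100
for the sex-bias consistency estimate. These sizes keep the whole suite
in the low minutes while leaving every code path exercised; all
statistical checks are against frozen oracle values or independent
in-test reimplementations, not against previously recorded outputs of
the package itself.

## Open design points, resolved

* **Flank length** (unstated upstream): 30 nt per side, configurable —
  long enough for a 15-nt precursor bin plus jitter, short enough that
  flanks of neighbouring genes cannot collide in practice.
* **Bin anchoring**: one bin per structural landmark (7 per gene), not a
  sliding tiling; genome-scale bin counts of ≈ 6.99 per gene are what a
  7-anchor scheme with occasional edge drops produces.
* **Discriminator base**: treated as mature; `3-Pre` starts at the first
  trailer base.
* **Raw vs normalized in reports**: sex-bias means are computed on
  whatever matrix is supplied (the pipeline passes normalized counts);
  Fisher contrasts default to TMM-adjusted pooled libraries with a
  `use_tmm = FALSE` escape hatch.
* **Replicate handling**: replicates are pooled within groups before
  testing (the convention the pooled-Fisher approach implies);
  per-replicate dispersion-aware testing is declared out of scope rather
  than half-implemented.
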