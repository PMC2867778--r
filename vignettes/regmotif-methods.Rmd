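---
title: "Models and methods behind regmotif"
author: "regmotif maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind regmotif}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regmotif)
```

# Scope and data model

regmotif is a headless toolkit for connecting DNA motifs to ChIP-style
binding data: interval management and set algebra on *location sets*,
position-weight-matrix (PWM) scoring with exact and sampled match
p-values, whole-sequence enrichment scores, de novo motif discovery by
Gibbs sampling, motif–motif comparison, and enrichment / positional /
spacing / Gene Ontology statistics. Everything operates on plain-text
formats (FASTA, BED, GFF, WIG, motif matrices, MEME minimal format, a
simple alignment-block format, two-column GO TSVs), so analyses are
scriptable and reproducible without a database.

Internally every coordinate is **0-based, half-open**, on the forward
strand; conversions to 1-based formats (GFF, WIG) happen only at file
boundaries. This single-convention rule eliminates whole classes of
off-by-one errors; the test suite verifies that BED `(s, e)` and GFF
`(s+1, e)` are a bijection. Sequences are normalized to `{A,C,G,T,N}`
(lowercase uppercased, `U` to `T`, other IUPAC ambiguity codes to `N`
with a warning). `N` is *unknown*, not *anything*: it never matches a
pattern symbol and any scoring window containing `N` is skipped rather
than scored.

# Motif model and scoring

A motif is a `4 x W` column-stochastic frequency matrix; an *affinity*
motif (as produced by biophysical models) instead stores relative weights
in `[0, 1]` with column maximum 1 and is scored by per-position products.
Frequency motifs are regularized before any log-odds computation:

$$ f'(i, b) = (1 - p)\, f(i, b) + p\, q(b), $$

with background $q$ and pseudo-weight $p = 0.01$ by default. The paper-level
quantity of interest, the LOD score of a word $w$, is
$\sum_i \log_2 \left( f'(i, w_i) / q(w_i) \right)$ — log base 2
throughout, so scores and information content are in bits and logo
heights follow the classic Schneider–Stephens design. The default
background is the order-0 composition of the bound genome (uniform when
no genome is available); backgrounds of order 1–3 are supported where the
Gibbs sampler uses them.

The choice $p = 0.01$ with background-proportional pseudocounts keeps
zero-frequency entries finite while shifting a strong consensus column's
log-odds by under 0.1 bit; it is configurable everywhere it is used.

## Match p-values

The null for a match p-value is a single W-mer drawn i.i.d. from the
order-0 background: `P(score >= t)` per window and strand. Multiple
testing across the windows of a scan is deliberately left to the caller.
Two estimators are provided:

* **exhaustive** — enumerate all $4^W$ words (widths up to 10), exact by
  construction;
* **compound importance sampling** — draw words from the defensive
  mixture $q(w) = \tfrac12 b(w) + \tfrac12 \prod_i f'(i, w_i)$ of the
  background and the PWM-tilted product distribution. The estimator
  averages $b(w)/q(w) \cdot 1\{score \ge t\}$. Because
  $f'(i,b) = q(b)\,2^{s(i,b)}$, the weight collapses to
  $1/(\tfrac12 + \tfrac12\, 2^{score})$, which is bounded by 2 — the
  mixture bounds the variance — while the tilted component concentrates
  samples in the tail where the events live. The reported standard error
  is the sample standard deviation of the weighted indicator over
  $\sqrt{n}$. The tests verify unbiasedness against the exhaustive truth
  over seeded replicates.

## Whole-sequence scores

Two cumulative scores summarize motif content of a full sequence. The
**cumulative LOD** is the sum over all windows on both strands of
$\max(\mathrm{lod} - \mathrm{floor},\, 0)$; "cumulative" is ambiguous in
informal usage, so the positive-part-above-a-floor definition is stated
explicitly and the floor (default 0) is configurable.

The **w-score** is a two-state hidden-process likelihood ratio: at each
step a background state emits one base from $q$, or, with transition
weight $w$, a motif state emits a full W-mer from $f'$. The forward
recursion over prefix likelihoods is

$$ F(i) = (1-w)\, q(x_i)\, F(i-1) + w\, M(x_{i-W+1..i})\, F(i-W), $$

evaluated in log space, and the score is $\log_2 L(\hat w)/L(0)$ with
$\hat w$ fitted by golden-section search on $\log_{10} w \in [-6,
\log_{10} 0.5]$ (tolerance $10^{-6}$; the likelihood is smooth and
unimodal in practice). When the motif equals the background the
recursion telescopes and the score is exactly 0 for every $w$ — a useful
analytic anchor the tests assert. Motif emission is evaluated on the
forward strand; score the reverse complement of the sequence for the
other orientation.

# Gibbs motif discovery

Discovery uses a ZOOPS (zero-or-one occurrence per sequence) Gibbs
sampler. Per restart: one random site per sequence; then repeatedly hold
one sequence out, build $f'$ from the remaining sites (one
background-proportional pseudo-observation in total), and resample the
held-out site among all N-free windows on both strands with probability
proportional to $\prod_i f'(i,b_i) / P_{bg}(word)$, against a no-site
alternative with prior `zoops_prob` (default 0.1 — ChIP regions can lack
a site, and the exact prior in the literature this follows is not fixed,
so it is a parameter). Backgrounds of order 0–3 are supported; order 0
estimated from the input is the default.

Two details matter in practice. First, every 50 sweeps (and during the
final deterministic sweeps) a **column-shift move** tries sliding all
sites by ±1–2 positions and accepts the shift if it raises the
configuration score; plain site-resampling mixes poorly across phase
shifts, and without this move the sampler routinely converges to the
planted motif offset by one or two columns. Second, after the sampling
sweeps, deterministic argmax sweeps run to a fixed point, so the reported
configuration is the predictive-update maximum rather than a random
sample. Restarts (seeded `seed + restart - 1`) are compared by total
information content times the number of sites; for multiple motifs the
winner's sites are masked to `N` and the search repeats. With a fixed
seed the output is reproducible bit for bit.

# Motif comparison

Motif–motif similarity follows the column-alignment approach popularized
by TomTom: for every target, both orientations and all offsets with at
least `min_overlap` columns are scored; the per-column metric is Pearson
correlation of regularized frequency columns (negative Euclidean distance
is available), and the alignment score is the column sum. The null for
one column is the empirical distribution of the metric over all pairs of
distinct columns pooled from the library, discretized into 100 bins; the
null of a k-column sum is the k-fold convolution of that histogram
(dynamic programming over bin indices), and the resulting p-value is
Bonferroni-corrected by the number of alignments tested per target.
Libraries under 10 motifs cannot calibrate the empirical null, so the
Pearson metric falls back to its analytic null — for 4-point vectors the
null correlation is uniform on $[-1, 1]$. A constant column (e.g. an
exactly uniform position) has no shape to correlate and scores 0.

# Interval algebra, gene assignment and peaks

Set operations are **per-base**: the result of union / intersection /
subtraction is the per-base membership set re-assembled into maximal
intervals (record annotations are not propagated; a record-preserving
overlap join is a different operation and out of scope). The
implementation delegates to GenomicRanges/IRanges and is tested against a
naive boolean-vector oracle plus the usual algebraic identities.

Gene assignment is parameterized rather than opinionated: a region is
assigned to a gene when it overlaps the body (distance 0), or lies within
`max_upstream` bp of the strand-aware TSS on the upstream side, or within
`max_downstream` bp past the 3' end. Distances are measured from the
region's nearest edge and an adjacent region has distance 1, so distance
0 is equivalent to overlap. With `allow_multiple = FALSE` only the
nearest gene(s) survive and exact ties keep all tied genes — divergent
promoters report both neighbors.

Peak extraction is deliberately a refinement utility, not a peak caller:
maximal runs of track values at or above a threshold, runs bridged across
gaps of at most `merge_gap` bases, merged runs shorter than `min_width`
dropped; the peak value is the run maximum and the summit is the leftmost
base attaining it (leftmost for determinism).

# Statistics

*Enrichment.* A location "has a match" when any window on either strand
reaches the cutoff; each cutoff yields a 2x2 table tested two-sided by
Fisher's exact test (`stats::fisher.test`, verified against the
hypergeometric closed form). When no control set exists, controls are
dinucleotide-shuffled target sequences (Altschul–Erikson shuffle, exact
dinucleotide counts preserved, seeded). Library-wide runs add
Benjamini–Hochberg q-values across motifs at each cutoff.

*Positional distribution.* Matches are assigned to their nearest anchor
(midpoint distance, ties leftmost); positions are either scaled to
$[0, 1]$ across the anchor span or signed distances to the anchor point.
The primary test is chi-square goodness-of-fit against uniform over 10
equal bins, with Kolmogorov–Smirnov as a secondary readout; the cited
basis for this utility names no formula, so both standard uniformity
tests are implemented and the method is recorded in the result. Fewer
than 10 matches flags the result underpowered.

*Spacing.* Gaps between facing edges of A,B match pairs (self-pairs
excluded when A = B) are binned into windows; the null re-places B's
matches uniformly within their sequences, preserving widths, and the
per-window empirical p-value is $(1 + \#\{null \ge obs\})/(1 + n_{perm})$
— never zero, valid by construction — with BH adjustment across windows.

*GO enrichment.* Annotations propagate to all ancestors (cycles are an
error), each term with a study gene is tested with the hypergeometric
upper tail, and correction is Bonferroni over tested terms, following the
GO-TermFinder convention. The motif-to-GO bridge takes as its study set
the genes whose upstream window (strand-aware, truncated at sequence
edges and, by default, at the nearest neighboring gene — appropriate for
compact genomes) contains a sufficiently strong match.

# Conservation filtering

Alignment blocks pair a reference interval with gapped rows from other
genomes (first row = reference; the degapped reference row must equal the
genome subsequence). A match survives filtering when at least `k`
non-reference rows contain, within the aligned span padded by one motif
width and after gap removal, a window on either strand scoring at least
`score_fraction` times the reference score. Matches outside every block
are dropped by default (strict mode) or kept with `lenient = TRUE`. The
simulator introduces substitutions but no indels, which keeps retention
expectations analytic; gapped parsing is covered by hand-written blocks.

# Synthetic fixtures: what they do and do not show

All tests run on generated data: i.i.d. genomes with a target GC
fraction, sites sampled from motif columns (or consensus) spliced in
without overlap — genome-wide or exactly one per sequence —
triangular-bump ChIP tracks with Gaussian noise, substitution-only
alignments, evenly spaced gene models with a shallow two-level GO DAG.
Every generator is a pure function of parameters and seed, and every
planted structure returns its truth set so recovery is measurable without
re-derivation.

The canonical discovery fixture plants a 10-bp motif with consensus-base
probability 0.95 (about 1.63 bits per column, ~16 bits total) once per
sequence in 20 sequences of 100 bp — a sharp, well-powered regime typical
of a fungal transcription factor with good ChIP data. Passing these tests
shows the algorithms are implemented correctly and calibrated under their
stated nulls; it does not show robustness to the things real data add —
repetitive sequence, composition heterogeneity, correlated noise, indels
in alignments, motif variants — which the fixtures deliberately omit.

# Problem sizes and numerical choices

The shipped test and acceptance runs use 10-kb scan oracles, widths <= 5
for exhaustive enumeration (bit-for-bit against a naive enumerator),
$10^5$ importance-sampling draws, 10 discovery fixtures of 20 x 100 bp
with 4 restarts x 1000 sweeps, 1000 positional-null replicates, 50
spacing-null and 20 planted-spacing replicates at up to 1000
permutations, and exhaustive w-score enumeration for all words of lengths
3–6 plus seeded spot checks at lengths 7–8. These sizes were chosen so
the full suite exercises every claim at tight tolerances while remaining
comfortable to run interactively.

Tie-breaks are deterministic everywhere (leftmost summit, leftmost
anchor, stable rank ordering); every stochastic routine takes an explicit
seed and restores the caller's RNG state; degenerate inputs (empty sets,
empty tracks, sequences shorter than a motif, all-N windows) return empty
results or errors as documented rather than propagating NaN.

# Known limitations

* Match p-values assume an order-0 null; higher-order null distributions
  are not implemented (higher-order backgrounds are available to the
  Gibbs sampler only).
* The w-score fits a single global transition weight; it does not model
  clustering of sites along the sequence.
* Motif discovery is fixed-width ZOOPS; variable-width search, dyads and
  EM refinement are out of scope.
* The comparison null is library-dependent by design (TomTom-style); two
  runs against different libraries are not comparable on p-values.
* Alignment handling assumes blocks are given; the package does not
  compute alignments, and simulated blocks contain no indels.
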