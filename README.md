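# regmotif

Regulatory-genomics analysis of transcription-factor binding data, as an R
package with a command-line front end. It is aimed at people analyzing
ChIP-Seq / ChIP-Chip experiments in compact genomes (yeasts and other
microbes, but nothing is organism-specific): given binding-region calls,
genome sequence and numeric enrichment tracks, it discovers, scores and
validates DNA motifs and connects them back to genes and Gene Ontology
terms — headlessly, on plain-text files, with every stochastic step seeded.

## What it computes

A motif is a position-specific weight matrix `f` (4 x W column
frequencies). After regularization `f'(i,b) = (1-p) f(i,b) + p q(b)`
against a background `q` (default `p = 0.01`), a word `w` scores

    LOD(w) = sum_i log2( f'(i, w_i) / q(w_i) )     [bits]

and a *match* is a genomic window whose score clears a threshold, given
either in bits or as a p-value under the i.i.d. background null —
computed exactly by `4^W` enumeration (W <= 10) or by compound importance
sampling from a defensive background/motif mixture, with a reported
standard error. On top of that core the package provides:

* interval set algebra (union / intersection / subtraction, per-base),
  tri-state curation flags, strand-aware gene assignment, threshold-based
  peak extraction;
* IUPAC degenerate-pattern search and direct / inverted repeat search;
* whole-sequence motif scores: cumulative LOD and a two-state HMM
  likelihood-ratio (w-score);
* de novo motif discovery with a ZOOPS Gibbs sampler (phase-shift moves,
  order-0..3 backgrounds, multi-motif masking, bit-reproducible);
* TomTom-style motif–motif comparison against a library with a
  convolution-based combined p-value;
* motif enrichment at incremental cutoffs (Fisher exact, BH across a
  library, dinucleotide-shuffled controls when none are supplied),
  positional-distribution and spacing statistics, and GO-TermFinder-style
  term enrichment with ancestor propagation;
* conservation filtering of matches against multiple-genome alignment
  blocks (phylogenetic footprinting);
* a synthetic-fixture generator (genomes, planted sites, ChIP-like
  tracks, alignments, gene models and GO annotations) so everything runs
  and is testable with no external data.

I/O covers FASTA, BED (3–6 col), GFF, WIG (fixedStep/variableStep), a
bit-exact motif matrix format, MEME minimal format, BioProspector-style
output, and a simple alignment-block text format. Internal coordinates
are 0-based half-open everywhere; `N` never matches anything.

## Worked example

Plant a sharp 10-bp motif (consensus `TTGACGTCAA`, ~16 bits) once in each
of twenty 100-bp random sequences, rediscover it, and scan with a p-value
threshold:

```r
library(regmotif)

truth <- motif(local({
  ch <- strsplit("TTGACGTCAA", "")[[1]]
  mat <- matrix(0.05/3, 4, 10, dimnames = list(c("A","C","G","T"), NULL))
  for (j in seq_along(ch)) mat[ch[j], j] <- 0.95
  mat
}), name = "planted")

g  <- make_genome(100, gc = 0.5, seed = 7, n_sequences = 20)
pl <- plant_sites(g, truth, 1, seed = 8, scatter = "per_sequence")

cfg <- gibbs_config(width = 10, iterations = 1000, n_restarts = 4, seed = 5)
fit <- gibbs_discover(unname(unclass(pl$genome)), cfg)[[1]]
fit$motif
#> Motif: gibbs_w10 | frequency | width 10
#>   [,1] [,2] [,3] [,4] [,5] [,6] [,7] [,8] [,9] [,10]
#> A    0    0 0.10 0.90    0 0.05    0    0 0.95  0.90
#> C    0    0 0.00 0.00    1 0.00    0    1 0.00  0.00
#> G    0    0 0.85 0.05    0 0.95    0    0 0.00  0.05
#> T    1    1 0.05 0.05    0 0.00    1    0 0.05  0.05
```

The sampler recovers the planted matrix (consensus `TTGACGTCAA`, one site
per sequence, score = total information content x 20 sites = 351.8).
Score it back against the sequences:

```r
bg <- background(pl$genome)
ps <- to_pssm(fit$motif, bg)
ps$max_score                       # 19.23 bits for the optimal word
tail_prob(score_distribution(ps, "exhaustive"), 12)$p
#> 1.26e-05                         # P(random 10-mer scores >= 12 bits)

hits <- scan_motif(pl$genome, ps, threshold = 1e-4, threshold_type = "pvalue")
head(as.data.frame(hits)[c("sequence_id", "start", "end", "strand", "value")], 3)
#>   sequence_id start end strand    value
#> 1          s1    42  52      - 19.23092
#> 2          s1    42  52      + 19.23092
#> 3         s10    34  44      - 19.23092
```

38 matches at p <= 1e-4 cover all 20 planted sites — the motif is a
near-palindrome, so each site is reported on both strands at the same
coordinates. From here `motif_enrichment()`, `positional_distribution()`,
`spacing_analysis()`, `filter_conserved()` and `motif_go_association()`
take the same objects onward; see the methods vignette
(`vignettes/regmotif-methods.Rmd`) for the models behind each.

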