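Package: regmotif
Title: Genomic Interval Algebra and DNA Motif Analysis for ChIP Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless toolkit for regulatory-genomics analysis of
    transcription-factor binding data. Provides genomic-interval management
    and set algebra on location sets, strand-aware gene assignment and
    threshold-based peak extraction; position-weight-matrix motif models
    with log-odds (LOD) and affinity scoring, exact and compound
    importance-sampling match p-values, cumulative LOD and HMM-based
    w-scores; de novo motif discovery by Gibbs sampling with a ZOOPS site
    model; motif-motif comparison against a library; motif enrichment,
    positional-distribution, spacing and Gene Ontology term statistics;
    IUPAC degenerate-sequence and direct/inverted repeat search;
    conservation filtering of motif matches against multiple-genome
    alignment blocks; and a synthetic-fixture generator so every analysis
    can be exercised without external data. Readers and writers are
    included for FASTA, BED, GFF, WIG, motif matrix/MEME/BioProspector
    formats and a simple alignment-block text format.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
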