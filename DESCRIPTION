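Package: motifdisruptr
Title: Transcription Factor Binding Site Disruption Scoring for SNVs and Indels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores single-nucleotide variants, multi-nucleotide variants and
    short insertion/deletion variants against transcription factor position
    weight matrices. For each (variant, motif) pair the best match on the
    reference and alternate allele sequences is found over both strands, with
    exact match p-values computed by dynamic-programming convolution of the
    per-position score distribution under an i.i.d. background. Motifs over
    indels are located in an edge-relative coordinate system with explicit
    overlap geometry classes. Disruption calls can be annotated with
    overlapping transcription factor ChIP-seq peaks from a locally built,
    ReMap2022-layout BED peak database, and exported as TSV, SQL, or
    color-ramped BED9 browser tracks. A seeded synthetic fixture generator
    produces toy genomes, motif libraries, variant sets and peak files for
    hermetic testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
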