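Package: TUfinder
Title: Transcription Unit Inference from Strand-Specific RNA-seq Coverage
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers condition-dependent bacterial transcription units (TUs)
    from strand-specific RNA-seq coverage. Builds per-base, per-strand read
    abundance tracks from mapped reads, derives consecutive same-strand gene
    pairs from a genome annotation, constructs training data automatically
    (gap/fold-change negatives, spanning-read positives, and pseudo gene
    pairs carved out of single genes at GC-minimal positions), extracts
    expression continuity and variance features at each gene junction,
    classifies junctions with a radial-basis support vector machine, and
    assembles maximal runs of co-transcribed genes into TUs. Includes
    evaluation utilities (long-read confirmed TUs, junction sensitivity,
    TU-set similarity, sequencing-depth resampling, inside/outside-TU
    intergenic expression contrast) and a seeded simulator of strand-specific
    bacterial transcriptomes with known TU structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    Rsamtools,
    e1071,
    pROC,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Transcriptomics, GenePrediction, Classification, Coverage,
    Sequencing
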