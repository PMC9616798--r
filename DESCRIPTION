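Package: nanodam
Title: DamID and NanoDam Binding-Profile Processing, Consensus Peak
    Calling and Combinatorial Binding Clustering
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for processing DamID-seq and NanoDam data from GATC
    fragment maps and per-sample read counts through normalised log2
    binding profiles, Poisson broad-peak calling with consensus merging
    and occurrence filtering, combinatorial transcription-factor binding
    clustering with silhouette-guided k selection, nearest-TSS and
    transcription-factor annotation, and a replicate quality-control
    suite (binned correlations, ROC-like peak recovery, signal
    enrichment meta-profiles, fingerprint curves). Includes a synthetic
    data generator that plants binding archetypes with negative-binomial
    count noise so every pipeline stage can be validated against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    cluster,
    jsonlite,
    yaml,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Epigenetics, PeakDetection, Clustering, QualityControl,
    Sequencing, Software
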