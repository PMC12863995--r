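Package: cloneComp
Title: Clonal Composition Analysis of Tumors from SNP-Array BAF/log2R Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the number of coexisting copy-number-defined subclones
    (the Clonal Composition, CC, number) in a tumor specimen from SNP-array
    B-allele-frequency (BAF) and log2-ratio (log2R) signals. Probe-level data
    are segmented, each copy-number-aberrant segment is assigned an
    allele-specific copy state and a cellular fraction by joint BAF/log2R
    grid fitting, fractions are clustered, and clusters passing a genomic
    footprint threshold are counted to give the CC number and a Mono-CC
    versus Poly-CC classification. Includes a clonal-architecture simulator
    that renders ground-truth clone mixtures into noisy OncoScan-style probe
    data, and the cohort-level statistics used to relate clonal complexity
    to outcome in diffuse large B-cell lymphoma (Fisher exact tests,
    rank tests, Kaplan-Meier, log-rank, Cox models, and a
    minimum-detectable-hazard-ratio power computation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    survival,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: CopyNumberVariation, Software, Survival
RoxygenNote: 7.3.3
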