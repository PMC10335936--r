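Package: repeatscope
Title: Assembly Validation and Repeat-Architecture Analysis for
    Telomere-to-Telomere Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational procedures for validating gapless
    telomere-to-telomere genome assemblies and dissecting their repeat
    architecture: mapped k-mer base-accuracy (QV) and completeness
    estimation, long-read artifact classification (proper, fused,
    symmetrical) with binned-depth coverage-anomaly calling, sliding-window
    satellite and transposable-element array calling, position-probability-
    matrix variant distances and higher-order-repeat grouping of satellite
    monomers, variant-site selection and genotype assignment across tandem
    rDNA copies with orientation and inversion profiling, and landmark
    calling for telomeres, subtelomeres and CENH3-defined centromeres.
    Ships a synthetic miniature-genome generator with planted truth so every
    stage can be exercised end-to-end against a known answer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
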