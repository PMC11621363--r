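Package: xcitools
Title: Sex-Specific Chromatin Accessibility Scanning and Allele-Specific
    X-Inactivation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying X chromosome inactivation (XCI) and
    sex-specific chromatin accessibility in F1 hybrid mice. Implements a
    genome-wide sliding-window binomial scanner that scores
    female-versus-male ATAC-seq peak density, an allelic-ratio engine for
    biallelic (maternal/paternal) read counts with the coverage filters and
    ratio thresholds used for imprinted and random XCI analysis, a
    single-cell active-X classifier with pseudobulk escape-gene detection,
    and downstream arithmetic for differential-expression overlaps,
    direction concordance, TPM normalisation and phenotype tallies. A
    synthetic-data module generates all pipeline inputs (peak sets, bulk and
    single-cell allele counts, DE tables) with ground-truth labels so every
    stage can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
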