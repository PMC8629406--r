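Package: clonehet
Title: Multi-Region Tumor Heterogeneity Analysis and Clonal Evolution
    Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of regional and temporal intra-tumor heterogeneity
    from multi-biopsy targeted deep-sequencing of epithelial ovarian
    cancer. Harmonizes somatic calls from paired variant callers against a
    matched blood sample, applies coverage and allelic-fraction filters,
    partitions variants into shared, concordant and private classes,
    computes mutational burden and per-gene/per-pathway heterogeneity
    statistics, clusters samples on allelic fractions, builds per-patient
    neighbor-joining phylogenies rooted on an unrelated control, compares
    single-base substitution spectra before and after chemotherapy, and
    ships a forward clonal-evolution simulator with ground truth so every
    stage can be validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    seqinr,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
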