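Package: oligoburden
Title: Rare-Variant Collapsing Burden and Oligogenic Enrichment Analysis for
    Case-Control Exome Cohorts
Version: 0.1.0
Authors@R:
    person("DISCO", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for gene-based rare-variant association in
    case-control exome studies: qualifying-variant selection by internal and
    external minor allele frequency, consequence class and gene panel;
    per-gene collapsing (carrier) burden tests with Pearson chi-square and
    Fisher's exact inference; screening of known disease genes;
    per-individual mutational-burden comparison; and detection and
    enrichment testing of oligogenic (multi-gene) carriers. Includes a
    seeded cohort simulator with planted per-gene carrier rates and
    enrichment odds so that type I error and power of the whole pipeline
    can be measured, plus a command-line interface and deterministic
    report assembly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    tools,
    utils
Suggests:
    BiocGenerics,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
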