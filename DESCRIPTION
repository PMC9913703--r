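Package: osap
Title: Derivation, Scoring and Cohort Refinement of an Oxidative Stress
    Adaptation Gene Signature
Version: 0.1.0
Authors@R:
    person("OSAP", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for deriving a core gene-expression signature from
    multi-condition cell-line contrasts by fold-change intersection,
    scoring it per sample with a from-scratch single-sample GSEA
    (ssGSEA) rank-weighted running-sum engine, refining it across
    independent patient cohorts by directional Wilcoxon rank tests with
    Hodges-Lehmann shift estimates, and running downstream association
    statistics (Mann-Whitney, Kruskal-Wallis, Spearman, hierarchical
    clustering, PCA). Includes expression-matrix input/output (GCT 1.2,
    TSV, GMT), quantile normalization, probe collapsing, a planted-signal
    expression simulator for cell-line and patient-cohort designs, and a
    reproducible end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse,
    withr
Config/testthat/edition: 3
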