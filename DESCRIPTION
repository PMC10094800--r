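Package: coagnet
Title: Differential Correlation Networks and Clustering for Four-Group
    Hemostasis and Plasma Proteomics Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical analysis pipeline for a four-group clinical cohort
    combining targeted plasma proteomics with functional coagulation assays
    (rotational thromboelastometry, thrombodynamics, impedance aggregometry,
    coagulation labs). Provides serostatus-based group assignment,
    nonparametric group contrasts (Mann-Whitney, Fisher exact, chi-square)
    with Benjamini-Hochberg FDR control and critical values, pairwise-deletion
    Spearman and partial correlation matrices, Fisher-z differential
    correlation testing and network construction, k-medoids clustering of
    parameters with gap-statistic model selection, nonparametric power and
    sample-size calculations, and a Gaussian-copula synthetic cohort
    generator with planted ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    cluster,
    MASS,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
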