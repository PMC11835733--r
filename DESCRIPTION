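Package: bmiprofiles
Title: Probabilistic Profiling of BMI-Biomarker Discordance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Identifies subgroups of individuals whose cardiometabolic
    biomarkers depart systematically from the values expected for their
    body-mass index. Biomarkers are residualized against BMI with age and
    smoking adjustment, multivariate discordance is scored with Mahalanobis
    distances, and discordant phenotypes are partitioned with a
    nearest-neighbour graph, Leiden community detection and a fixed-moment
    Gaussian mixture that yields per-individual profile probabilities.
    Includes cross-cohort profile replication, probability-weighted
    epidemiological estimates with meta-analysis, compositional log-contrast
    Cox models quantifying the added predictive value of the profiles for
    cardiovascular events and diabetes, decision-curve analysis, and a
    synthetic cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    mvtnorm,
    igraph,
    RANN,
    survival,
    glmnet,
    metafor,
    sandwich,
    jsonlite
Suggests:
    uwot,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
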