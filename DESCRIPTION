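Package: dscascade
Title: Biomarker Cascade Ordering and GFAP Mediation in Down Syndrome Alzheimer's Disease
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for ordering Alzheimer's disease biomarker
    changes in adults with Down syndrome relative to sibling controls:
    amyloid/tau (A/T) pathology-group comparisons of plasma GFAP and
    pTau-217 with Wilcoxon rank-sum tests and Hodges-Lehmann shift
    estimates, penalized cubic-regression-spline trajectory fits with
    bootstrap estimation of the age at which each biomarker diverges from
    controls, and covariate-adjusted causal mediation quantifying the share
    of the amyloid-tau association carried by plasma GFAP. Includes a
    seeded synthetic-cohort generator with a known amyloid-GFAP-tau causal
    structure so every stage is testable without restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
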