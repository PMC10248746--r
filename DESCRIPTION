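Package: abxgvhd
Title: Time-Dependent Antibiotic Exposure and Acute GVHD Under Competing
    Risks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates associations between interval-coded, time-dependent
    antibiotic exposures and acute graft-vs-host disease (aGVHD) after
    allogeneic hematopoietic cell transplantation, treating death without
    aGVHD as a competing risk. Implements three complementary estimators:
    a weighted partial-likelihood engine for proportional hazards with
    time-dependent covariates and Fine-Gray inverse-probability-of-
    censoring extension, together with an AIC-guided backward-elimination
    procedure that merges adjacent exposure intervals; a marginal
    structural model with stabilized inverse-probability-of-treatment
    weights built from pooled per-day logistic treatment models; and a
    shadow-feature (Boruta-style) random-forest selector using out-of-bag
    permutation importance. A seeded discrete-time simulator generates
    allo-HCT-like cohorts with known ground-truth effects for calibration
    and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    randomForest,
    stats,
    survival,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
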