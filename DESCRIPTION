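Package: prsbench
Title: Standardised Benchmarking of Polygenic Risk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A standardised evaluation pipeline for per-individual polygenic
    risk scores (PRSs). Given cohort, score, phenotype and carrier tables it
    produces like-for-like performance reports: per-SD odds, hazard and linear
    effect sizes with covariate adjustment, AUC, Kaplan-Meier cumulative
    incidence stratified by PRS percentile band, paired-bootstrap comparison
    of competing scores, ancestry, age and sex stratification, equivalence of
    polygenic and rare-variant carrier risk, and multi-PRS all-cause mortality
    models on participants' own and parental lifespans. A seeded synthetic
    cohort generator emulating an ancestry-stratified biobank testing subgroup
    makes every analysis testable without access to individual-level biobank
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
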