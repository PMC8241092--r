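Package: sicstrat
Title: Shock Index-C Risk Stratification and Validation Pipeline for STEMI Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the Shock Index-C (SIC) risk score -- shock index times
    100 minus estimated creatinine clearance -- for cohorts of ST-segment
    elevation myocardial infarction (STEMI) patients undergoing percutaneous
    coronary intervention, and provides a validation toolkit for clinical
    risk scores: empirical ROC curves with DeLong variance and paired DeLong
    AUC comparison, Youden-optimal cutoffs, Hosmer-Lemeshow calibration,
    continuous net reclassification improvement and integrated discrimination
    improvement with bootstrap intervals, decision-curve analysis,
    Kaplan-Meier/log-rank/Cox survival analysis, and a seeded synthetic
    cohort generator for fully reproducible end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
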