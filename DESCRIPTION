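Package: liverplanr
Title: Virtual Hepatectomy Planning and Post-Operative Liver Performance Scoring
Version: 0.1.0
Authors@R: person("HepaTools", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Landmark-based Couinaud segmentation of delineated liver volumes,
    virtual hepatectomy with future-liver-remnant estimation (anatomical
    segmentectomies and conical-frustrum wedge resections), summarisation of
    quantitative MRI maps (cT1, proton density fat fraction) over the
    parenchyma, post-operative morbidity scoring (daily and five-day-summed
    modified Hyder-Pawlik scores, day-3 Hyder-Pawlik score), a composite
    FLR+cT1 risk score with regeneration scoring, and the associated
    statistical evaluation (stepwise-AIC logistic regression, ROC analysis
    with DeLong comparison, Youden thresholds, rank tests). Includes analytic
    phantoms and a synthetic cohort generator so the full pipeline runs
    without clinical data, plus a minimal NIfTI-1 reader/writer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
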