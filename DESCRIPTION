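Package: rdmprec
Title: Personalized Action Recommendations for Remote Diabetes Monitoring
    Programs via Doubly Robust Uplift Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates per-member heterogeneous treatment effects of five
    engagement action categories (coaching, glucose monitoring, physical
    activity, nutrition, educational content) on change in estimated A1c
    within a remote diabetes monitoring program, using a doubly robust
    learner with cross-fitted nuisance models. Includes a synthetic cohort
    generator with known ground-truth effects and confounded engagement,
    engagement-threshold treatment assignment with a threshold sweep,
    uplift / cumulative-gain / AUUC model evaluation against random-ranking
    baselines, and an argmin-CATE action recommendation policy with
    matched-versus-unmatched outcome analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xgboost,
    ranger,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
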