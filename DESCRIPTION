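Package: affimpute
Title: Self-Training Imputation for Pose-Level Binding Affinity Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for structure-based receptor-ligand binding affinity
    regression on pose-level docking corpora in which most pocket-ligand
    complexes lack experimental affinity labels. Implements a dual-head
    (pose score + affinity) training objective with a hinged pseudo-Huber
    affinity loss, balanced pocket-stratified minibatch sampling, a small
    feed-forward reference learner trained by SGD, eight ensemble
    imputation schemes for missing affinity labels, the iterative
    train-impute-retrain loop, and the evaluation and significance
    machinery (top-pose selection, RMSE/Pearson R/R-squared/AUC/Top1,
    bootstrap confidence intervals, t-tests, and bootstrap RMSE
    comparison). A seeded synthetic-corpus generator emulating the
    statistical structure of large cross-docking datasets makes the whole
    pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0), pROC
Config/testthat/edition: 3
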