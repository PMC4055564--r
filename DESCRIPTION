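Package: cgbnet
Title: Conditional Gaussian Bayesian Networks for Mixed-Data Phenotype Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learning and exact inference in conditional Gaussian Bayesian
    networks over mixed discrete and continuous variables, aimed at predicting
    a discrete (case/control) phenotype from, e.g., multimodal omics data.
    Provides Bayesian marginal-likelihood family scores (BDeu for discrete
    children, conjugate normal-inverse-gamma scores for continuous children),
    four structure-search algorithms (K2 ordered search, greedy exhaustive
    hill-climbing, phenotype-centric Markov-blanket search, simulated
    annealing), Bayes-factor variable filtering, exact posterior prediction,
    ROC/AUC machinery with convex hull, DeLong confidence intervals and paired
    tests, stratified cross-validation with prior-hyperparameter tuning,
    bootstrap edge-frequency estimation with consensus-network construction,
    a forward-sampling network simulator with equal-width discretization, and
    readers/writers for delimited mixed tables, PED genotype files and
    TGF/SIF/GraphML network exchange formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
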