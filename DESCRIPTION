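Package: cnnforest
Title: Random Forests over Convolutional Network Features for Two-Class
    Medical Image Cohorts
Version: 0.1.0
Authors@R:
    person("cnnforest", "maintainers", email = "maintainers@cnnforest.dev",
           role = c("aut", "cre"))
Description: An ensemble classifier for two-class grayscale image cohorts
    (motivated by cardiac magnetic resonance screening for coronary artery
    disease) in which several lightweight convolutional networks, trained on
    disjoint subsets of each cross-validation training fold, convert images
    into a small numeric feature matrix over which a from-scratch random
    forest of Gini-driven decision trees is grown.  Includes patient-grouped
    stratified k-fold cross-validation, an equal-epoch-budget single-network
    baseline, a synthetic lesion-cohort generator for fully offline testing,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    jpeg,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
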