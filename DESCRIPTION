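Package: beliefstate
Title: Bayesian Belief-State Modelling of Restless Bandits with
    Multivoxel and Pupillometric Readouts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how uncertainty (entropy) in a probabilistic
    model of environment state is computed, read out from multivoxel activity
    patterns, and coupled to pupil-linked arousal signals. Implements a
    normative Bayesian ideal observer with a uniform leak for a restless
    four-armed bandit, explore/exploit behavioural segmentation, synthetic
    generators for trial-wise voxel patterns, univariate signals and pupil
    traces, pupillometry preprocessing, a cross-validated multinomial
    decoding pipeline yielding a log-odds representation-strength statistic
    (with searchlight mapping and a voxel-shuffle bias check), a trial-wise
    regression suite with group-level tests and cluster-mass permutation
    correction, and exact noncentral-t power calculations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    nnet,
    glmnet,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
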