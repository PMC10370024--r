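Package: erptfpca
Title: Time-Frequency PCA of Feedback-Locked ERPs with Synthetic Gambling-Task Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates gambling-task cohorts with feedback-locked EEG epochs
    (delta-band reward positivity, mediofrontal theta burst, 1/f noise, blink
    artifacts), preprocesses them (baseline correction, ocular regression,
    amplitude-based artifact rejection, condition-averaged ERPs), transforms
    band-filtered ERPs to time-frequency energy surfaces with a binomial
    reduced interference distribution, decomposes the surfaces by
    covariance-matrix PCA with varimax rotation to separate a delta-band
    reward-positivity component from a theta-band feedback-related-negativity
    component, scores components at designated sensors, computes risky-choice
    behavior, and relates scores and behavior to clinical covariates through
    robust linear mixed-effects models with small-sample degrees of freedom.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    lme4,
    lmerTest,
    pbkrtest,
    MASS,
    rhdf5,
    jsonlite,
    yaml,
    digest,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
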