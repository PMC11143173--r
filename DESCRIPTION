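Package: speechdcm
Title: Dynamic Causal Modeling of Audiovisual Speech Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Effective-connectivity analysis of audiovisual (McGurk) speech
    perception over a four-region left-hemisphere network (precentral gyrus,
    posterior and mid superior temporal gyrus, fusiform gyrus). Builds a
    factorial space of 44 bilinear dynamic causal models in 7 families,
    simulates region-level BOLD through a Balloon-Windkessel observation
    model, inverts models with a variational-Laplace scheme, performs
    random-effects Bayesian model selection with family-level inference and
    Bayesian model averaging, scores McGurk susceptibility from trial-level
    syllable reports, and relates subject-specific coupling strengths to
    behavior with covariate-adjusted, FDR-controlled statistics. A synthetic
    cohort generator provides complete study-shaped datasets so that every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    Matrix,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
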