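Package: choicesel
Title: Hierarchical Bayesian Discrete-Choice Resource Selection for
    Nest Sites and Postfledging Birds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits multinomial-logit discrete choice (conditional logit)
    resource-selection models to used-versus-available choice sets of
    habitat locations, in a Bayesian framework.  Supports a pooled model
    for nest-site selection and a hierarchical random-coefficient model
    for repeatedly observed postfledging juveniles, in which
    individual-level coefficients arise from stage-specific normal
    population distributions.  Includes a synthetic choice-set generator
    with known ground truth, an adaptive Metropolis-within-Gibbs sampler
    with split-chain Gelman-Rubin diagnostics, and posterior summaries:
    credible intervals, directional confidence (f), selection ratios
    exp(beta), Estrella's pseudo R-squared, and relative
    probability-of-use curves.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    coda,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
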