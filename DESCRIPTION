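Package: cstmc
Title: Hierarchical Bayesian Continuous-Time Markov Models for Vaginal
    Community State Type Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models transitions among pooled vaginal microbiota community
    state types (optimal, sub-optimal, non-optimal) observed as irregular
    longitudinal panel data. Transition intensities follow a proportional
    hazards form with participant-level random effects in a non-centred
    parameterisation; interval transition probabilities are matrix
    exponentials of the intensity matrix, with antibiotic episodes handled
    as piecewise-constant time-varying covariates. Includes covariate
    screening and transformation, chained-equation multiple imputation,
    an adaptive MCMC engine with rank-normalised convergence diagnostics,
    posterior summaries (persistence, sojourn times, hazard-ratio
    direction probabilities, counterfactual prevalence, individual
    variability), and a model-faithful synthetic cohort generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    Matrix,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
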