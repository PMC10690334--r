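Package: mcffhbm
Title: Trial-by-Trial Perceptual Learning Curves via Hierarchical Bayesian
    Modeling of a Multi-Component Functional Form
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative modeling and Bayesian inference for trial-by-trial
    contrast-threshold learning curves in adaptive (staircase) perceptual
    learning experiments. The learning curve is decomposed into a
    multi-component functional form (MCFF): log-linear general learning,
    between-session forgetting steps, a within-session rapid-relearning elbow,
    and a within-session adaptation ramp, linked to binary two-alternative
    forced-choice responses through a Weibull psychometric function. Provides
    three inference procedures -- an independent per-subject Bayesian inference
    procedure (BIP) and two three-level hierarchical Bayesian models with
    variance (HBMv) or full covariance (HBMc) hyperparameters -- implemented as
    Gibbs-within-Metropolis MCMC, together with an accelerated
    stochastic-approximation staircase simulator, hierarchical population
    simulation, Bayesian predictive information criterion (BPIC) model
    comparison, learning-curve posterior summaries (68.2% half-width credible
    intervals), group-level MANOVA/LDA statistics, partial-data learning-curve
    prediction, and a command-line workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo: Rcpp
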