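# mcffhbm

Trial-by-trial estimation of perceptual learning curves by hierarchical
Bayesian modeling of a multi-component functional form (MCFF).

## What this package is for

Adaptive (staircase) perceptual-learning experiments produce thousands of
binary two-alternative forced-choice (2AFC) responses per observer across
daily sessions. Aggregating them into blocks hides the fast dynamics —
between-session forgetting, rapid relearning at the start of each session,
within-session adaptation. `mcffhbm` models the log10 contrast threshold on
every trial as a sum of four latent component processes,

ξ(t) = b − γ·log10(t) + δ_s + max(−d_s, −τ·t′) + φ·t′,

(general learning, forgetting step, relearning elbow, adaptation ramp; t′ is
the within-session trial index), links ξ(t) to the binary responses through
a Weibull psychometric function (guessing rate 0.5, lapse rate 0.04, slope
β, threshold anchored at the 2AFC accuracy for d′ = 1.5, p = 0.856), and
estimates the posterior of the K-dimensional parameter vector θ (K = 2, 6 or
14) by MCMC under three procedures:

* **BIP** — each subject fit independently with uniform priors and β = 2;
* **HBMv** — a population → subject → test Gaussian hierarchy with variance
  hyperparameters per dimension;
* **HBMc** — the same hierarchy with full covariance matrices and Wishart
  priors on their inverses (df = K + 1), capturing correlations between
  components within and between subjects.

On top of the fits: BPIC model comparison, per-trial posterior mean curves
with 68.2% half-width credible intervals (HWCI), group-level posteriors with
MANOVA/LDA separation statistics, and prediction of a subject's full
learning curve from 0, 1 or 2 sessions of their data. A simulator
reproduces the motivating six-group staircase design (65%/85%/mixed
accuracy, 6 × 320 trials, optional pre-training) so the entire pipeline is
testable end to end without access to the original raw data.

It is aimed at psychophysicists and computational modelers who have
trial-level staircase data (or want to plan such studies by simulation).

## Worked example

```r
library(mcffhbm)

# one simulated observer: 6 sessions x 320 staircase trials at 85% accuracy
s <- session_structure(n_sessions = 6, trials_per_session = 320)
truth <- mcff_params(c(-1, -0.6), K = 2)   # gamma = 0.1, b = -0.25
set.seed(42)
sim <- simulate_subject(truth, s, condition = "high")
mean(sim$trials$response)
#> [1] 0.8822917

# posterior for this subject under the independent-subject procedure (BIP)
cfg <- sampler_config("bip", n_chains = 2, kept_samples = 400, thin = 2,
                      burn_in = 400, adaptation = 400, seed = 1)
post <- fit_bip(sim$trials, prior_bounds(2), cfg, s)
post
#> MCFF posterior (BIP, K = 2): 2 chains x 400 kept samples x 2 parameters
#> max between/within variance ratio: 1.06 (NOT converged)
round(colMeans(theta_draws(post)), 3)
#> theta1 theta2
#> -0.785 -1.410

# trial-by-trial learning curve with 68.2% half-width credible intervals
curve <- curve_posterior(theta_draws(post), s)
round(curve[c(1, 320, 1920), ], 3)
#>      trial session   mean  hwci
#> 1        1       1 -0.056 0.040
#> 320    320       1 -0.468 0.011
#> 1920  1920       6 -0.596 0.011
```

Reading the output: the realized accuracy (88.2%) sits near the staircase's
85% target. The posterior mean of θ = (log10 γ, log10(−b)) looks far from
the generating (−1, −0.6) — that is the γ–b ridge at work: with staircase
data the late curve is tightly determined (at trial 1,920 the estimated
log10 threshold −0.596 carries an HWCI of only 0.011 log10 units, against a
true value of −0.578), while the trial-1 intercept is informed by only a
handful of early trials and its uncertainty (HWCI 0.040, with the ridge
trade-off folded into the two marginals) is honestly wide. The flagged
variance ratio of 1.06 sits just above the 1.05 convergence threshold —
a longer schedule (the default is 5,000 kept samples with thinning 10)
settles it. Joint fits work the same way through `fit_hbmv()` /
`fit_hbmc()` on a multi-subject trial table (see
`simulate_population()`), and `bpic()`, `group_posterior()`,
`manova_groups()`, `lda_groups()` and `predict_curve()` consume the fitted
posteriors.

A command-line workflow covering `simulate → fit → summarize → predict` is
installed at `inst/cli/mcffhbm.R`:

```sh
Rscript inst/cli/mcffhbm.R simulate --spec sim.cfg --seed 7 --out data/
Rscript inst/cli/mcffhbm.R fit --model hbmc --K 14 --data data/trials.csv --out fits/hbmc
Rscript inst/cli/mcffhbm.R check-convergence --posterior fits/hbmc
```

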