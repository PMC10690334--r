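#' Multi-component functional form (MCFF) parameter vector
#'
#' Bundles the K-dimensional parameter vector `theta` of an MCFF observer.
#' All entries are log10 magnitudes of the underlying (strictly positive)
#' component magnitudes; see [decode_params()] for the mapping onto the named
#' component processes.
#'
#' @param theta Numeric vector of length `K`, log10-scale component magnitudes.
#' @param K Model order, one of 2, 6 or 14. `K = 2` retains only general
#'   learning; `K = 6` adds forgetting, rapid relearning and adaptation with a
#'   single forgetting step and relearning asymptote shared across sessions;
#'   `K = 14` lets the forgetting step and relearning asymptote vary across
#'   sessions 2..6.
#' @return An object of class `mcff_params`.
#' @export
#' @examples
#' mcff_params(c(-1, -0.6), K = 2)
mcff_params <- function(theta, K = length(theta)) {
  if (!K %in% c(2L, 6L, 14L)) {
    stop("invalid model order: K must be one of 2, 6, 14 (got ", K, ")")
  }
  theta <- as.numeric(theta)
  if (length(theta) != K) {
    stop("length(theta) == ", length(theta), " but K == ", K)
  }
  if (any(!is.finite(theta))) {
    stop("theta must be finite")
  }
  structure(list(theta = theta, K = as.integer(K)), class = "mcff_params")
}

#' @export
print.mcff_params <- function(x, ...) {
  cat("MCFF parameters (K = ", x$K, "):\n", sep = "")
  print(signif(x$theta, 4))
  invisible(x)
}

#' Default prior bounds for MCFF parameters
#'
#' Box bounds of the uniform priors on each dimension of `theta`. Dimensions 1
#' and 2 (log10 learning rate, log10 negative initial threshold) lie in
#' \[-3, -0.5\]; the adaptation rate in \[-6, -3\]; forgetting steps in
#' \[-3, -1\]; the relearning rate in \[-4, -2\]; and relearning asymptotes in
#' \[-3, -0.6\].
#'
#' @param K Model order (2, 6 or 14).
#' @return An object of class `mcff_bounds` with numeric vectors `lower` and
#'   `upper` of length `K`.
#' @export
prior_bounds <- function(K) {
  K <- as.integer(K)
  if (K == 2L) {
    lower <- c(-3, -3); upper <- c(-0.5, -0.5)
  } else if (K == 6L) {
    lower <- c(-3, -3, -6, -3, -4, -3)
    upper <- c(-0.5, -0.5, -3, -1, -2, -0.6)
  } else if (K == 14L) {
    lower <- c(-3, -3, -6, rep(-3, 5), -4, rep(-3, 5))
    upper <- c(-0.5, -0.5, -3, rep(-1, 5), -2, rep(-0.6, 5))
  } else {
    stop("invalid model order: K must be one of 2, 6, 14 (got ", K, ")")
  }
  structure(list(lower = lower, upper = upper, K = K), class = "mcff_bounds")
}

#' Session structure of a training protocol
#'
#' Describes how global trial numbers map to sessions and within-session
#' indices. Pre-training trials, when present, are prepended to session 1, so
#' session 1 spans `pretrain_trials + trials_per_session[1]` trials and the
#' global trial counter includes them.
#'
#' @param n_sessions Number of daily sessions (default 6).
#' @param trials_per_session Trials per session; scalar (recycled) or vector of
#'   length `n_sessions`. Default 320.
#' @param pretrain_trials Number of pre-training trials prepended to session 1
#'   (0 to 80; default 0).
#' @return An object of class `session_structure`.
#' @export
session_structure <- function(n_sessions = 6, trials_per_session = 320,
                              pretrain_trials = 0) {
  n_sessions <- as.integer(n_sessions)
  stopifnot(n_sessions >= 1, pretrain_trials >= 0)
  tps <- as.integer(rep_len(trials_per_session, n_sessions))
  stopifnot(all(tps >= 1))
  len <- tps
  len[1] <- len[1] + as.integer(pretrain_trials)
  structure(list(
    n_sessions = n_sessions,
    trials_per_session = tps,
    pretrain_trials = as.integer(pretrain_trials),
    session_lengths = len,
    n_trials = sum(len)
  ), class = "session_structure")
}

#' Per-trial layout of a session structure
#'
#' @param structure A [session_structure()].
#' @return A data frame with one row per global trial and columns `trial`
#'   (1-based global trial number), `session`, and `within` (0-based
#'   within-session trial index; 0 at the first trial of each session,
#'   pre-training trials counting from 0 at the start of session 1).
#' @export
trial_layout <- function(structure) {
  stopifnot(inherits(structure, "session_structure"))
  len <- structure$session_lengths
  data.frame(
    trial = seq_len(structure$n_trials),
    session = rep(seq_along(len), len),
    within = unlist(lapply(len, function(l) seq_len(l) - 1L), use.names = FALSE)
  )
}

#' Psychometric function constants
#'
#' Constants of the Weibull psychometric function for a two-alternative
#' forced-choice (2AFC) task: guessing rate `g`, lapse rate `lapse`, the
#' reference probability `p_ref` defining threshold (probability correct at
#' d' = 1.5 under the equal-variance Gaussian model), and the Weibull slope
#' `beta`.
#'
#' @param g Guessing rate (default 0.5).
#' @param lapse Lapse rate (default 0.04).
#' @param p_ref Probability correct at threshold contrast (default 0.856).
#' @param beta Weibull slope (default 2).
#' @return An object of class `psychometric_config`.
#' @export
psychometric_config <- function(g = 0.5, lapse = 0.04, p_ref = 0.856, beta = 2) {
  stopifnot(g > 0, g < 1, lapse >= 0, lapse < 1, p_ref > g, p_ref < 1, beta > 0)
  structure(list(g = g, lapse = lapse, p_ref = p_ref, beta = beta),
            class = "psychometric_config")
}

# Fast internal decoder working on a bare numeric vector.
# Returns component magnitudes on the natural scale; delta[1] = d[1] = 0 by
# construction (no forgetting step or relearning asymptote in session 1).
decode_theta <- function(theta, K, n_sessions) {
  out <- list(gamma = 10^theta[1], b = -10^theta[2], phi = 0,
              delta = numeric(n_sessions), tau = 0, d = numeric(n_sessions))
  if (K == 2L) return(out)
  out$phi <- 10^theta[3]
  if (K == 6L) {
    if (n_sessions > 1) {
      out$delta[-1] <- 10^theta[4]
      out$d[-1] <- 10^theta[6]
    }
    out$tau <- 10^theta[5]
  } else {
    if (n_sessions != 6L) {
      stop("K = 14 requires a 6-session structure (per-session parameters ",
           "are allocated for sessions 2..6)")
    }
    out$delta[2:6] <- 10^theta[4:8]
    out$tau <- 10^theta[9]
    out$d[2:6] <- 10^theta[10:14]
  }
  out
}

#' Decode an MCFF parameter vector into named component magnitudes
#'
#' Maps the log10-scale vector `theta` onto the named processes of the
#' multi-component functional form: general-learning rate `gamma` and initial
#' threshold `b` (negative by convention, `b = -10^theta_2`), adaptation rate
#' `phi`, per-session forgetting steps `delta`, rapid-relearning rate `tau`,
#' and per-session relearning asymptotes `d`. Session 1 has no forgetting step
#' or relearning asymptote (`delta[1] = d[1] = 0`); for `K = 6` the single
#' step/asymptote is shared by sessions 2 onwards; for `K = 2` all components
#' other than general learning are zero.
#'
#' @param params An [mcff_params()] object.
#' @param n_sessions Number of sessions the per-session components span
#'   (default 6; `K = 14` requires 6).
#' @return A list with elements `gamma`, `b`, `phi`, `delta`, `tau`, `d`.
#' @export
#' @examples
#' decode_params(mcff_params(c(-1, -1), K = 2))
decode_params <- function(params, n_sessions = 6) {
  stopifnot(inherits(params, "mcff_params"))
  decode_theta(params$theta, params$K, as.integer(n_sessions))
}

#' Latent component processes of the learning curve
#'
#' Evaluates the four component processes of the MCFF on every trial of a
#' training protocol, in log10 threshold units:
#' general learning `b - gamma * log10(t)`; between-session forgetting (a step
#' `delta_s` constant within each session, zero in session 1, non-cumulative);
#' within-session rapid relearning `max(-d_s, -tau * t')` (an elbow dropping at
#' rate `tau` per trial down to the floor `-d_s`); and within-session
#' adaptation `phi * t'` (a ramp resetting at each session start), where `t'`
#' is the 0-based within-session trial index.
#'
#' @inheritParams decode_params
#' @param structure A [session_structure()].
#' @return A data frame with columns `trial`, `session`, `within`, `general`,
#'   `forgetting`, `relearning`, `adaptation`.
#' @export
component_curves <- function(params, structure) {
  stopifnot(inherits(params, "mcff_params"), inherits(structure, "session_structure"))
  lay <- trial_layout(structure)
  cmp <- decode_theta(params$theta, params$K, structure$n_sessions)
  lay$general <- cmp$b - cmp$gamma * log10(lay$trial)
  lay$forgetting <- cmp$delta[lay$session]
  lay$relearning <- pmax(-cmp$d[lay$session], -cmp$tau * lay$within)
  lay$adaptation <- cmp$phi * lay$within
  lay
}

#' Trial-by-trial log10 contrast threshold curve
#'
#' The learning curve `xi(t)`: the sum of the four MCFF component processes on
#' each trial.
#'
#' @inheritParams component_curves
#' @return Numeric vector of length `structure$n_trials`: the log10 contrast
#'   threshold on each global trial.
#' @export
#' @examples
#' s <- session_structure(n_sessions = 2, trials_per_session = 10)
#' threshold_curve(mcff_params(c(-1, -0.6), K = 2), s)
threshold_curve <- function(params, structure) {
  cc <- component_curves(params, structure)
  cc$general + cc$forgetting + cc$relearning + cc$adaptation
}

# xi(t) evaluated directly from a bare theta vector on a precomputed layout;
# hot path shared by the samplers and simulators.
xi_curve <- function(theta, K, layout, n_sessions) {
  cmp <- decode_theta(theta, K, n_sessions)
  cmp$b - cmp$gamma * layout$log10t + cmp$delta[layout$session] +
    pmax(-cmp$d[layout$session], -cmp$tau * layout$within) +
    cmp$phi * layout$within
}

#' Weibull psychometric function
#'
#' Probability of a correct 2AFC response at contrast `c` for an observer with
#' log10 contrast threshold `xi`. The threshold parameter of the Weibull is
#' placed so that the lapse-free probability correct equals `p_ref` exactly at
#' `c = 10^xi`:
#' `log10(vartheta) = xi - (1/beta) * log10(ln((1 - g)/(1 - p_ref)))`, and
#' `p = g * lapse + (1 - lapse) * (g + (1 - g) * (1 - exp(-(c/vartheta)^beta)))`.
#' The floor (as `c -> 0`) is `g*lapse + (1 - lapse)*g` and the ceiling
#' (as `c -> Inf`) is `g*lapse + (1 - lapse)`; with the defaults, 0.50 and 0.98.
#'
#' @param xi Log10 contrast threshold (scalar or vector).
#' @param contrast Stimulus contrast in (0, 1] (scalar or vector).
#' @param config A [psychometric_config()].
#' @param beta Weibull slope; defaults to `config$beta`.
#' @return Probability of a correct response, in (0, 1).
#' @export
#' @examples
#' weibull_prob(-1, 0.1, psychometric_config())  # contrast at threshold
weibull_prob <- function(xi, contrast, config = psychometric_config(),
                         beta = config$beta) {
  if (any(contrast <= 0)) stop("contrast must be strictly positive")
  g <- config$g; lam <- config$lapse
  log10_vt <- xi - log10(log((1 - g) / (1 - config$p_ref))) / beta
  w <- 10^(beta * (log10(contrast) - log10_vt))
  g * lam + (1 - lam) * (g + (1 - g) * (1 - exp(-w)))
}

# Precompute per-trial quantities invariant across likelihood evaluations.
# `trials` is a data.frame with columns global_trial, contrast, response.
trial_cache <- function(trials, structure, config) {
  lay <- trial_layout(structure)
  t <- as.integer(trials$global_trial)
  if (any(t < 1L) || any(t > structure$n_trials)) {
    stop("global_trial outside the session structure (1..",
         structure$n_trials, ")")
  }
  if (any(trials$contrast <= 0)) stop("contrast must be strictly positive")
  g <- config$g; lam <- config$lapse
  list(
    log10t = log10(t),
    session = as.integer(lay$session[t]),
    within = as.numeric(lay$within[t]),
    log10c = log10(as.numeric(trials$contrast)),
    r = as.numeric(trials$response),
    n = length(t),
    # probability floor a and span b2: p = a + b2 * (1 - exp(-w))
    a = g * lam + (1 - lam) * g,
    b2 = (1 - lam) * (1 - g),
    # log10 of ln((1-g)/(1-p_ref)); reused in every likelihood evaluation
    log10_lref = log10(log((1 - g) / (1 - config$p_ref))),
    n_sessions = structure$n_sessions
  )
}

# Bernoulli log likelihood of one subject/test's trials given bare theta.
# Probabilities are clipped to [1e-9, 1 - 1e-9] so extreme proposals during
# sampling keep the log likelihood finite. Compiled hot path.
loglik_cached <- function(theta, K, beta, cache) {
  if (cache$n == 0L) return(0)
  loglik_cpp(theta, cache$session, cache$within, cache$log10t, cache$log10c,
             cache$r, beta, cache$log10_lref, cache$a, cache$b2,
             cache$n_sessions)
}

#' Trial-by-trial Bernoulli log likelihood
#'
#' Log probability of an observed response sequence under an MCFF observer:
#' `sum_t [ r_t log p_t + (1 - r_t) log(1 - p_t) ]` with
#' `p_t = weibull_prob(xi(t), c_t)`, the log of the product of per-trial
#' Bernoulli probabilities. Probabilities are clipped to
#' `[1e-9, 1 - 1e-9]` before taking logs. An empty trial collection has log
#' likelihood 0.
#'
#' @inheritParams component_curves
#' @param trials Data frame of trials for one subject/test with columns
#'   `global_trial`, `contrast`, `response` (0/1).
#' @param config A [psychometric_config()].
#' @param beta Weibull slope; defaults to `config$beta`.
#' @return Scalar log likelihood.
#' @export
trial_loglik <- function(params, trials, structure,
                         config = psychometric_config(), beta = config$beta) {
  stopifnot(inherits(params, "mcff_params"), inherits(structure, "session_structure"))
  if (is.null(trials) || nrow(trials) == 0L) return(0)
  if (any(!trials$response %in% c(0, 1))) stop("response must be 0 or 1")
  cache <- trial_cache(trials, structure, config)
  loglik_cached(params$theta, params$K, beta, cache)
}
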