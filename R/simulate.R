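#' Accelerated stochastic-approximation staircase
#'
#' State of an adaptive staircase tracking a target accuracy on log10
#' contrast, using Kesten-style accelerated stochastic approximation: on the
#' first two trials the contrast moves by `(step / n) * (r - p_target)` and
#' thereafter by `(step / (2 + m)) * (r - p_target)`, where `m` is the number
#' of response reversals accumulated so far, so steps shrink as the staircase
#' brackets its target. Contrast is clipped so it never exceeds 1.
#'
#' @param target_accuracy Target probability correct, in (0.5, 1); the study
#'   conditions use 0.65 (low) and 0.85 (high).
#' @param initial_log10_contrast Starting log10 contrast (default -0.5).
#' @param initial_step Initial step size in log10 units (default 0.3).
#' @return An object of class `staircase_state` with fields `target`, `x`
#'   (current log10 contrast), `n` (trials run), `reversals`, `step`,
#'   `last_response`.
#' @export
staircase_state <- function(target_accuracy,
                            initial_log10_contrast = -0.5,
                            initial_step = 0.3) {
  stopifnot(target_accuracy > 0.5, target_accuracy < 1,
            initial_log10_contrast <= 0, initial_step > 0)
  structure(list(target = target_accuracy, x = initial_log10_contrast,
                 n = 0L, reversals = 0L, step = initial_step,
                 last_response = NA_integer_),
            class = "staircase_state")
}

#' Advance a staircase by one response
#'
#' @param state A [staircase_state()].
#' @param response Binary response (1 correct, 0 incorrect) on the trial just
#'   run at `state$x`.
#' @return The updated `staircase_state`, with `x` set to the log10 contrast
#'   for the next trial.
#' @export
staircase_step <- function(state, response) {
  stopifnot(inherits(state, "staircase_state"), response %in% c(0, 1))
  n <- state$n + 1L
  if (!is.na(state$last_response) && response != state$last_response) {
    state$reversals <- state$reversals + 1L
  }
  gain <- if (n <= 2L) state$step / n else state$step / (2 + state$reversals)
  state$x <- min(state$x - gain * (response - state$target), 0)
  state$n <- n
  state$last_response <- as.integer(response)
  state
}

#' Simulate one response from an MCFF observer
#'
#' Bernoulli draw with success probability given by the Weibull psychometric
#' function at the observer's trial-`t` threshold.
#'
#' @inheritParams component_curves
#' @param t Global trial number.
#' @param contrast Stimulus contrast in (0, 1].
#' @param config A [psychometric_config()].
#' @param beta Weibull slope; defaults to `config$beta`.
#' @return 0 or 1.
#' @export
observer_response <- function(params, structure, t, contrast,
                              config = psychometric_config(),
                              beta = config$beta) {
  xi <- threshold_curve(params, structure)[t]
  p <- weibull_prob(xi, contrast, config, beta)
  as.integer(stats::runif(length(p)) < p)
}

#' Simulate a full staircase-controlled training run for one observer
#'
#' Runs the adaptive staircase(s) of one training condition against an MCFF
#' observer across all sessions of `structure` (including any pre-training
#' block, which uses the same staircase). The `"mixed"` condition interleaves a
#' low- (0.65) and a high-accuracy (0.85) staircase in strict alternation,
#' each updating only on its own trials. Staircase state carries over between
#' sessions unless `reset_between_sessions` is set.
#'
#' @inheritParams component_curves
#' @param condition One of `"low"` (65% target), `"high"` (85%) or `"mixed"`.
#' @param config A [psychometric_config()].
#' @param beta Weibull slope; defaults to `config$beta`.
#' @param subject,test,group Identifiers written into the trial table.
#' @param feedback Logical; recorded as metadata only (the generative model
#'   has no feedback term).
#' @param initial_log10_contrast,initial_step Staircase tuning; see
#'   [staircase_state()].
#' @param reset_between_sessions Logical; restart staircases at
#'   `initial_log10_contrast` at each session boundary (default `FALSE`).
#' @return A list with `trials` (data frame with columns `subject`, `test`,
#'   `group`, `session`, `global_trial`, `contrast`, `response`,
#'   `staircase_id`) and `xi` (the observer's true log10 threshold curve).
#' @export
simulate_subject <- function(params, structure,
                             condition = c("low", "high", "mixed"),
                             config = psychometric_config(),
                             beta = config$beta,
                             subject = 1L, test = 1L, group = NA_integer_,
                             feedback = FALSE,
                             initial_log10_contrast = -0.5,
                             initial_step = 0.3,
                             reset_between_sessions = FALSE) {
  condition <- match.arg(condition)
  xi <- threshold_curve(params, structure)
  lay <- trial_layout(structure)
  n_trials <- structure$n_trials
  targets <- switch(condition, low = 0.65, high = 0.85, mixed = c(0.65, 0.85))
  stairs <- lapply(targets, staircase_state,
                   initial_log10_contrast = initial_log10_contrast,
                   initial_step = initial_step)
  log10_lref <- log10(log((1 - config$g) / (1 - config$p_ref)))
  g <- config$g; lam <- config$lapse
  contrast <- numeric(n_trials); response <- integer(n_trials); sid <- integer(n_trials)
  u <- stats::runif(n_trials)
  for (t in seq_len(n_trials)) {
    if (reset_between_sessions && lay$within[t] == 0L) {
      for (k in seq_along(stairs)) stairs[[k]]$x <- initial_log10_contrast
    }
    k <- if (length(stairs) == 2L) 1L + (t + 1L) %% 2L else 1L
    x <- stairs[[k]]$x
    w <- 10^(beta * (x - xi[t] + log10_lref / beta))
    p <- g * lam + (1 - lam) * (g + (1 - g) * (1 - exp(-w)))
    r <- as.integer(u[t] < p)
    contrast[t] <- 10^x
    response[t] <- r
    sid[t] <- k
    stairs[[k]] <- staircase_step(stairs[[k]], r)
  }
  trials <- data.frame(
    subject = subject, test = test, group = group,
    session = lay$session, global_trial = lay$trial,
    contrast = contrast, response = response, staircase_id = sid
  )
  list(trials = trials, xi = xi)
}

#' Specification of a simulated study population
#'
#' Defines the three-level Gaussian hierarchy and group design of a simulated
#' staircase study. Subject-level means are drawn `rho_i ~ MVN(mu, Sigma)` and
#' test-level parameters `theta_ij ~ MVN(rho_i, phi)`. The default design
#' mirrors a six-group study: groups 1-2 train at low (65%) accuracy, 3-4 at
#' mixed, 5-6 at high (85%), with (12, 12, 6, 6, 12, 12) subjects, feedback
#' alternating off/on, six 320-trial sessions and a 70-trial pre-training
#' block. Group 1 (low accuracy, no feedback) gets a lower general-learning
#' rate via `group_mu_offsets`, mirroring the slower learning such training
#' produces; feedback itself is metadata only.
#'
#' @param K Model order (2, 6 or 14).
#' @param mu Population mean vector (length `K`); defaults to plausible
#'   mid-prior values (see vignette).
#' @param Sigma Between-subject covariance (K x K); default `diag(0.15^2, K)`.
#' @param phi Within-subject (between-test) covariance; default
#'   `diag(0.05^2, K)`.
#' @param beta Weibull slope shared by all observers (default 2).
#' @param groups Data frame with columns `group`, `n_subjects`, `condition`
#'   (`"low"`, `"high"` or `"mixed"`), `feedback` (logical).
#' @param structure A [session_structure()]; default 6 sessions x 320 trials
#'   with 70 pre-training trials.
#' @param config A [psychometric_config()].
#' @param group_mu_offsets Optional list (one K-vector per group) added to `mu`
#'   when drawing that group's subjects; default shifts group 1's
#'   log10 learning rate by -0.2.
#' @param n_tests Tests per subject (default 1).
#' @param seed Integer seed consumed by [simulate_population()].
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(K = 14,
                            mu = default_population_mean(K),
                            Sigma = diag(0.15^2, K),
                            phi = diag(0.05^2, K),
                            beta = 2,
                            groups = default_group_design(),
                            structure = session_structure(6, 320, pretrain_trials = 70),
                            config = psychometric_config(),
                            group_mu_offsets = NULL,
                            n_tests = 1L,
                            seed = NULL) {
  K <- as.integer(K)
  stopifnot(K %in% c(2L, 6L, 14L), length(mu) == K)
  check_pd <- function(M, name) {
    if (!isTRUE(all.equal(M, t(M))) ||
        inherits(try(chol(M), silent = TRUE), "try-error")) {
      stop(name, " must be a symmetric positive-definite ", K, "x", K, " matrix")
    }
  }
  Sigma <- as.matrix(Sigma); phi <- as.matrix(phi)
  stopifnot(all(dim(Sigma) == K), all(dim(phi) == K))
  check_pd(Sigma, "Sigma"); check_pd(phi, "phi")
  stopifnot(is.data.frame(groups),
            all(c("group", "n_subjects", "condition", "feedback") %in% names(groups)),
            all(groups$condition %in% c("low", "high", "mixed")))
  if (is.null(group_mu_offsets)) {
    group_mu_offsets <- rep(list(numeric(K)), nrow(groups))
    group_mu_offsets[[1]][1] <- -0.2
  }
  stopifnot(length(group_mu_offsets) == nrow(groups),
            all(vapply(group_mu_offsets, length, 1L) == K))
  structure(list(K = K, mu = as.numeric(mu), Sigma = Sigma, phi = phi,
                 beta = beta, groups = groups, structure = structure,
                 config = config, group_mu_offsets = group_mu_offsets,
                 n_tests = as.integer(n_tests), seed = seed),
            class = "population_spec")
}

#' Default population mean parameters
#'
#' Plausible study-scale values: learning rate `gamma = 0.1` per log10-trial,
#' initial log10 threshold `b = -0.25`, adaptation rate `3.2e-5` per trial,
#' forgetting steps of 0.01 log10 units, relearning rate `1e-3` per trial and
#' relearning asymptotes of 0.05 log10 units.
#'
#' @param K Model order.
#' @return Numeric vector of length `K` (log10 scale).
#' @export
default_population_mean <- function(K) {
  K <- as.integer(K)
  switch(as.character(K),
         "2" = c(-1.0, -0.6),
         "6" = c(-1.0, -0.6, -4.5, -2.0, -3.0, -1.3),
         "14" = c(-1.0, -0.6, -4.5, rep(-2.0, 5), -3.0, rep(-1.3, 5)),
         stop("invalid model order: K must be one of 2, 6, 14 (got ", K, ")"))
}

#' Default six-group study design
#'
#' @return Data frame of groups sized (12, 12, 6, 6, 12, 12) with conditions
#'   low/low/mixed/mixed/high/high and feedback off/on alternating.
#' @export
default_group_design <- function() {
  data.frame(
    group = 1:6,
    n_subjects = c(12L, 12L, 6L, 6L, 12L, 12L),
    condition = c("low", "low", "mixed", "mixed", "high", "high"),
    feedback = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE)
  )
}

#' Simulate a full hierarchical study population
#'
#' Draws subject means `rho_i ~ MVN(mu, Sigma)` (with any per-group mean
#' offsets), test-level parameters `theta_ij ~ MVN(rho_i, phi)`, and runs each
#' subject through [simulate_subject()] under its group's staircase condition.
#'
#' @param spec A [population_spec()].
#' @param seed Overrides `spec$seed` when given.
#' @return A list with `trials` (the combined trial table), `truth` (a list
#'   with `rho` (subjects x K), `theta` (array subjects x tests x K), `xi`
#'   (list of true curves indexed `"subject.test"`), `subjects` (data frame of
#'   subject, group, condition, feedback)), and `spec`.
#' @export
simulate_population <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "population_spec"))
  if (!is.null(seed)) set.seed(seed)
  K <- spec$K; J <- spec$n_tests
  I <- sum(spec$groups$n_subjects)
  rho <- matrix(NA_real_, I, K)
  theta <- array(NA_real_, c(I, J, K))
  subjects <- data.frame(subject = seq_len(I), group = NA_integer_,
                         condition = NA_character_, feedback = NA)
  xi_truth <- list()
  all_trials <- vector("list", I * J)
  i <- 0L
  for (gr in seq_len(nrow(spec$groups))) {
    gmu <- spec$mu + spec$group_mu_offsets[[gr]]
    for (s in seq_len(spec$groups$n_subjects[gr])) {
      i <- i + 1L
      subjects$group[i] <- spec$groups$group[gr]
      subjects$condition[i] <- spec$groups$condition[gr]
      subjects$feedback[i] <- spec$groups$feedback[gr]
      rho[i, ] <- MASS::mvrnorm(1, gmu, spec$Sigma)
      for (j in seq_len(J)) {
        theta[i, j, ] <- MASS::mvrnorm(1, rho[i, ], spec$phi)
        sim <- simulate_subject(
          mcff_params(theta[i, j, ], K), spec$structure,
          condition = spec$groups$condition[gr], config = spec$config,
          beta = spec$beta, subject = i, test = j,
          group = spec$groups$group[gr], feedback = spec$groups$feedback[gr]
        )
        xi_truth[[paste(i, j, sep = ".")]] <- sim$xi
        all_trials[[(i - 1L) * J + j]] <- sim$trials
      }
    }
  }
  list(
    trials = do.call(rbind, all_trials),
    truth = list(rho = rho, theta = theta, xi = xi_truth, subjects = subjects),
    spec = spec
  )
}
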