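# Independent reference implementations used as oracles, written as plain
# per-trial loops so they share no code with the package's vectorized /
# compiled paths.

# Decode a log10-scale parameter vector (independent of decode_params).
ora_decode <- function(theta, K) {
  gam <- 10^theta[1]
  b <- -10^theta[2]
  delta <- d <- rep(0, 6)
  phi <- tau <- 0
  if (K >= 6) {
    phi <- 10^theta[3]
    if (K == 6) {
      delta[2:6] <- 10^theta[4]
      tau <- 10^theta[5]
      d[2:6] <- 10^theta[6]
    } else {
      delta[2:6] <- 10^theta[4:8]
      tau <- 10^theta[9]
      d[2:6] <- 10^theta[10:14]
    }
  }
  list(gam = gam, b = b, phi = phi, delta = delta, tau = tau, d = d)
}

# Session / within-session index of global trial t under (n_sessions,
# trials_per_session scalar, pretrain) -- session 1 absorbs pre-training.
ora_session_of <- function(t, tps, pretrain) {
  if (t <= pretrain + tps) return(c(1L, t - 1L))
  rest <- t - (pretrain + tps)
  s <- 1L + ceiling(rest / tps)
  within <- (rest - 1L) %% tps
  c(s, within)
}

# Per-trial probability correct and log likelihood, one trial at a time.
ora_prob <- function(xi, contrast, beta, g = 0.5, lapse = 0.04, p_ref = 0.856) {
  vt <- 10^(xi - log10(log((1 - g) / (1 - p_ref))) / beta)
  g * lapse + (1 - lapse) * (g + (1 - g) * (1 - exp(-(contrast / vt)^beta)))
}

ora_loglik <- function(theta, K, trials, tps, pretrain, beta) {
  cmp <- ora_decode(theta, K)
  total <- 0
  for (row in seq_len(nrow(trials))) {
    t <- trials$global_trial[row]
    sw <- ora_session_of(t, tps, pretrain)
    s <- sw[1]; w <- sw[2]
    xi <- cmp$b - cmp$gam * log10(t) + cmp$delta[s] +
      max(-cmp$d[s], -cmp$tau * w) + cmp$phi * w
    p <- ora_prob(xi, trials$contrast[row], beta)
    p <- min(max(p, 1e-9), 1 - 1e-9)
    total <- total + log(if (trials$response[row] == 1) p else 1 - p)
  }
  total
}

# Random trial table consistent with a session structure (responses need not
# follow any model; the likelihood is a pure function of the table).
random_trials <- function(n, structure) {
  t <- sort(sample.int(structure$n_trials, n, replace = FALSE))
  lay <- trial_layout(structure)
  data.frame(subject = 1L, test = 1L, group = 1L,
             session = lay$session[t], global_trial = t,
             contrast = 10^stats::runif(n, -3, 0),
             response = stats::rbinom(n, 1, 0.5), staircase_id = 1L)
}

random_theta_in_bounds <- function(K) {
  b <- prior_bounds(K)
  stats::runif(K, b$lower, b$upper)
}

empty_trials <- function() {
  data.frame(subject = integer(), test = integer(), group = integer(),
             session = integer(), global_trial = integer(),
             contrast = numeric(), response = integer(),
             staircase_id = integer())
}

# Short schedules for sampler tests.
quick_config <- function(model, ..., seed = 1) {
  defaults <- list(n_chains = 2, kept_samples = 250, thin = 2,
                   burn_in = 300, adaptation = 400, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(sampler_config, c(list(model = model), args))
}

# Stationary-observer staircase run; returns realized accuracy over the
# second half of the run.
staircase_longrun_accuracy <- function(target, n_trials = 10000, xi = -1.3,
                                       beta = 2) {
  cfg <- psychometric_config()
  st <- staircase_state(target)
  acc <- integer(n_trials)
  for (t in seq_len(n_trials)) {
    p <- weibull_prob(xi, 10^st$x, cfg, beta)
    r <- as.integer(stats::runif(1) < p)
    acc[t] <- r
    st <- staircase_step(st, r)
  }
  mean(acc[(n_trials / 2 + 1):n_trials])
}

# Hand-built BIP-format posterior from an explicit draw matrix (n x K),
# split across 2 chains.
make_bip_posterior <- function(draws, beta = 2, structure = session_structure()) {
  draws <- as.matrix(draws)
  n <- nrow(draws); K <- ncol(draws)
  stopifnot(n %% 2 == 0)
  labels <- paste0("theta[", seq_len(K), "]")
  arr <- array(NA_real_, c(2, n / 2, K), dimnames = list(NULL, NULL, labels))
  arr[1, , ] <- draws[seq_len(n / 2), ]
  arr[2, , ] <- draws[(n / 2 + 1):n, ]
  structure(list(model = "bip", K = K, draws = arr, subjects = 1L,
                 tests = 1L, convergence = setNames(rep(NA_real_, K), labels),
                 converged = NA, config = sampler_config("bip"),
                 beta_fixed = beta, structure = structure),
            class = "mcff_posterior")
}

# Type-7 quantile computed from first principles (order statistics).
ora_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
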