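#' MCMC sampler schedule
#'
#' Sampling schedule for the three inference procedures. Defaults follow the
#' reference schedule: 3 chains, 5,000 kept samples per chain with a thinning
#' ratio of 10, 5,000 adaptation steps, and a burn-in of 5,000 steps (500,000
#' for the covariance model, whose hyperparameters mix more slowly).
#' Convergence is declared when the between/within-chain variance ratio is
#' below `convergence_threshold` for every scalar parameter.
#'
#' @param model One of `"bip"`, `"hbmv"`, `"hbmc"` (sets the burn-in default).
#' @param n_chains Number of MCMC chains (default 3).
#' @param kept_samples Kept samples per chain (default 5000).
#' @param thin Thinning ratio (default 10).
#' @param burn_in Burn-in sweeps; default 5000 (BIP/HBMv) or 500000 (HBMc).
#' @param adaptation Adaptation sweeps during which proposal scales are tuned
#'   (default 5000).
#' @param convergence_threshold Between/within variance ratio below which
#'   convergence is declared (default 1.05).
#' @param seed Optional integer seed; fixing it makes the fit reproducible.
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(model = c("bip", "hbmv", "hbmc"),
                           n_chains = 3, kept_samples = 5000, thin = 10,
                           burn_in = NULL, adaptation = 5000,
                           convergence_threshold = 1.05, seed = NULL) {
  model <- match.arg(model)
  if (is.null(burn_in)) burn_in <- if (model == "hbmc") 500000 else 5000
  stopifnot(n_chains >= 1, kept_samples >= 1, thin >= 1, burn_in >= 0,
            adaptation >= 0, convergence_threshold > 1)
  structure(list(model = model, n_chains = as.integer(n_chains),
                 kept_samples = as.integer(kept_samples),
                 thin = as.integer(thin), burn_in = as.integer(burn_in),
                 adaptation = as.integer(adaptation),
                 convergence_threshold = convergence_threshold, seed = seed),
            class = "sampler_config")
}

#' Between/within-chain variance ratio
#'
#' Convergence diagnostic for one scalar parameter: the variance of the
#' samples pooled across chains divided by the mean within-chain variance.
#' Values near 1 indicate the chains have mixed; convergence is declared when
#' the ratio is below 1.05 for all parameters.
#'
#' @param draws Matrix of draws, chains in rows and samples in columns (or an
#'   array whose first dimension indexes chains).
#' @return Scalar variance ratio.
#' @export
convergence_ratio <- function(draws) {
  if (is.null(dim(draws))) stop("convergence diagnostic requires >= 2 chains")
  m <- matrix(draws, nrow = dim(draws)[1])
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("convergence diagnostic requires >= 2 chains with >= 2 samples each")
  }
  within <- mean(apply(m, 1, stats::var))
  pooled <- stats::var(as.vector(m))
  if (within == 0) {
    if (pooled == 0) return(1)
    return(Inf)
  }
  pooled / within
}

# --- internal sampler machinery ------------------------------------------

# Truncated-normal draw by inverse-CDF; vectorized over all arguments.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  x <- stats::qnorm(pmin(pmax(u, 1e-15), 1 - 1e-15), mean, sd)
  pmin(pmax(x, lower), upper)
}

# Organize a trial table into per-(subject, test) likelihood caches.
# `subjects` may extend beyond those present in `trials` (units without data
# contribute only their prior, used by likelihood-free runs and prediction).
build_units <- function(trials, structure, config, subjects = NULL,
                        tests = NULL, likelihood = TRUE) {
  if (is.null(subjects)) subjects <- sort(unique(trials$subject))
  if (is.null(tests)) tests <- sort(unique(trials$test))
  if (length(tests) == 0L) tests <- 1L
  if (length(subjects) == 0L) stop("no subjects in dataset")
  I <- length(subjects); J <- length(tests)
  units <- vector("list", I * J)
  empty <- list(n = 0L)
  for (i in seq_len(I)) {
    for (j in seq_len(J)) {
      sub <- trials[trials$subject == subjects[i] & trials$test == tests[j], ,
                    drop = FALSE]
      units[[(i - 1L) * J + j]] <-
        if (!likelihood || nrow(sub) == 0L) empty
        else trial_cache(sub, structure, config)
    }
  }
  list(units = units, subjects = subjects, tests = tests, I = I, J = J)
}

# Componentwise random-walk Metropolis update of one unit's theta (compiled).
# `prior` is one of mh_prior_uniform / mh_prior_diag / mh_prior_mvn.
# Returns list(theta, ll, acc).
mh_update_theta <- function(theta, K, ll, cache, beta, scales, prior) {
  mh_update_cpp(theta, ll, beta, cache$session, cache$within, cache$log10t,
                cache$log10c, cache$r, cache$log10_lref, cache$a, cache$b2,
                cache$n_sessions, scales, prior$type, prior$lower,
                prior$upper, prior$rho, prior$eps2, prior$Lambda)
}

mh_prior_uniform <- function(lower, upper) {
  list(type = 0L, lower = lower, upper = upper, rho = numeric(0),
       eps2 = numeric(0), Lambda = matrix(0, 0, 0))
}
mh_prior_diag <- function(rho, eps2) {
  list(type = 1L, lower = numeric(0), upper = numeric(0), rho = rho,
       eps2 = eps2, Lambda = matrix(0, 0, 0))
}
mh_prior_mvn <- function(rho, Lambda) {
  list(type = 2L, lower = numeric(0), upper = numeric(0), rho = rho,
       eps2 = numeric(0), Lambda = Lambda)
}

adapt_scales <- function(scales, acc_count, batch_size, target = 0.44) {
  rate <- acc_count / batch_size
  pmin(pmax(scales * exp(0.3 * (rate - target)), 0.01), 3)
}

# Assemble kept-draw matrices (one per chain) into an mcff_posterior object.
finish_posterior <- function(chains, labels, model, K, subjects, tests,
                             config, beta_fixed) {
  draws <- array(NA_real_, c(length(chains), nrow(chains[[1]]), length(labels)),
                 dimnames = list(NULL, NULL, labels))
  for (c in seq_along(chains)) draws[c, , ] <- chains[[c]]
  conv <- rep(NA_real_, length(labels))
  names(conv) <- labels
  if (length(chains) >= 2 && nrow(chains[[1]]) >= 2) {
    for (p in seq_along(labels)) conv[p] <- convergence_ratio(draws[, , p])
  }
  converged <- if (all(is.na(conv))) NA else
    all(conv < config$convergence_threshold, na.rm = TRUE)
  structure(list(model = model, K = K, draws = draws, subjects = subjects,
                 tests = tests, convergence = conv, converged = converged,
                 config = config, beta_fixed = beta_fixed),
            class = "mcff_posterior")
}

#' @export
print.mcff_posterior <- function(x, ...) {
  d <- dim(x$draws)
  cat("MCFF posterior (", toupper(x$model), ", K = ", x$K, "): ",
      d[1], " chains x ", d[2], " kept samples x ", d[3], " parameters\n",
      sep = "")
  if (!is.na(x$converged)) {
    cat("max between/within variance ratio: ",
        signif(max(x$convergence, na.rm = TRUE), 4),
        if (isTRUE(x$converged)) " (converged)" else " (NOT converged)", "\n",
        sep = "")
  }
  invisible(x)
}

#' Pooled posterior draws of one subject/test's MCFF parameters
#'
#' @param posterior An `mcff_posterior` from [fit_bip()], [fit_hbmv()] or
#'   [fit_hbmc()].
#' @param subject Subject id (matched against `posterior$subjects`); for BIP
#'   fits the single fitted unit is returned.
#' @param test Test id (default the first).
#' @return Matrix of draws pooled across chains, one column per dimension of
#'   `theta`.
#' @export
theta_draws <- function(posterior, subject = posterior$subjects[1],
                        test = posterior$tests[1]) {
  stopifnot(inherits(posterior, "mcff_posterior"))
  i <- match(subject, posterior$subjects)
  j <- match(test, posterior$tests)
  if (is.na(i) || is.na(j)) stop("unknown subject/test")
  labels <- if (posterior$model == "bip") {
    paste0("theta[", seq_len(posterior$K), "]")
  } else {
    paste0("theta[", i, ",", j, ",", seq_len(posterior$K), "]")
  }
  d <- posterior$draws[, , labels, drop = FALSE]
  matrix(d, ncol = posterior$K,
         dimnames = list(NULL, paste0("theta", seq_len(posterior$K))))
}

#' Pooled draws of a named scalar or vector quantity
#'
#' @param posterior An `mcff_posterior`.
#' @param name Parameter label prefix, e.g. `"mu"`, `"beta"`, `"sigma"`.
#' @return Matrix of pooled draws (columns = matching parameters, in label
#'   order).
#' @export
param_draws <- function(posterior, name) {
  labels <- dimnames(posterior$draws)[[3]]
  sel <- labels == name | startsWith(labels, paste0(name, "["))
  if (!any(sel)) stop("no parameter matching '", name, "'")
  d <- posterior$draws[, , sel, drop = FALSE]
  matrix(d, ncol = sum(sel), dimnames = list(NULL, labels[sel]))
}

# --- BIP -------------------------------------------------------------------

#' Bayesian inference procedure (BIP) for one subject/test
#'
#' Samples the posterior of one subject's MCFF parameter vector under
#' independent uniform priors on each dimension, with the Weibull slope fixed
#' (at 2 by default). When the trial set is empty the posterior equals the
#' prior and is drawn directly.
#'
#' @param trials Trial table for a single subject/test (columns
#'   `global_trial`, `contrast`, `response`).
#' @param bounds A [prior_bounds()] matching `K`.
#' @param config A [sampler_config()].
#' @param structure A [session_structure()].
#' @param psych A [psychometric_config()].
#' @param beta Fixed Weibull slope (default 2).
#' @return An `mcff_posterior` (model `"bip"`) with parameters
#'   `theta[1..K]`. Non-convergence is flagged in `$converged`, never raised
#'   as an error.
#' @export
fit_bip <- function(trials, bounds, config = sampler_config("bip"),
                    structure = session_structure(),
                    psych = psychometric_config(), beta = 2) {
  stopifnot(inherits(bounds, "mcff_bounds"), inherits(config, "sampler_config"))
  K <- bounds$K
  lower <- bounds$lower; upper <- bounds$upper
  cache <- if (is.null(trials) || nrow(trials) == 0L) list(n = 0L)
           else trial_cache(trials, structure, psych)
  if (!is.null(config$seed)) set.seed(config$seed)
  n_adapt <- config$adaptation; n_burn <- config$burn_in
  n_keep <- config$kept_samples; thin <- config$thin
  n_sweeps <- n_adapt + n_burn + n_keep * thin
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    theta <- stats::runif(K, lower, upper)
    ll <- loglik_cached(theta, K, beta, cache)
    scales <- rep(0.1, K); accc <- numeric(K)
    kept <- matrix(NA_real_, n_keep, K); ki <- 0L
    for (sw in seq_len(n_sweeps)) {
      if (cache$n == 0L) {
        theta <- stats::runif(K, lower, upper)
      } else {
        up <- mh_update_theta(theta, K, ll, cache, beta, scales,
                              mh_prior_uniform(lower, upper))
        theta <- up$theta; ll <- up$ll; accc <- accc + up$acc
        if (sw <= n_adapt && sw %% 25L == 0L) {
          scales <- adapt_scales(scales, accc, 25); accc[] <- 0
        }
      }
      if (sw > n_adapt + n_burn && (sw - n_adapt - n_burn) %% thin == 0L) {
        ki <- ki + 1L; kept[ki, ] <- theta
      }
    }
    chains[[ch]] <- kept
  }
  subj <- if (!is.null(trials) && nrow(trials) > 0L && "subject" %in% names(trials))
    trials$subject[1] else 1L
  post <- finish_posterior(chains, paste0("theta[", seq_len(K), "]"),
                           "bip", K, subj, 1L, config, beta)
  post$structure <- structure
  post
}

# --- HBMv ------------------------------------------------------------------

#' Hierarchical Bayesian model with variance hyperparameters (HBMv)
#'
#' Three-level per-dimension Gaussian hierarchy fitted jointly to all
#' subjects: subject means `rho_ik ~ N(mu_k, sigma_k)`, test-level parameters
#' `theta_ijk ~ N(rho_ik, eps_k)` (the between-test scatter `eps_k` shared by
#' all subjects), with priors `mu_k ~ U(bounds)`, `1/sigma_k^2 ~ Gamma(15, 1)`,
#' `1/eps_k^2 ~ Gamma(20, 1)` and `beta ~ U(1, 4)` shared across subjects.
#' Gaussian levels are not truncated at the bounds; the box applies to `mu`'s
#' prior only. Sampling is Gibbs-within-Metropolis: conjugate updates for
#' `rho`, `mu`, `sigma`, `eps`, componentwise adaptive random-walk Metropolis
#' for `theta` and `beta`.
#'
#' @param trials Trial table for all subjects (columns `subject`, `test`,
#'   `global_trial`, `contrast`, `response`).
#' @param bounds A [prior_bounds()].
#' @param config A [sampler_config()].
#' @param structure A [session_structure()].
#' @param psych A [psychometric_config()].
#' @param beta Fixed slope, or `NULL` (default) to sample it.
#' @param subjects,tests Optional explicit unit grids (defaults: those present
#'   in `trials`); subjects without trials contribute prior-only units.
#' @param likelihood Set `FALSE` to disable the likelihood entirely (the
#'   sampler then draws from the joint prior; used for prior-predictive
#'   checks).
#' @return An `mcff_posterior` (model `"hbmv"`) with parameters
#'   `theta[i,j,k]`, `rho[i,k]`, `mu[k]`, `sigma[k]`, `eps[k]` and `beta`.
#' @export
fit_hbmv <- function(trials, bounds, config = sampler_config("hbmv"),
                     structure = session_structure(),
                     psych = psychometric_config(), beta = NULL,
                     subjects = NULL, tests = NULL, likelihood = TRUE) {
  stopifnot(inherits(bounds, "mcff_bounds"), inherits(config, "sampler_config"))
  K <- bounds$K
  lower <- bounds$lower; upper <- bounds$upper
  du <- build_units(trials, structure, psych, subjects, tests, likelihood)
  I <- du$I; J <- du$J; units <- du$units
  has_data <- vapply(units, function(u) u$n > 0L, TRUE)
  if (!is.null(config$seed)) set.seed(config$seed)
  beta_fixed <- !is.null(beta)
  n_adapt <- config$adaptation; n_burn <- config$burn_in
  n_keep <- config$kept_samples; thin <- config$thin
  n_sweeps <- n_adapt + n_burn + n_keep * thin
  labels <- c(
    unlist(lapply(seq_len(I), function(i) unlist(lapply(seq_len(J), function(j)
      paste0("theta[", i, ",", j, ",", seq_len(K), "]"))))),
    unlist(lapply(seq_len(I), function(i) paste0("rho[", i, ",", seq_len(K), "]"))),
    paste0("mu[", seq_len(K), "]"),
    paste0("sigma[", seq_len(K), "]"),
    paste0("eps[", seq_len(K), "]"),
    "beta")
  P <- length(labels)
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    mu <- stats::runif(K, lower, upper)
    sigma2 <- 1 / stats::rgamma(K, 15, 1)
    eps2 <- 1 / stats::rgamma(K, 20, 1)
    # theta and rho start inside the box so no chain begins in the flat
    # far tail of the likelihood (hyperparameters still start from priors)
    rho <- matrix(pmin(pmax(stats::rnorm(I * K, rep(mu, each = I),
                                         rep(sqrt(sigma2), each = I)),
                            rep(lower, each = I)), rep(upper, each = I)), I, K)
    theta <- matrix(NA_real_, I * J, K)
    for (i in seq_len(I)) for (j in seq_len(J)) {
      theta[(i - 1L) * J + j, ] <-
        pmin(pmax(stats::rnorm(K, rho[i, ], sqrt(eps2)), lower), upper)
    }
    bet <- if (beta_fixed) beta else stats::runif(1, 1, 4)
    ll <- vapply(seq_len(I * J), function(u)
      loglik_cached(theta[u, ], K, bet, units[[u]]), 0)
    scales <- matrix(0.1, I * J, K); accc <- matrix(0, I * J, K)
    bscale <- 0.1; bacc <- 0
    kept <- matrix(NA_real_, n_keep, P); ki <- 0L
    for (sw in seq_len(n_sweeps)) {
      # prior independence refresh: propose the whole state from the joint
      # prior and accept by the likelihood ratio. Rarely accepted once the
      # data dominate, but an exact draw whenever the likelihood is absent
      # and a cheap escape from distant initializations.
      p_mu <- stats::runif(K, lower, upper)
      p_sigma2 <- 1 / stats::rgamma(K, 15, 1)
      p_eps2 <- 1 / stats::rgamma(K, 20, 1)
      p_rho <- matrix(stats::rnorm(I * K, rep(p_mu, each = I),
                                   rep(sqrt(p_sigma2), each = I)), I, K)
      p_theta <- matrix(stats::rnorm(I * J * K,
                                     p_rho[rep(seq_len(I), each = J), ],
                                     rep(sqrt(p_eps2), each = I * J)), I * J, K)
      p_bet <- if (beta_fixed) bet else stats::runif(1, 1, 4)
      p_ll <- vapply(seq_len(I * J), function(u)
        loglik_cached(p_theta[u, ], K, p_bet, units[[u]]), 0)
      if (isTRUE(log(stats::runif(1)) < sum(p_ll) - sum(ll))) {
        mu <- p_mu; sigma2 <- p_sigma2; eps2 <- p_eps2
        rho <- p_rho; theta <- p_theta; bet <- p_bet; ll <- p_ll
      }
      # theta | rest
      for (i in seq_len(I)) for (j in seq_len(J)) {
        u <- (i - 1L) * J + j
        if (!has_data[u]) {
          theta[u, ] <- stats::rnorm(K, rho[i, ], sqrt(eps2))
        } else {
          up <- mh_update_theta(theta[u, ], K, ll[u], units[[u]], bet,
                                scales[u, ], mh_prior_diag(rho[i, ], eps2))
          theta[u, ] <- up$theta; ll[u] <- up$ll
          accc[u, ] <- accc[u, ] + up$acc
          # independence refresh from the conditional prior N(rho_i, eps):
          # prior terms cancel, acceptance is the likelihood ratio alone
          prop <- stats::rnorm(K, rho[i, ], sqrt(eps2))
          llp <- loglik_cached(prop, K, bet, units[[u]])
          if (isTRUE(log(stats::runif(1)) < llp - ll[u])) {
            theta[u, ] <- prop; ll[u] <- llp
          }
        }
      }
      # rho | rest (conjugate per dimension)
      sum_theta <- if (J == 1L) theta else
        t(vapply(seq_len(I), function(i)
          colSums(theta[((i - 1L) * J + 1L):(i * J), , drop = FALSE]), numeric(K)))
      prec <- outer(rep(1, I), 1 / sigma2) + outer(rep(J, I), 1 / eps2)
      pm <- (outer(rep(1, I), mu / sigma2) + sum_theta / outer(rep(1, I), eps2)) / prec
      rho <- matrix(stats::rnorm(I * K, pm, sqrt(1 / prec)), I, K)
      # mu | rho (truncated normal)
      mu <- rtruncnorm(K, colMeans(rho), sqrt(sigma2 / I), lower, upper)
      # 1/sigma^2, 1/eps^2 | rest (conjugate Gamma)
      ss_rho <- colSums((rho - outer(rep(1, I), mu))^2)
      sigma2 <- 1 / stats::rgamma(K, 15 + I / 2, 1 + ss_rho / 2)
      rho_exp <- rho[rep(seq_len(I), each = J), , drop = FALSE]
      ss_th <- colSums((theta - rho_exp)^2)
      eps2 <- 1 / stats::rgamma(K, 20 + I * J / 2, 1 + ss_th / 2)
      # beta | rest
      if (!beta_fixed) {
        bp <- bet + stats::rnorm(1, 0, bscale)
        if (bp >= 1 && bp <= 4) {
          llp <- vapply(seq_len(I * J), function(u)
            if (has_data[u]) loglik_cached(theta[u, ], K, bp, units[[u]]) else 0, 0)
          if (isTRUE(log(stats::runif(1)) < sum(llp) - sum(ll))) {
            bet <- bp; ll <- llp; bacc <- bacc + 1
          }
        }
      }
      if (sw <= n_adapt && sw %% 25L == 0L) {
        scales <- adapt_scales(scales, accc, 25); accc[] <- 0
        if (!beta_fixed) {
          bscale <- adapt_scales(bscale, bacc, 25); bacc <- 0
        }
      }
      if (sw > n_adapt + n_burn && (sw - n_adapt - n_burn) %% thin == 0L) {
        ki <- ki + 1L
        kept[ki, ] <- c(as.vector(t(theta)), as.vector(t(rho)), mu,
                        sqrt(sigma2), sqrt(eps2), bet)
      }
    }
    chains[[ch]] <- kept
  }
  post <- finish_posterior(chains, labels, "hbmv", K, du$subjects, du$tests,
                           config, if (beta_fixed) beta else NULL)
  post$structure <- structure
  post
}

# --- HBMc ------------------------------------------------------------------

#' Hierarchical Bayesian model with covariance hyperparameters (HBMc)
#'
#' Three-level multivariate Gaussian hierarchy with full covariance at the
#' population and subject levels: `rho_i ~ MVN(mu, Sigma)`,
#' `theta_ij ~ MVN(rho_i, phi)`, with priors `mu ~ U(bounds)` per dimension,
#' Wishart priors on the precision matrices
#' `Omega = Sigma^-1 ~ W(scale$Sigma^-1 / v, v)` and
#' `Lambda = phi^-1 ~ W(scale$phi^-1 / v, v)` with `v = K + 1` degrees of
#' freedom (so the prior mean of each precision equals the supplied scale
#' matrix's inverse), and `beta ~ U(1, 4)`. The scale matrices conventionally
#' come from a previous HBMv run (see [hbmv_scale_matrices()]); without one,
#' identity matrices are used as a cold-start fallback. Sampling is
#' Gibbs-within-Metropolis (conjugate multivariate-normal updates for `rho`,
#' per-dimension truncated-normal Gibbs for `mu`, conjugate Wishart updates
#' for the precisions, adaptive random-walk Metropolis for `theta` and
#' `beta`).
#'
#' @inheritParams fit_hbmv
#' @param scale List with symmetric positive-definite K x K matrices `Sigma`
#'   and `phi` used as Wishart prior scales, or `NULL` for the identity
#'   fallback.
#' @return An `mcff_posterior` (model `"hbmc"`) with parameters
#'   `theta[i,j,k]`, `rho[i,k]`, `mu[k]`, `Sigma[k,l]` and `phi[k,l]`
#'   (upper triangles of the covariance matrices) and `beta`.
#' @export
fit_hbmc <- function(trials, bounds, config = sampler_config("hbmc"),
                     structure = session_structure(),
                     psych = psychometric_config(), scale = NULL,
                     beta = NULL, subjects = NULL, tests = NULL,
                     likelihood = TRUE) {
  stopifnot(inherits(bounds, "mcff_bounds"), inherits(config, "sampler_config"))
  K <- bounds$K
  lower <- bounds$lower; upper <- bounds$upper
  v0 <- K + 1
  if (is.null(scale)) scale <- list(Sigma = diag(K), phi = diag(K))
  check_scale <- function(M, name) {
    M <- as.matrix(M)
    if (!all(dim(M) == K)) stop(name, " scale must be ", K, "x", K)
    if (max(abs(M - t(M))) > 1e-8 ||
        inherits(try(chol(M), silent = TRUE), "try-error")) {
      stop(name, " scale must be symmetric positive-definite")
    }
    M
  }
  Sigma_scale <- check_scale(scale$Sigma, "Sigma")
  phi_scale <- check_scale(scale$phi, "phi")
  # Wishart prior W(S0, v0) with S0 = scale^-1 / v0, so E[precision] = scale^-1.
  S0_Sigma <- solve(Sigma_scale) / v0
  S0_phi <- solve(phi_scale) / v0
  du <- build_units(trials, structure, psych, subjects, tests, likelihood)
  I <- du$I; J <- du$J; units <- du$units
  has_data <- vapply(units, function(u) u$n > 0L, TRUE)
  if (!is.null(config$seed)) set.seed(config$seed)
  beta_fixed <- !is.null(beta)
  n_adapt <- config$adaptation; n_burn <- config$burn_in
  n_keep <- config$kept_samples; thin <- config$thin
  n_sweeps <- n_adapt + n_burn + n_keep * thin
  ut <- which(upper.tri(diag(K), diag = TRUE), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  cov_labels <- function(nm) paste0(nm, "[", ut[, 1], ",", ut[, 2], "]")
  labels <- c(
    unlist(lapply(seq_len(I), function(i) unlist(lapply(seq_len(J), function(j)
      paste0("theta[", i, ",", j, ",", seq_len(K), "]"))))),
    unlist(lapply(seq_len(I), function(i) paste0("rho[", i, ",", seq_len(K), "]"))),
    paste0("mu[", seq_len(K), "]"),
    cov_labels("Sigma"), cov_labels("phi"), "beta")
  P <- length(labels)
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    mu <- stats::runif(K, lower, upper)
    Omega <- stats::rWishart(1, v0, S0_Sigma)[, , 1]
    Lambda <- stats::rWishart(1, v0, S0_phi)[, , 1]
    Sigma <- chol2inv(chol(Omega))
    phi <- chol2inv(chol(Lambda))
    # clamp starting theta/rho into the box (see fit_hbmv)
    rho <- MASS::mvrnorm(I, mu, Sigma)
    if (I == 1L) rho <- matrix(rho, 1L, K)
    rho <- pmin(pmax(rho, rep(lower, each = I)), rep(upper, each = I))
    theta <- matrix(NA_real_, I * J, K)
    for (i in seq_len(I)) for (j in seq_len(J)) {
      theta[(i - 1L) * J + j, ] <-
        pmin(pmax(MASS::mvrnorm(1, rho[i, ], phi), lower), upper)
    }
    bet <- if (beta_fixed) beta else stats::runif(1, 1, 4)
    ll <- vapply(seq_len(I * J), function(u)
      loglik_cached(theta[u, ], K, bet, units[[u]]), 0)
    scales <- matrix(0.1, I * J, K); accc <- matrix(0, I * J, K)
    bscale <- 0.1; bacc <- 0
    kept <- matrix(NA_real_, n_keep, P); ki <- 0L
    for (sw in seq_len(n_sweeps)) {
      # prior independence refresh (see fit_hbmv)
      p_mu <- stats::runif(K, lower, upper)
      p_Omega <- stats::rWishart(1, v0, S0_Sigma)[, , 1]
      p_Lambda <- stats::rWishart(1, v0, S0_phi)[, , 1]
      p_Sigma <- chol2inv(chol(p_Omega))
      p_phi <- chol2inv(chol(p_Lambda))
      p_rho <- MASS::mvrnorm(I, p_mu, p_Sigma)
      if (I == 1L) p_rho <- matrix(p_rho, 1L, K)
      p_theta <- p_rho[rep(seq_len(I), each = J), , drop = FALSE] +
        MASS::mvrnorm(I * J, rep(0, K), p_phi)
      if (I * J == 1L) p_theta <- matrix(p_theta, 1L, K)
      p_bet <- if (beta_fixed) bet else stats::runif(1, 1, 4)
      p_ll <- vapply(seq_len(I * J), function(u)
        loglik_cached(p_theta[u, ], K, p_bet, units[[u]]), 0)
      if (isTRUE(log(stats::runif(1)) < sum(p_ll) - sum(ll))) {
        mu <- p_mu; Omega <- p_Omega; Lambda <- p_Lambda
        Sigma <- p_Sigma; phi <- p_phi
        rho <- p_rho; theta <- p_theta; bet <- p_bet; ll <- p_ll
      }
      R_phi <- chol(phi)
      # theta | rest: MVN(rho_i, phi) prior, MH on each component
      for (i in seq_len(I)) for (j in seq_len(J)) {
        u <- (i - 1L) * J + j
        if (!has_data[u]) {
          theta[u, ] <- rho[i, ] + drop(crossprod(R_phi, stats::rnorm(K)))
        } else {
          up <- mh_update_theta(theta[u, ], K, ll[u], units[[u]], bet,
                                scales[u, ], mh_prior_mvn(rho[i, ], Lambda))
          theta[u, ] <- up$theta; ll[u] <- up$ll
          accc[u, ] <- accc[u, ] + up$acc
          # independence refresh from the conditional prior MVN(rho_i, phi)
          prop <- rho[i, ] + drop(crossprod(R_phi, stats::rnorm(K)))
          llp <- loglik_cached(prop, K, bet, units[[u]])
          if (isTRUE(log(stats::runif(1)) < llp - ll[u])) {
            theta[u, ] <- prop; ll[u] <- llp
          }
        }
      }
      # rho | rest: MVN posterior, common precision Omega + J * Lambda
      Prho <- Omega + J * Lambda
      Rrho <- chol(Prho)
      sum_theta <- if (J == 1L) theta else
        t(vapply(seq_len(I), function(i)
          colSums(theta[((i - 1L) * J + 1L):(i * J), , drop = FALSE]), numeric(K)))
      bvec <- Omega %*% mu
      means <- backsolve(Rrho, forwardsolve(t(Rrho), bvec[, 1] + Lambda %*% t(sum_theta)))
      rho <- t(means + backsolve(Rrho, matrix(stats::rnorm(K * I), K, I)))
      # mu | rho: per-dimension truncated normal (box prior)
      rbar <- colMeans(rho)
      for (k in seq_len(K)) {
        cmean <- rbar[k] - sum(Omega[k, -k] * (mu[-k] - rbar[-k])) / Omega[k, k]
        mu[k] <- rtruncnorm(1, cmean, sqrt(1 / (I * Omega[k, k])),
                            lower[k], upper[k])
      }
      # Omega, Lambda | rest: conjugate Wishart
      cr <- rho - outer(rep(1, I), mu)
      Omega <- stats::rWishart(1, v0 + I,
                               chol2inv(chol(solve(S0_Sigma) + crossprod(cr))))[, , 1]
      rho_exp <- rho[rep(seq_len(I), each = J), , drop = FALSE]
      ct <- theta - rho_exp
      Lambda <- stats::rWishart(1, v0 + I * J,
                                chol2inv(chol(solve(S0_phi) + crossprod(ct))))[, , 1]
      Sigma <- chol2inv(chol(Omega))
      phi <- chol2inv(chol(Lambda))
      # beta | rest
      if (!beta_fixed) {
        bp <- bet + stats::rnorm(1, 0, bscale)
        if (bp >= 1 && bp <= 4) {
          llp <- vapply(seq_len(I * J), function(u)
            if (has_data[u]) loglik_cached(theta[u, ], K, bp, units[[u]]) else 0, 0)
          if (isTRUE(log(stats::runif(1)) < sum(llp) - sum(ll))) {
            bet <- bp; ll <- llp; bacc <- bacc + 1
          }
        }
      }
      if (sw <= n_adapt && sw %% 25L == 0L) {
        scales <- adapt_scales(scales, accc, 25); accc[] <- 0
        if (!beta_fixed) {
          bscale <- adapt_scales(bscale, bacc, 25); bacc <- 0
        }
      }
      if (sw > n_adapt + n_burn && (sw - n_adapt - n_burn) %% thin == 0L) {
        ki <- ki + 1L
        kept[ki, ] <- c(as.vector(t(theta)), as.vector(t(rho)), mu,
                        Sigma[ut], phi[ut], bet)
      }
    }
    chains[[ch]] <- kept
  }
  post <- finish_posterior(chains, labels, "hbmc", K, du$subjects, du$tests,
                           config, if (beta_fixed) beta else NULL)
  post$structure <- structure
  post
}

#' Wishart scale matrices from an HBMv fit
#'
#' Builds the covariance scale matrices conventionally passed to [fit_hbmc()]:
#' `Sigma` is the covariance of the estimated (posterior-mean) parameter
#' vectors across subjects, and `phi` is the HBMv's own estimate of the
#' test-level dispersion, the diagonal matrix of posterior-mean `eps_k^2`
#' (the variance model has no test-level covariance to carry over). A small
#' ridge keeps both positive-definite.
#'
#' @param posterior An `mcff_posterior` from [fit_hbmv()].
#' @param ridge Diagonal jitter added to both matrices (default 1e-4).
#' @return List with matrices `Sigma` and `phi`.
#' @export
hbmv_scale_matrices <- function(posterior, ridge = 1e-4) {
  stopifnot(inherits(posterior, "mcff_posterior"), posterior$model == "hbmv")
  K <- posterior$K
  I <- length(posterior$subjects)
  means <- matrix(NA_real_, I, K)
  for (i in seq_len(I)) {
    means[i, ] <- colMeans(theta_draws(posterior, posterior$subjects[i],
                                       posterior$tests[1]))
  }
  Sigma <- if (I >= 2) stats::cov(means) else diag(K)
  eps2 <- colMeans(param_draws(posterior, "eps")^2)
  list(Sigma = Sigma + diag(ridge, K),
       phi = diag(as.numeric(eps2), K) + diag(ridge, K))
}
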