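#' Posterior learning-curve estimate
#'
#' Pushes every posterior draw of `theta` through the MCFF learning curve and
#' summarizes the resulting per-trial posterior by its mean and the half width
#' of the central 68.2% credible interval (HWCI; the 15.9th to 84.1st
#' percentile range halved), in log10 threshold units.
#'
#' @param draws Matrix of posterior draws of `theta` (rows = draws, columns =
#'   the K dimensions), e.g. from [theta_draws()].
#' @param structure A [session_structure()].
#' @param K Model order; defaults to `ncol(draws)`.
#' @return An object of class `learning_curve`: a data frame with columns
#'   `trial`, `session`, `mean`, `hwci`.
#' @export
curve_posterior <- function(draws, structure, K = ncol(draws)) {
  draws <- as.matrix(draws)
  stopifnot(nrow(draws) >= 1, inherits(structure, "session_structure"))
  lay <- trial_layout(structure)
  cache <- list(log10t = log10(lay$trial), session = lay$session,
                within = lay$within)
  xi <- t(apply(draws, 1, xi_curve, K = K, layout = cache,
                n_sessions = structure$n_sessions))
  if (nrow(draws) == 1L) xi <- matrix(xi, nrow = 1L)
  q <- apply(xi, 2, stats::quantile, probs = c(0.159, 0.841), names = FALSE)
  out <- data.frame(trial = lay$trial, session = lay$session,
                    mean = colMeans(xi), hwci = (q[2, ] - q[1, ]) / 2)
  class(out) <- c("learning_curve", "data.frame")
  out
}

#' Bayesian predictive information criterion (BPIC)
#'
#' Goodness of fit with a complexity penalty: `BPIC = Dbar + 2 * pD`, where
#' `Dbar` is the posterior mean of the deviance (-2 log likelihood of the
#' whole dataset) and `pD = Dbar - D(posterior mean parameters)` is the
#' effective number of parameters. Lower is better.
#'
#' @param posterior An `mcff_posterior` from any of the three fit functions.
#' @param trials The trial table the model was fitted to.
#' @param structure A [session_structure()].
#' @param psych A [psychometric_config()].
#' @param max_draws Deviance is averaged over at most this many evenly spaced
#'   pooled draws (default 1000).
#' @return Scalar BPIC, with attributes `Dbar`, `pD`.
#' @export
bpic <- function(posterior, trials, structure = posterior$structure,
                 psych = psychometric_config(), max_draws = 1000) {
  stopifnot(inherits(posterior, "mcff_posterior"))
  K <- posterior$K
  du <- build_units(trials, structure, psych,
                    subjects = posterior$subjects, tests = posterior$tests)
  beta_d <- if (is.null(posterior$beta_fixed)) drop(param_draws(posterior, "beta"))
            else NULL
  unit_draws <- list()
  for (i in seq_along(posterior$subjects)) {
    for (j in seq_along(posterior$tests)) {
      unit_draws[[(i - 1L) * du$J + j]] <-
        theta_draws(posterior, posterior$subjects[i], posterior$tests[j])
    }
  }
  n <- nrow(unit_draws[[1]])
  idx <- if (n > max_draws) unique(round(seq(1, n, length.out = max_draws)))
         else seq_len(n)
  dev <- numeric(length(idx))
  for (m in seq_along(idx)) {
    b <- if (is.null(beta_d)) posterior$beta_fixed else beta_d[idx[m]]
    ll <- 0
    for (u in seq_along(unit_draws)) {
      ll <- ll + loglik_cached(unit_draws[[u]][idx[m], ], K, b, du$units[[u]])
    }
    dev[m] <- -2 * ll
  }
  Dbar <- mean(dev)
  bbar <- if (is.null(beta_d)) posterior$beta_fixed else mean(beta_d)
  ll_hat <- 0
  for (u in seq_along(unit_draws)) {
    ll_hat <- ll_hat + loglik_cached(colMeans(unit_draws[[u]]), K, bbar,
                                     du$units[[u]])
  }
  pD <- Dbar - (-2 * ll_hat)
  structure(Dbar + 2 * pD, Dbar = Dbar, pD = pD)
}

#' Group-level posterior of the MCFF parameters
#'
#' Constructs the posterior of each group's mean parameter vector by
#' repeatedly (a) drawing one posterior sample of `theta` per subject, with
#' replacement and independently across subjects, and (b) averaging those
#' samples across the group's subjects; by default 15,000 repetitions.
#'
#' @param posterior An `mcff_posterior` from a joint fit ([fit_hbmv()] or
#'   [fit_hbmc()]).
#' @param groups Named assignment of subjects to groups: a data frame with
#'   columns `subject` and `group`, covering the fitted subjects.
#' @param n_samples Number of group-mean samples (default 15000).
#' @param test Test id used for the test-level draws (default the first).
#' @return An object of class `group_posterior`: a list with one
#'   `n_samples x K` matrix per group, named by group id.
#' @export
group_posterior <- function(posterior, groups, n_samples = 15000,
                            test = posterior$tests[1]) {
  stopifnot(inherits(posterior, "mcff_posterior"),
            all(c("subject", "group") %in% names(groups)))
  gids <- sort(unique(groups$group))
  out <- vector("list", length(gids))
  names(out) <- as.character(gids)
  for (g in seq_along(gids)) {
    subj <- groups$subject[groups$group == gids[g]]
    subj <- subj[subj %in% posterior$subjects]
    if (length(subj) == 0L) stop("group ", gids[g], " has no fitted subjects")
    acc <- matrix(0, n_samples, posterior$K)
    for (s in subj) {
      d <- theta_draws(posterior, s, test)
      acc <- acc + d[sample.int(nrow(d), n_samples, replace = TRUE), , drop = FALSE]
    }
    out[[g]] <- acc / length(subj)
  }
  structure(out, class = "group_posterior", K = posterior$K)
}

#' Per-subject posterior mean parameter vectors
#'
#' @param posterior An `mcff_posterior` from a joint fit.
#' @param test Test id (default the first).
#' @return Matrix (subjects x K) of posterior means, rownames the subject ids.
#' @export
subject_posterior_means <- function(posterior, test = posterior$tests[1]) {
  stopifnot(inherits(posterior, "mcff_posterior"))
  m <- t(vapply(posterior$subjects, function(s)
    colMeans(theta_draws(posterior, s, test)), numeric(posterior$K)))
  rownames(m) <- as.character(posterior$subjects)
  m
}

#' One-way MANOVA on group mean parameters
#'
#' Standard one-way MANOVA (Pillai's trace) on per-subject posterior-mean
#' parameter vectors grouped by training condition.
#'
#' @param means Matrix of per-subject posterior mean `theta` (subjects x K),
#'   e.g. from [subject_posterior_means()].
#' @param groups Group label per row of `means`.
#' @return List with `statistic` (Pillai's trace), `approx_f`, `df`,
#'   `p_value`, and the underlying `manova` fit.
#' @export
manova_groups <- function(means, groups) {
  means <- as.matrix(means)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("MANOVA requires >= 2 groups")
  if (nrow(means) - nlevels(groups) < ncol(means)) {
    stop("rank deficiency: need more subjects than parameters per group ",
         "(", nrow(means), " subjects, ", ncol(means), " parameters, ",
         nlevels(groups), " groups)")
  }
  fit <- stats::manova(means ~ groups)
  s <- summary(fit, test = "Pillai")$stats
  list(statistic = s[1, "Pillai"], approx_f = s[1, "approx F"],
       df = c(s[1, "num Df"], s[1, "den Df"]),
       p_value = s[1, "Pr(>F)"], fit = fit)
}

#' Pairwise linear discriminant analysis of group posteriors
#'
#' For each pair of groups, repeatedly splits each group's posterior samples
#' into 90% training / 10% held-out sets, fits a linear discriminant (equal
#' priors) on the training split, and scores held-out classification
#' accuracy; reports the mean and standard deviation over repeats.
#'
#' @param gp A [group_posterior()].
#' @param train_frac Training fraction (default 0.9).
#' @param repeats Number of random splits (default 100).
#' @return List of matrices `mean` and `sd` (accuracy in percent, lower
#'   triangle filled, dimnames = group ids).
#' @export
lda_groups <- function(gp, train_frac = 0.9, repeats = 100) {
  stopifnot(inherits(gp, "group_posterior"), train_frac > 0, train_frac < 1)
  gids <- names(gp)
  G <- length(gids)
  acc_mean <- acc_sd <- matrix(NA_real_, G, G, dimnames = list(gids, gids))
  for (a in seq_len(G - 1)) {
    for (b in (a + 1):G) {
      xa <- gp[[a]]; xb <- gp[[b]]
      accs <- numeric(repeats)
      for (r in seq_len(repeats)) {
        ia <- sample.int(nrow(xa), round(train_frac * nrow(xa)))
        ib <- sample.int(nrow(xb), round(train_frac * nrow(xb)))
        train_x <- rbind(xa[ia, , drop = FALSE], xb[ib, , drop = FALSE])
        train_y <- factor(rep(c(gids[a], gids[b]), c(length(ia), length(ib))))
        test_x <- rbind(xa[-ia, , drop = FALSE], xb[-ib, , drop = FALSE])
        test_y <- factor(rep(c(gids[a], gids[b]),
                             c(nrow(xa) - length(ia), nrow(xb) - length(ib))))
        fit <- tryCatch(
          MASS::lda(train_x, grouping = train_y, prior = c(0.5, 0.5)),
          error = function(e) {
            # singular within-class covariance: retry on jittered samples
            MASS::lda(train_x + stats::rnorm(length(train_x), 0, 1e-8),
                      grouping = train_y, prior = c(0.5, 0.5))
          })
        pred <- stats::predict(fit, test_x)$class
        accs[r] <- mean(pred == test_y)
      }
      acc_mean[b, a] <- 100 * mean(accs)
      acc_sd[b, a] <- 100 * stats::sd(accs)
    }
  }
  list(mean = acc_mean, sd = acc_sd)
}

#' Predict a subject's learning curve from partial data
#'
#' Refits the covariance-hierarchy model (HBMc) on a dataset in which one
#' target subject's trials are truncated to their first 0, 1 or 2 sessions
#' while all other subjects keep their full data, then reads off the target
#' subject's learning-curve posterior across all sessions. With no data the
#' prediction is driven entirely by the population posterior; each added
#' session sharpens it.
#'
#' @param trials Full trial table for all subjects.
#' @param subject Target subject id.
#' @param n_sessions_data Number of leading sessions of the target subject's
#'   data to retain (0, 1 or 2 in the canonical analysis).
#' @param bounds A [prior_bounds()].
#' @param config A [sampler_config()].
#' @param structure A [session_structure()].
#' @param psych A [psychometric_config()].
#' @param scale Wishart scale matrices for [fit_hbmc()] (optional).
#' @param beta Fixed slope or `NULL` to sample (passed to [fit_hbmc()]).
#' @param reference Optional `learning_curve` of the same subject estimated
#'   from full data, for comparison metrics.
#' @return List with `curve` (the predicted [curve_posterior()]),
#'   `posterior` (the truncated-data HBMc fit), and, when `reference` is
#'   given, `correlation` (Pearson correlation between predicted and
#'   reference mean curves) and `hwci_ratio` (mean predicted HWCI over mean
#'   reference HWCI).
#' @export
predict_curve <- function(trials, subject, n_sessions_data, bounds,
                          config = sampler_config("hbmc"),
                          structure = session_structure(),
                          psych = psychometric_config(), scale = NULL,
                          beta = NULL, reference = NULL) {
  stopifnot(n_sessions_data >= 0, subject %in% trials$subject)
  keep <- trials$subject != subject | trials$session <= n_sessions_data
  subjects <- sort(unique(trials$subject))
  post <- fit_hbmc(trials[keep, , drop = FALSE], bounds, config, structure,
                   psych, scale = scale, beta = beta, subjects = subjects)
  curve <- curve_posterior(theta_draws(post, subject), structure)
  out <- list(curve = curve, posterior = post)
  if (!is.null(reference)) {
    out$correlation <- stats::cor(curve$mean, reference$mean)
    out$hwci_ratio <- mean(curve$hwci) / mean(reference$hwci)
  }
  out
}
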