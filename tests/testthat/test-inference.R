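test_that("between/within variance ratio behaves at its anchors", {
  # identical chains: no between-chain variance
  m <- matrix(rep(rnorm(100), each = 3), nrow = 3)
  expect_equal(convergence_ratio(m), 1, tolerance = 0.01)
  # chains stuck at disjoint constants: pure between-chain variance
  expect_gt(convergence_ratio(rbind(rep(0, 50), rep(10, 50))), 10)
  # iid chains from the same distribution
  set.seed(21)
  m <- matrix(rnorm(3 * 5000), nrow = 3)
  expect_gt(convergence_ratio(m), 0.99)
  expect_lt(convergence_ratio(m), 1.02)
  expect_error(convergence_ratio(matrix(1:10, nrow = 1)), ">= 2 chains")
  expect_error(convergence_ratio(1:10), ">= 2 chains")
})

test_that("BIP with no trials samples the uniform prior", {
  b <- prior_bounds(6)
  cfg <- quick_config("bip", kept_samples = 1500, thin = 1, burn_in = 10,
                      adaptation = 0)
  post <- fit_bip(empty_trials(), b, cfg, session_structure())
  d <- theta_draws(post)
  expect_equal(dim(d), c(2 * 1500, 6))
  mid <- (b$lower + b$upper) / 2
  halfw <- (b$upper - b$lower) / 2
  # mean near the midpoint, spread filling the box, support respected
  expect_true(all(abs(colMeans(d) - mid) < 0.12 * halfw))
  expect_true(all(apply(d, 2, min) >= b$lower))
  expect_true(all(apply(d, 2, max) <= b$upper))
  expect_true(all(apply(d, 2, max) - apply(d, 2, min) > 1.8 * halfw))
})

test_that("BIP recovers known parameters from simulated trials", {
  s <- session_structure(6, 320)
  truth <- c(-1, -0.6)
  set.seed(31)
  sim <- simulate_subject(mcff_params(truth, 2), s, "high")
  cfg <- quick_config("bip", kept_samples = 400, thin = 2, burn_in = 400,
                      adaptation = 400, seed = 31)
  post <- fit_bip(sim$trials, prior_bounds(2), cfg, s)
  d <- theta_draws(post)
  pm <- colMeans(d); psd <- apply(d, 2, sd)
  expect_true(all(abs(pm - truth) < 3 * psd))
  expect_true(all(d >= -3 & d <= -0.5))  # posterior respects the prior box
  # determinism: same seed, same draws
  post2 <- fit_bip(sim$trials, prior_bounds(2), cfg, s)
  expect_identical(post$draws, post2$draws)
  expect_s3_class(post, "mcff_posterior")
  expect_equal(post$model, "bip")
})

test_that("HBMv returns the full parameter inventory and recovers the
           population mean", {
  s <- session_structure(2, 160)
  gr <- data.frame(group = 1, n_subjects = 8, condition = "high",
                   feedback = FALSE)
  spec <- population_spec(K = 2, mu = c(-1, -0.6), Sigma = diag(0.15^2, 2),
                          phi = diag(0.05^2, 2), groups = gr, structure = s,
                          group_mu_offsets = list(numeric(2)), seed = 7)
  sim <- simulate_population(spec)
  cfg <- quick_config("hbmv", kept_samples = 300, thin = 2, burn_in = 400,
                      adaptation = 400, seed = 3)
  post <- fit_hbmv(sim$trials, prior_bounds(2), cfg, s)
  labels <- dimnames(post$draws)[[3]]
  # theta (8x2), rho (8x2), mu, sigma, eps (2 each), beta
  expect_equal(length(labels), 16 + 16 + 2 + 2 + 2 + 1)
  expect_true(all(c("theta[1,1,1]", "rho[8,2]", "mu[1]", "sigma[2]",
                    "eps[1]", "beta") %in% labels))
  mu_d <- param_draws(post, "mu")
  pm <- colMeans(mu_d); psd <- apply(mu_d, 2, sd)
  expect_true(all(abs(pm - c(-1, -0.6)) < 3.5 * psd))
  expect_true(all(mu_d >= -3 & mu_d <= -0.5))
  # beta sampled within its prior support
  beta_d <- param_draws(post, "beta")
  expect_true(all(beta_d >= 1 & beta_d <= 4))
  # sigma, eps positive
  expect_true(all(param_draws(post, "sigma") > 0))
  expect_true(all(param_draws(post, "eps") > 0))
})

test_that("HBMc returns covariance posteriors and accepts HBMv scale
           matrices", {
  s <- session_structure(2, 160)
  gr <- data.frame(group = 1, n_subjects = 8, condition = "high",
                   feedback = FALSE)
  spec <- population_spec(K = 2, mu = c(-1, -0.6), Sigma = diag(0.15^2, 2),
                          phi = diag(0.05^2, 2), groups = gr, structure = s,
                          group_mu_offsets = list(numeric(2)), seed = 7)
  sim <- simulate_population(spec)
  cfgv <- quick_config("hbmv", kept_samples = 250, thin = 2, burn_in = 400,
                       adaptation = 400, seed = 3)
  pv <- fit_hbmv(sim$trials, prior_bounds(2), cfgv, s, beta = 2)
  sc <- hbmv_scale_matrices(pv)
  expect_true(all(eigen(sc$Sigma)$values > 0))
  expect_true(all(eigen(sc$phi)$values > 0))

  cfgc <- quick_config("hbmc", kept_samples = 300, thin = 2, burn_in = 600,
                       adaptation = 400, seed = 5)
  post <- fit_hbmc(sim$trials, prior_bounds(2), cfgc, s, scale = sc, beta = 2)
  labels <- dimnames(post$draws)[[3]]
  expect_true(all(c("Sigma[1,1]", "Sigma[1,2]", "Sigma[2,2]", "phi[1,1]",
                    "phi[2,2]", "mu[1]", "rho[4,2]") %in% labels))
  # covariance diagonal draws are positive, mu respects the box
  expect_true(all(param_draws(post, "Sigma")[, c("Sigma[1,1]", "Sigma[2,2]")] > 0))
  expect_true(all(param_draws(post, "mu") >= -3 & param_draws(post, "mu") <= -0.5))
  mu_d <- param_draws(post, "mu")
  expect_true(all(abs(colMeans(mu_d) - c(-1, -0.6)) < 3.5 * apply(mu_d, 2, sd)))

  expect_error(fit_hbmc(sim$trials, prior_bounds(2), cfgc, s,
                        scale = list(Sigma = matrix(c(1, 2, 2, 1), 2),
                                     phi = diag(2))),
               "positive-definite")
})

test_that("hierarchy shrinks a data-poor subject toward the population", {
  s <- session_structure(2, 160)
  gr <- data.frame(group = 1, n_subjects = 10, condition = "high",
                   feedback = FALSE)
  spec <- population_spec(K = 2, mu = c(-1, -0.6), Sigma = diag(0.1^2, 2),
                          phi = diag(0.03^2, 2), groups = gr, structure = s,
                          group_mu_offsets = list(numeric(2)), seed = 17)
  sim <- simulate_population(spec)
  # subject 1 keeps only a tenth of their trials
  keep <- sim$trials$subject != 1 | sim$trials$global_trial <= 32
  trials <- sim$trials[keep, ]

  cfgb <- quick_config("bip", kept_samples = 400, thin = 2, burn_in = 400,
                       adaptation = 400, seed = 2)
  pb <- fit_bip(trials[trials$subject == 1, ], prior_bounds(2), cfgb, s)
  cfgv <- quick_config("hbmv", kept_samples = 250, thin = 2, burn_in = 300,
                       adaptation = 300, seed = 2)
  pv <- fit_hbmv(trials, prior_bounds(2), cfgv, s, beta = 2)
  cfgc <- quick_config("hbmc", kept_samples = 400, thin = 2, burn_in = 600,
                       adaptation = 400, seed = 2)
  pc <- fit_hbmc(trials, prior_bounds(2), cfgc, s,
                 scale = hbmv_scale_matrices(pv), beta = 2)

  pop_mean <- colMeans(subject_posterior_means(pc)[-1, ])
  bip_mean <- colMeans(theta_draws(pb))
  hbm_mean <- colMeans(theta_draws(pc, 1))
  # HBMc pulls the sparse subject toward the population relative to the BIP
  expect_lt(sum((hbm_mean - pop_mean)^2), sum((bip_mean - pop_mean)^2))
  # and tightens the learning-curve posterior
  hw_b <- mean(curve_posterior(theta_draws(pb), s)$hwci)
  hw_c <- mean(curve_posterior(theta_draws(pc, 1), s)$hwci)
  expect_lt(hw_c, hw_b)
})

test_that("non-convergence is flagged, not raised", {
  s <- session_structure(2, 80)
  set.seed(41)
  sim <- simulate_subject(mcff_params(c(-1, -0.6), 2), s, "high")
  cfg <- quick_config("bip", kept_samples = 20, thin = 1, burn_in = 5,
                      adaptation = 20, seed = 1)
  expect_no_error(post <- fit_bip(sim$trials, prior_bounds(2), cfg, s))
  expect_false(is.na(post$converged))
  expect_named(post$convergence)
  expect_equal(length(post$convergence), 2)
})
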