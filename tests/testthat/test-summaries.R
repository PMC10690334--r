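test_that("curve posterior mean and HWCI follow the percentile rule", {
  s <- session_structure(2, 20)
  th <- c(-1, -0.6)

  # degenerate posterior: zero credible width, mean equals the point curve
  cv <- curve_posterior(matrix(th, 10, 2, byrow = TRUE), s)
  expect_equal(cv$hwci, rep(0, 40))
  expect_equal(cv$mean, threshold_curve(mcff_params(th, 2), s))
  expect_equal(cv$trial, 1:40)
  expect_true(all(cv$hwci >= 0))

  # two equally-weighted draws differing only in the initial threshold b:
  # check against a direct two-point quantile computation
  b_lo <- -0.35; b_hi <- -0.15
  d2 <- rbind(c(-1, log10(-b_lo)), c(-1, log10(-b_hi)))
  cv2 <- curve_posterior(d2, s)
  q_lo <- ora_quantile7(c(b_lo, b_hi), 0.159)
  q_hi <- ora_quantile7(c(b_lo, b_hi), 0.841)
  expect_equal(cv2$hwci, rep((q_hi - q_lo) / 2, 40), tolerance = 1e-12)
  # the curve is linear in b, so the mean curve passes through the mean b
  mid <- mcff_params(c(-1, log10(-(b_lo + b_hi) / 2)), 2)
  expect_equal(cv2$mean, threshold_curve(mid, s), tolerance = 1e-12)

  # quantile correctness against raw order statistics on random draws
  set.seed(55)
  d <- cbind(runif(101, -2, -1), runif(101, -1, -0.5))
  cv3 <- curve_posterior(d, s)
  xi <- t(apply(d, 1, function(t) threshold_curve(mcff_params(t, 2), s)))
  for (t in c(1, 17, 40)) {
    expect_equal(cv3$hwci[t],
                 (ora_quantile7(xi[, t], 0.841) - ora_quantile7(xi[, t], 0.159)) / 2,
                 tolerance = 1e-12)
    expect_equal(cv3$mean[t], mean(xi[, t]), tolerance = 1e-12)
  }
})

test_that("BPIC reduces to the plug-in deviance for a point-mass posterior
           and grows with parameter uncertainty", {
  s <- session_structure(2, 100)
  set.seed(61)
  sim <- simulate_subject(mcff_params(c(-1, -0.6), 2), s, "high")
  post <- make_bip_posterior(matrix(c(-1, -0.6), 40, 2, byrow = TRUE),
                             structure = s)
  b <- bpic(post, sim$trials, s)
  D_hat <- -2 * trial_loglik(mcff_params(c(-1, -0.6), 2), sim$trials, s)
  expect_equal(attr(b, "pD"), 0, tolerance = 1e-9)
  expect_equal(as.numeric(b), D_hat, tolerance = 1e-9)

  # spreading the posterior around the same mean adds a positive complexity
  # penalty
  set.seed(62)
  spread <- cbind(rnorm(40, -1, 0.05), rnorm(40, -0.6, 0.05))
  spread <- sweep(spread, 2, colMeans(spread) - c(-1, -0.6))
  b2 <- bpic(make_bip_posterior(spread, structure = s), sim$trials, s)
  expect_gt(attr(b2, "pD"), 0)
  expect_gt(as.numeric(b2), as.numeric(b))
})

test_that("BPIC prefers the generating model order", {
  s <- session_structure(6, 320)
  # observer with pronounced forgetting and relearning components
  th14 <- c(-1, -0.55, -4, rep(-1.3, 5), -2.5, rep(-0.9, 5))
  set.seed(63)
  sim <- simulate_subject(mcff_params(th14, 14), s, "high")
  cfg <- quick_config("bip", kept_samples = 300, thin = 2, burn_in = 400,
                      adaptation = 400, seed = 63)
  p14 <- fit_bip(sim$trials, prior_bounds(14), cfg, s)
  p2 <- fit_bip(sim$trials, prior_bounds(2), cfg, s)
  expect_lt(bpic(p14, sim$trials, s), bpic(p2, sim$trials, s))
})

test_that("group posteriors average one resampled draw per subject", {
  s <- session_structure(2, 20)
  K <- 2
  set.seed(71)
  # hand-built joint posterior for 3 subjects (hbmv-format labels)
  I <- 3; n <- 400
  subj_draws <- lapply(1:I, function(i)
    cbind(rnorm(n, -1 - 0.1 * i, 0.02 * i), rnorm(n, -0.6, 0.01 * i)))
  labels <- c(unlist(lapply(1:I, function(i) paste0("theta[", i, ",1,", 1:K, "]"))),
              "beta")
  arr <- array(NA_real_, c(2, n / 2, length(labels)),
               dimnames = list(NULL, NULL, labels))
  for (i in 1:I) for (k in 1:K) {
    v <- subj_draws[[i]][, k]
    arr[1, , (i - 1) * K + k] <- v[1:(n / 2)]
    arr[2, , (i - 1) * K + k] <- v[(n / 2 + 1):n]
  }
  arr[, , "beta"] <- 2
  post <- structure(list(model = "hbmv", K = K, draws = arr, subjects = 1:I,
                         tests = 1L,
                         convergence = setNames(rep(NA_real_, length(labels)), labels),
                         converged = NA, config = sampler_config("hbmv"),
                         beta_fixed = NULL, structure = s),
                    class = "mcff_posterior")

  # single-subject group: the group posterior is a resample of that subject
  gp1 <- group_posterior(post, data.frame(subject = 1, group = 1),
                         n_samples = 20000)
  expect_equal(colMeans(gp1[["1"]]), colMeans(subj_draws[[1]]),
               tolerance = 0.005, ignore_attr = TRUE)
  expect_equal(apply(gp1[["1"]], 2, sd), apply(subj_draws[[1]], 2, sd),
               tolerance = 0.05, ignore_attr = TRUE)

  # full group: variance of the mean of independent resamples
  gmap <- data.frame(subject = 1:3, group = 9)
  gp <- group_posterior(post, gmap, n_samples = 20000)
  expect_equal(dim(gp[["9"]]), c(20000, 2))
  want_mean <- Reduce(`+`, lapply(subj_draws, colMeans)) / 3
  want_var <- Reduce(`+`, lapply(subj_draws, function(d) apply(d, 2, var))) / 9
  expect_equal(colMeans(gp[["9"]]), want_mean, tolerance = 0.01,
               ignore_attr = TRUE)
  expect_equal(apply(gp[["9"]], 2, var), want_var,
               tolerance = 0.1, ignore_attr = TRUE)

  # point-mass subject posteriors collapse the group cloud
  arr2 <- arr
  for (i in 1:I) for (k in 1:K) arr2[, , (i - 1) * K + k] <- c(-1, -0.6)[k]
  post2 <- post; post2$draws <- arr2
  gp2 <- group_posterior(post2, gmap, n_samples = 100)
  expect_true(all(abs(sweep(gp2[["9"]], 2, c(-1, -0.6))) < 1e-12))
})

test_that("MANOVA separates separated groups and not relabeled ones", {
  set.seed(81)
  K <- 3
  base <- matrix(rnorm(30 * K, 0, 1), 30, K)
  # identical groups: the two groups contain the same subject vectors
  means_same <- rbind(base[1:10, ], base[1:10, ])
  g_same <- rep(1:2, each = 10)
  mv <- manova_groups(means_same, g_same)
  expect_gt(mv$p_value, 0.99)
  expect_lt(mv$statistic, 1e-6)

  # two groups separated by ten pooled SDs in dimension 1
  sep <- base
  sep[16:30, 1] <- sep[16:30, 1] + 10
  g <- rep(1:2, c(15, 15))
  mv2 <- manova_groups(sep, g)
  expect_lt(mv2$p_value, 1e-3)

  # permuting the labels destroys the separation
  gp <- sample(g)
  mv3 <- manova_groups(sep, gp)
  expect_gt(mv3$p_value, 0.05)

  expect_error(manova_groups(base[1:4, ], rep(1:2, 2)), "rank")
  expect_error(manova_groups(base, rep(1, 30)), ">= 2 groups")
})

test_that("LDA accuracy tracks group separation", {
  set.seed(91)
  n <- 400; K <- 2
  cloud <- function(mu) cbind(rnorm(n, mu[1], 1), rnorm(n, mu[2], 1))
  gp_same <- structure(list("1" = cloud(c(0, 0)), "2" = cloud(c(0, 0))),
                       class = "group_posterior", K = K)
  ld <- lda_groups(gp_same, repeats = 30)
  expect_lt(abs(ld$mean["2", "1"] - 50), 10)

  gp_far <- structure(list("1" = cloud(c(0, 0)), "2" = cloud(c(30, 0))),
                      class = "group_posterior", K = K)
  ld_far <- lda_groups(gp_far, repeats = 10)
  expect_gt(ld_far$mean["2", "1"], 99)

  # monotone in separation at fixed covariance
  accs <- vapply(c(0.5, 1.5, 4), function(d) {
    gp <- structure(list("1" = cloud(c(0, 0)), "2" = cloud(c(d, 0))),
                    class = "group_posterior", K = K)
    lda_groups(gp, repeats = 20)$mean["2", "1"]
  }, 0)
  expect_true(all(diff(accs) > 0))
})

test_that("prediction from a full dataset reproduces the standard fit", {
  s <- session_structure(2, 60)
  gr <- data.frame(group = 1, n_subjects = 4, condition = "high",
                   feedback = FALSE)
  spec <- population_spec(K = 2, mu = c(-1, -0.6), Sigma = diag(0.1^2, 2),
                          phi = diag(0.03^2, 2), groups = gr, structure = s,
                          group_mu_offsets = list(numeric(2)), seed = 23)
  sim <- simulate_population(spec)
  cfg <- quick_config("hbmc", kept_samples = 120, thin = 1, burn_in = 150,
                      adaptation = 150, seed = 8)
  full <- fit_hbmc(sim$trials, prior_bounds(2), cfg, s, beta = 2)
  ref <- curve_posterior(theta_draws(full, 1), s)
  # keeping every session is the same dataset, same seed: identical result
  pred <- predict_curve(sim$trials, 1, 2, prior_bounds(2), cfg, s,
                        beta = 2, reference = ref)
  expect_equal(pred$curve$mean, ref$mean)
  expect_equal(pred$curve$hwci, ref$hwci)
  expect_equal(pred$correlation, 1)
  expect_equal(pred$hwci_ratio, 1)
})
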