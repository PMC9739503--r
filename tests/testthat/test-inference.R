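test_that("training sets merge sources with weights and variance rule", {
  m <- data.frame(time_days = 1:10, value_scaled = rep(0.4, 10))
  s <- data.frame(time_days = 10.5 + 1:8, value_scaled = rep(0.4, 8))
  tr <- build_training_set(m, s)
  expect_equal(nrow(tr), 18)
  expect_equal(sum(tr$weight == 5), 10)
  expect_equal(sum(tr$weight == 1), 8)
  expect_equal(unique(tr$sigma2[tr$source == "measured"]), 0.04)
  expect_equal(unique(tr$sigma2[tr$source == "simulated"]), 0.20)
  # near-zero values keep the assay variance floor
  tiny <- build_training_set(data.frame(time_days = 1, value_scaled = 0))
  expect_equal(tiny$sigma2, 0.10 * 0.05)
  # measured-only set and overlap rejection
  expect_equal(nrow(build_training_set(m)), 10)
  expect_error(build_training_set(m, data.frame(time_days = 5,
                                                value_scaled = 1)),
               "disjoint")
})

test_that("single-parameter WNLS agrees with the log-linear oracle", {
  alpha_true <- 2.5
  t <- seq(0.2, 5, 0.2)
  y <- 0.8 * exp(-alpha_true * t)
  training <- build_training_set(data.frame(time_days = t, value_scaled = y))
  p <- e2_params(e1 = 0, e2 = 0, e3 = 0, e4 = 0, a3 = 0, E2_0 = 0.8)
  fit <- wnls_fit(training, p, zero_forcing(), constant_p4(0.5), c(0, 5),
                  theta_init = c(alpha_E2 = 1.8))
  oracle <- -unname(coef(lm(log(y) ~ t))[2])
  expect_equal(unname(fit$theta[["alpha_E2"]]), oracle, tolerance = 1e-4)
  expect_equal(unname(fit$theta[["alpha_E2"]]), alpha_true, tolerance = 1e-4)
  expect_lt(fit$objective, 1e-6)
})

test_that("zero-noise fits recover perturbed parameters to machine noise", {
  cyc <- fixture_cycle(noise_frac_measured = 0)
  tp <- fixture_params()
  obs <- generate_observations(tp, cyc)
  forcing <- class_volume_forcing(cyc$tracks, t0 = 0, scale = "data")
  training <- build_training_set(obs$e2_measured)
  truth <- c(e3 = tp$e3, alpha_E2 = tp$alpha_E2)
  fit <- wnls_fit(training, tp, forcing, cyc$p4, c(0, 23),
                  theta_init = truth * c(1.2, 0.8))
  expect_equal(unname(fit$theta), unname(truth), tolerance = 1e-3)
  expect_lt(fit$objective, 1e-3)
})

test_that("weights rescale the objective but not the equal-weight optimum", {
  m <- data.frame(time_days = seq(0.5, 4, 0.5),
                  value_scaled = 0.9 * exp(-2 * seq(0.5, 4, 0.5)))
  p <- e2_params(e1 = 0, e2 = 0, e3 = 0, e4 = 0, a3 = 0, E2_0 = 0.9)
  tr5 <- build_training_set(m, weight_measured = 5)
  tr1 <- build_training_set(m, weight_measured = 1)
  f5 <- wnls_fit(tr5, p, zero_forcing(), constant_p4(0.3), c(0, 4),
                 theta_init = c(alpha_E2 = 1.5))
  f1 <- wnls_fit(tr1, p, zero_forcing(), constant_p4(0.3), c(0, 4),
                 theta_init = c(alpha_E2 = 1.5))
  expect_equal(f5$theta, f1$theta, tolerance = 1e-6)
})

test_that("log prior is flat on the ordered 0.6L-1.6L box", {
  theta_hat <- c(e3 = 7.2019, T = 0.0020)
  L <- log10(theta_hat)
  expect_equal(log_prior(L, L), 0)
  # T support from the identified value: [1.6L, 0.6L] = [-4.318, -1.619]
  b <- prior_bounds(L)
  expect_equal(unname(b$lower[2]), 1.6 * log10(0.0020), tolerance = 1e-12)
  expect_equal(unname(b$upper[2]), 0.6 * log10(0.0020), tolerance = 1e-12)
  expect_equal(log_prior(c(L[1], -4.0), L), 0)
  expect_equal(log_prior(c(L[1], -4.4), L), -Inf)
  expect_equal(log_prior(c(1.61 * L[1], L[2]), L), -Inf)
  # near-degenerate interval (L close to 0) is widened to 0.2 log-units
  b2 <- prior_bounds(log10(c(x = 1.01)))
  expect_gte(b2$upper - b2$lower, 0.2 - 1e-12)
})

test_that("log likelihood is Gaussian with per-point variances", {
  p <- e2_params(e1 = 0, e2 = 0, e3 = 0, e4 = 0, a3 = 0, E2_0 = 0.8,
                 alpha_E2 = 2)
  t1 <- 1.5
  pred <- 0.8 * exp(-2 * t1)
  tr <- build_training_set(data.frame(time_days = t1, value_scaled = pred))
  tr$sigma2 <- 0.04
  ll0 <- log_likelihood(c(alpha_E2 = 2), tr, p, zero_forcing(),
                        constant_p4(0.5), c(0, 3))
  expect_equal(ll0, -0.5 * log(2 * pi * 0.04), tolerance = 1e-6)
  # shifting the observation by 0.1 subtracts 0.1^2/(2*0.04) = 0.125
  tr2 <- tr; tr2$value_scaled <- pred + 0.1
  ll1 <- log_likelihood(c(alpha_E2 = 2), tr2, p, zero_forcing(),
                        constant_p4(0.5), c(0, 3))
  expect_equal(ll1, ll0 - 0.125, tolerance = 1e-4)
  # additivity over points
  trb <- build_training_set(data.frame(time_days = c(t1, 2.5),
                                       value_scaled = c(pred, 0.1)))
  trb$sigma2 <- 0.04
  lla <- log_likelihood(c(alpha_E2 = 2), trb[1, ], p, zero_forcing(),
                        constant_p4(0.5), c(0, 3))
  llb <- log_likelihood(c(alpha_E2 = 2), trb[2, ], p, zero_forcing(),
                        constant_p4(0.5), c(0, 3))
  llab <- log_likelihood(c(alpha_E2 = 2), trb, p, zero_forcing(),
                         constant_p4(0.5), c(0, 3))
  expect_equal(llab, lla + llb, tolerance = 1e-8)
})

test_that("posterior factorises as prior plus likelihood", {
  cyc <- fixture_cycle()
  tp <- fixture_params()
  obs <- generate_observations(tp, cyc)
  forcing <- class_volume_forcing(cyc$tracks, t0 = 0, scale = "data")
  training <- build_training_set(obs$e2_measured)
  theta_hat <- c(e3 = tp$e3, alpha_E2 = tp$alpha_E2)
  lp <- make_log_posterior(training, tp, forcing, cyc$p4, c(0, 23),
                           theta_hat = theta_hat)
  x <- log10(theta_hat) * 1.05
  manual <- log_prior(x, log10(theta_hat)) +
    log_likelihood(stats::setNames(10^x, names(theta_hat)), training, tp,
                   forcing, cyc$p4, c(0, 23))
  expect_equal(lp(x), manual, tolerance = 1e-10)
  expect_equal(lp(log10(theta_hat) * 3), -Inf)
})

test_that("the sampler reproduces known distributions", {
  # flat posterior over a box: thinned marginals are uniform
  lp_flat <- function(th) if (all(th >= 0 & th <= 1)) 0 else -Inf
  dr <- mcmc_sample(lp_flat, c(0.5, 0.5), n_draws = 1000, burn_in = 500,
                    thin = 10, init_scale = 0.3, seed = 4)
  for (j in 1:2) {
    ks <- suppressWarnings(stats::ks.test(dr$draws[, j], "punif"))
    expect_gt(ks$p.value, 0.01)
  }
  # 2D Gaussian: sample mean within 3 standard errors of truth
  mu <- c(1.2, -0.7)
  lp_norm <- function(th) -0.5 * sum((th - mu)^2 / 0.09)
  dg <- mcmc_sample(lp_norm, c(0, 0), n_draws = 1000, burn_in = 500,
                    thin = 10, init_scale = 0.3, seed = 5)
  for (j in 1:2) {
    se <- stats::sd(dg$draws[, j]) / sqrt(nrow(dg$draws))
    expect_lt(abs(mean(dg$draws[, j]) - mu[j]), 3 * se * sqrt(10))
  }
  # determinism
  d1 <- mcmc_sample(lp_flat, c(0.5, 0.5), n_draws = 200, burn_in = 100,
                    seed = 9)
  d2 <- mcmc_sample(lp_flat, c(0.5, 0.5), n_draws = 200, burn_in = 100,
                    seed = 9)
  expect_identical(d1$draws, d2$draws)
  expect_error(mcmc_sample(lp_flat, c(5, 5), n_draws = 10), "not finite")
})

test_that("credible regions are quantile intervals with nesting", {
  draws <- matrix(rep(c(1.5, -2), each = 50), ncol = 2)
  cr <- credible_region(draws, 0.9)
  expect_equal(cr$intervals$lower, cr$intervals$upper)
  set.seed(3)
  u <- matrix(runif(2000), ncol = 2)
  cr90 <- credible_region(u, 0.90)
  expect_lt(max(abs(cr90$intervals$lower - 0.05)), 0.03)
  expect_lt(max(abs(cr90$intervals$upper - 0.95)), 0.03)
  cr95 <- credible_region(u, 0.95)
  expect_true(all(cr95$intervals$lower <= cr90$intervals$lower))
  expect_true(all(cr95$intervals$upper >= cr90$intervals$upper))
  expect_error(credible_region(u, 1.2), "level")
  pw <- credible_region(u, 0.9, pairwise = TRUE)
  expect_true(length(pw$pairs) == 1 && nrow(pw$pairs[[1]]) >= 3)
})

test_that("prediction bands widen with parameter spread under pure decay", {
  p <- e2_params(e1 = 0, e2 = 0, e3 = 0, e4 = 0, a3 = 0, E2_0 = 1,
                 alpha_E2 = 4)
  one <- matrix(log10(4), 1, 1, dimnames = list(NULL, "alpha_E2"))
  b1 <- prediction_band(one, p, zero_forcing(), constant_p4(0.5), c(0, 0.5),
                        t_grid = seq(0, 0.25, 0.05))
  expect_equal(b1$lower, b1$upper)
  expect_equal(b1$median, exp(-4 * b1$time_days), tolerance = 1e-5)
  many <- matrix(log10(seq(3.5, 4.5, length.out = 30)), ncol = 1,
                 dimnames = list(NULL, "alpha_E2"))
  b <- prediction_band(many, p, zero_forcing(), constant_p4(0.5), c(0, 0.5),
                       t_grid = seq(0, 0.25, 0.05), level = 0.9)
  width <- b$upper - b$lower
  # analytic envelope: spread grows with t up to ln(a2/a1)/(a2-a1) = 0.251
  expect_true(all(diff(width) > 0))
})
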