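test_that("production-rate scaling divides by class maxima and round-trips", {
  p <- e2_params(e1 = 10, e2 = 30, e3 = 130, e4 = 78, a3 = 13)
  s <- scaling_factors()
  ps <- scale_production_rates(p, s)
  expect_equal(ps$e1, 1)        # 10 / 10
  expect_equal(ps$e2, 2)        # 30 / 15
  expect_equal(ps$e3, 2)        # 130 / 65
  expect_equal(ps$e4, 2)        # 78 / 39
  expect_equal(ps$a3, 0.2)      # 13 / 65
  back <- unscale_production_rates(ps, s)
  for (nm in c("e1", "e2", "e3", "e4", "a1", "a2", "a3", "a4")) {
    expect_equal(back[[nm]], p[[nm]], tolerance = 1e-12)
  }
  expect_error(scaling_factors(ReF_max = 0))
})

test_that("reduced RHS assembles its terms as written", {
  p <- e2_params()
  # clearance only
  expect_equal(e2_rhs_reduced(0, 1, zero_forcing()(0), 0.5, p), -p$alpha_E2)
  # term-by-term oracle at DmF = 65, P4 = 0.5
  vols <- constant_forcing(DmF = 65)(3)
  igf1 <- igf1_from_p4(0.5)
  hp <- igf1^p$hill$nI / (p$hill$TI^p$hill$nI + igf1^p$hill$nI)
  hm <- p$hill$T^p$hill$n / (p$hill$T^p$hill$n + 0.5^p$hill$n)
  expected <- p$e3 * 65 * hp + p$a3 * 65 * hm - p$alpha_E2 * 0.3
  expect_equal(e2_rhs_reduced(3, 0.3, vols, 0.5, p), expected,
               tolerance = 1e-12)
  # atretic factor is exactly 1 on the onset day
  v1 <- constant_forcing(atr_volume = 10, atr_delay = 4)(4)
  with_m0 <- update_e2_params(p, m = 0)
  expect_equal(e2_rhs_reduced(4, 0, v1, 0.5, p),
               e2_rhs_reduced(4, 0, v1, 0.5, with_m0))
  expect_error(e2_rhs_reduced(0, 0, list(ReF = -1, SeF = 0, DmF = 0,
                                         atretic_dominants = list(volume = numeric(),
                                                                  delay = numeric(),
                                                                  active = logical())),
                              0.5, p), "negative")
})

test_that("model forms reduce to one another exactly", {
  set.seed(11)
  p_red <- e2_params(a1 = 0, a2 = 0, a4 = 0)
  p_exp <- e2_params(a1 = 0.4, a2 = 0.7, a4 = 1.2, m2 = 0.31)
  for (i in 1:25) {
    vols <- random_volumes()
    t <- runif(1, 0, 20)
    p4 <- runif(1, 0, 1)
    e2 <- runif(1, 0, 1)
    # exponential form with a1 = a2 = a4 = 0 is the reduced form
    expect_equal(e2_rhs_exponential(t, e2, vols, p4, p_red),
                 e2_rhs_reduced(t, e2, vols, p4, p_red), tolerance = 1e-12)
    # full form with geometrically decaying per-day constants matches the
    # exponential form at integer days (integer onsets and times)
    ti <- sample(0:15, 1)
    vols$atretic_dominants$delay <- sample(0:5, 2, replace = TRUE)
    vols$atretic_dominants$age <-
      pmax(1L, as.integer(ti - vols$atretic_dominants$delay) + 1L)
    p_full <- update_e2_params(p_exp,
                               e_atr = p_exp$e4 * exp(-p_exp$m * (0:10)),
                               a_atr = p_exp$a4 * exp(-p_exp$m2 * (0:10)))
    if (all(vols$atretic_dominants$age <= 11)) {
      expect_equal(e2_rhs_full(ti, e2, vols, p4, p_full),
                   e2_rhs_exponential(ti, e2, vols, p4, p_exp),
                   tolerance = 1e-10)
    }
  }
})

test_that("full form handles missing atretics and clamps long atresia", {
  p <- e2_params()
  vols0 <- zero_forcing()(0)
  expect_equal(e2_rhs_full(0, 0.4, vols0, 0.5, p),
               e2_rhs_reduced(0, 0.4, vols0, 0.5, p))
  vols <- constant_forcing(atr_volume = 5, atr_delay = 0)(14)
  vols$atretic_dominants$age <- 15L
  expect_warning(e2_rhs_full(14, 0, vols, 0.5, p), "clamping")
})

test_that("with zero production the solution is pure exponential decay", {
  p <- e2_params(e1 = 0, e2 = 0, e3 = 0, e4 = 0, a1 = 0, a2 = 0, a3 = 0,
                 a4 = 0, alpha_E2 = 3.916, E2_0 = 0.8298)
  sim <- simulate_e2(p, zero_forcing(), constant_p4(0.5), c(0, 25))
  expect_equal(sim$value_scaled, 0.8298 * exp(-3.916 * sim$time_days),
               tolerance = 1e-6)
})

test_that("constant forcing converges to the analytic steady state", {
  p <- e2_params(E2_0 = 0)
  f <- constant_forcing(ReF = 3, SeF = 4, DmF = 10)
  p4 <- 0.6
  igf1 <- igf1_from_p4(p4)
  hp <- hill_positive(igf1, p$hill$TI, p$hill$nI)
  hm <- hill_negative(p4, p$hill$T, p$hill$n)
  prod <- (p$e1 * 3 + p$e2 * 4 + p$e3 * 10) * hp + p$a3 * 10 * hm
  sim <- simulate_e2(p, f, constant_p4(p4), c(0, 10))
  expect_equal(sim$value_scaled[nrow(sim)], prod / p$alpha_E2,
               tolerance = 1e-6)
})

test_that("the trajectory stays non-negative and converges in tolerance", {
  cyc <- fixture_cycle()
  tp <- fixture_params()
  forcing <- class_volume_forcing(cyc$tracks, t0 = 0, scale = "data")
  sim <- simulate_e2(tp, forcing, cyc$p4, c(0, 23))
  expect_true(all(sim$value_scaled > -1e-9))
  sim2 <- simulate_e2(tp, forcing, cyc$p4, c(0, 23), rtol = 1e-9,
                      atol = 1e-11)
  expect_lt(max(abs(sim2$value_scaled - sim$value_scaled)) /
              max(abs(sim$value_scaled)), 1e-5)
})

test_that("fast linear-path simulation matches the adaptive integrator", {
  cyc <- fixture_cycle()
  tp <- fixture_params()
  forcing <- class_volume_forcing(cyc$tracks, t0 = 0, scale = "data")
  ref <- simulate_e2(tp, forcing, cyc$p4, c(0, 23), rtol = 1e-10,
                     atol = 1e-12)
  fast <- simulate_e2(tp, forcing, cyc$p4, c(0, 23), method = "linear")
  v <- stats::approx(fast$time_days, fast$value_scaled,
                     xout = ref$time_days)$y
  expect_lt(max(abs(v - ref$value_scaled)), 5e-4)
  expect_error(simulate_e2(tp, zero_forcing(), cyc$p4, c(0, 23),
                           method = "linear"), "class_volume_forcing")
})

test_that("atretic production declines monotonically after onset", {
  p <- e2_params(e1 = 0, e2 = 0, e3 = 0, a3 = 0)
  f <- constant_forcing(atr_volume = 20, atr_delay = 2)
  times <- seq(2, 15, 0.5)
  rhs_at_zero_e2 <- vapply(times, function(t)
    e2_rhs_reduced(t, 0, f(t), 0.5, p), numeric(1))
  expect_true(all(diff(rhs_at_zero_e2) < 0))
})

test_that("data-derived scaling factors are the observed class maxima", {
  cyc <- fixture_cycle()
  s <- compute_scaling_factors(cyc$tracks)
  daily <- lapply(0:23, classify_day, tracks = cyc$tracks)
  expect_equal(s$DmF_max, max(vapply(daily, function(x) x$DmF, numeric(1))))
  expect_equal(s$ReF_max, max(vapply(daily, function(x) x$ReF, numeric(1))))
  forcing <- class_volume_forcing(cyc$tracks, t0 = 0, scale = "data")
  vols <- vapply(0:23, function(d) forcing(d)$DmF, numeric(1))
  expect_equal(max(vols), 1, tolerance = 1e-10)
})
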