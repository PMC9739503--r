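test_that("cycle construction follows the wave rules", {
  cyc <- fixture_cycle()
  spec <- cyc$spec
  # exactly one ever-dominant follicle per wave (no double ovulation)
  n_dom <- sum(vapply(cyc$tracks, function(tr) tr$ever_dominant, logical(1)))
  expect_equal(n_dom, spec$n_waves)
  # non-final-wave dominants become atretic; final-wave dominant survives
  doms <- Filter(function(tr) tr$ever_dominant, cyc$tracks)
  onsets <- vapply(doms, function(tr) tr$atresia_onset_day, numeric(1))
  expect_equal(sum(is.na(onsets)), 1)
  # at least one atretic dominant is present at each later wave emergence
  for (w in 2:spec$n_waves) {
    day <- spec$wave_emergence_days[w]
    dv <- classify_day(cyc$tracks, day)
    expect_gte(nrow(dv$atretic_dominants), 1)
  }
  # diameters bounded by the configured maximum
  expect_true(all(cyc$tracks_df$diameter_mm <=
                    spec$max_dominant_diameter + 0.5))
  expect_true(all(cyc$tracks_df$diameter_mm >= 0))
  # exactly one DmF-class follicle shortly after each deviation
  for (w in 1:spec$n_waves) {
    day <- spec$wave_emergence_days[w] + 4
    if (day > spec$cycle_length) next
    dv <- classify_day(cyc$tracks, day)
    in_dmf <- vapply(cyc$tracks, function(tr) {
      idx <- match(day, tr$days)
      atretic <- !is.na(tr$atresia_onset_day) && day >= tr$atresia_onset_day
      !is.na(idx) && !atretic && tr$diameters[idx] > 8
    }, logical(1))
    expect_equal(sum(in_dmf), 1)
  }
})

test_that("the 90% rule fires within two days of constructed regression", {
  cyc <- fixture_cycle()
  spec <- cyc$spec
  doms <- Filter(function(tr) tr$ever_dominant &&
                   !is.na(tr$atresia_onset_day), cyc$tracks)
  # constructed dominance loss: 6 days after wave emergence
  regress_days <- spec$wave_emergence_days[1:2] + 6
  onsets <- sort(vapply(doms, function(tr) tr$atresia_onset_day, numeric(1)))
  expect_true(all(onsets - regress_days >= 0 & onsets - regress_days <= 2))
})

test_that("generation is reproducible and responsive to options", {
  a <- fixture_cycle(seed = 5)
  b <- fixture_cycle(seed = 5)
  expect_identical(a$tracks_df, b$tracks_df)
  expect_identical(a$p4, b$p4)
  dbl <- fixture_cycle(seed = 5, double_ovulation = TRUE)
  n_dom <- sum(vapply(dbl$tracks, function(tr) tr$ever_dominant, logical(1)))
  expect_equal(n_dom, dbl$spec$n_waves + 1)
  # two final-wave follicles pass the deviation diameter
  final_emerge <- max(dbl$spec$wave_emergence_days)
  late <- Filter(function(tr) min(tr$days) >= final_emerge, dbl$tracks)
  expect_equal(sum(vapply(late, function(tr) tr$max_diameter > 8.5,
                          logical(1))), 2)
  expect_error(synthetic_cycle_spec(cycle_length = 10,
                                    wave_emergence_days = c(1, 12),
                                    n_waves = 2), "after cycle end")
})

test_that("observations respect the measured windows and noise model", {
  cyc <- fixture_cycle()
  tp <- fixture_params()
  obs <- generate_observations(tp, cyc)
  t_e2 <- obs$e2_measured$time_days
  expect_false(any(t_e2 > 6 & t_e2 < 15))
  expect_true(any(t_e2 <= 6) && any(t_e2 >= 15))
  # 8-hourly stamps inside the windows
  expect_true(all(abs(t_e2 * 3 - round(t_e2 * 3)) < 1e-9))
  # P4 is sampled on every day of the cycle
  expect_true(all(0:23 %in% round(obs$p4_sampled$time_days, 6) |
                    vapply(0:23, function(d)
                      any(abs(obs$p4_sampled$time_days - d) < 1e-9),
                      logical(1))))
  # zero noise reproduces the truth at the sample times exactly
  cyc0 <- fixture_cycle(noise_frac_measured = 0)
  obs0 <- generate_observations(tp, cyc0)
  truth_at <- stats::approx(obs0$e2_truth$time_days,
                            obs0$e2_truth$value_scaled,
                            xout = obs0$e2_measured$time_days)$y
  expect_equal(obs0$e2_measured$value_scaled, truth_at, tolerance = 1e-12)
  # seeded reproducibility of the noisy draw
  obs2 <- generate_observations(tp, cyc)
  expect_identical(obs$e2_measured, obs2$e2_measured)
})
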