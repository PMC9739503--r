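test_that("the 90% rule finds the first qualifying scan day", {
  tr <- follicle_track("f", 1:5, c(10, 11, 12, 11.5, 10.7))
  expect_equal(detect_atresia(tr), 5)  # 10.7 < 0.9*12; 11.5 is not
  expect_true(is.na(detect_atresia(follicle_track("f", 1:4, c(4, 5, 6, 6)))))
  expect_equal(detect_atresia(follicle_track("f", 1:2, c(12, 10.79))), 2)
  # onset is invariant to appending later days
  tr2 <- follicle_track("f", 1:7, c(10, 11, 12, 11.5, 10.7, 9, 8))
  expect_equal(detect_atresia(tr2), 5)
})

test_that("track construction validates input and derives dominance", {
  expect_error(follicle_track("f", c(1, 1, 2), c(1, 2, 3)), "increasing")
  expect_error(follicle_track("f", 1:2, c(3, -1)), "non-negative")
  tr <- follicle_track("f", 1:6, c(6, 8.5, 10, 9.5, 7, 5))
  expect_true(tr$ever_dominant)
  expect_equal(tr$max_diameter, 10)
  # a follicle only ever above threshold after onset is not dominant
  tr2 <- follicle_track("f", 1:4, c(6, 7, 6, 5))
  expect_false(tr2$ever_dominant)
})

test_that("delays measure onset relative to the calculation start", {
  tr <- follicle_track("f", 0:8, c(6, 8, 9, 10, 11, 12, 10.5, 9, 8))
  expect_equal(detect_atresia(tr), 6)  # 10.5 < 0.9*12
  expect_equal(compute_delay(tr, t0 = 0), 6)
  expect_equal(compute_delay(tr, t0 = 6), 0)
  expect_equal(compute_delay(tr, t0 = 3), 3)
  healthy <- follicle_track("f", 1:3, c(4, 5, 6))
  expect_error(compute_delay(healthy), "no atresia onset")
})

test_that("daily classification bins healthy follicles by diameter", {
  dv <- classify_day(fixture_simple_tracks(), 1)
  VG <- function(d) granulosa_volume_from_diameter(d, warn_range = FALSE)
  expect_equal(dv$ReF, VG(4))
  expect_equal(dv$SeF, VG(6))
  expect_equal(dv$DmF, VG(9))
  expect_equal(nrow(dv$atretic_dominants), 0)
  # boundary values: 5 mm and 8 mm both belong to SeF
  dv2 <- classify_day(list(follicle_track("x", 1, 5),
                           follicle_track("y", 1, 8)), 1)
  expect_equal(dv2$SeF, VG(5) + VG(8))
  expect_equal(dv2$ReF, 0); expect_equal(dv2$DmF, 0)
  # empty day
  dv3 <- classify_day(fixture_simple_tracks(), 10)
  expect_equal(dv3$ReF + dv3$SeF + dv3$DmF, 0)
  expect_error(classify_day(list(follicle_track("x", 1, 5),
                                 follicle_track("x", 1, 6)), 1), "duplicate")
})

test_that("an atretic dominant leaves DmF and enters the atretic class", {
  tr <- follicle_track("d", 0:4, c(10, 12, 10, 9, 8))  # onset day 2
  dv <- classify_day(list(tr), 2)
  expect_equal(dv$DmF, 0)
  expect_equal(dv$atretic_dominants$volume,
               granulosa_volume_from_diameter(10, warn_range = FALSE))
  expect_equal(dv$atretic_dominants$delay, 2)
  # atretic never-dominant follicles are excluded by default, kept on request
  sub <- follicle_track("s", 0:2, c(7, 7, 6))  # onset day 2, never dominant
  dv2 <- classify_day(list(sub), 2)
  expect_equal(dv2$ReF + dv2$SeF + dv2$DmF, 0)
  expect_equal(nrow(dv2$atretic_dominants), 0)
  dv3 <- classify_day(list(sub), 2, keep_atretic_subordinates = TRUE)
  expect_equal(dv3$SeF, granulosa_volume_from_diameter(6, warn_range = FALSE))
})

test_that("every follicle-day lands in exactly one bin (volume conservation)", {
  cyc <- fixture_cycle()
  VG <- function(d) granulosa_volume_from_diameter(d, warn_range = FALSE)
  for (day in c(3, 7, 11, 17, 21)) {
    dv <- classify_day(cyc$tracks, day)
    total_classed <- dv$ReF + dv$SeF + dv$DmF + sum(dv$atretic_dominants$volume)
    excluded <- 0
    per_follicle <- 0
    for (tr in cyc$tracks) {
      idx <- match(day, tr$days)
      if (is.na(idx)) next
      v <- VG(tr$diameters[idx])
      per_follicle <- per_follicle + v
      atretic <- !is.na(tr$atresia_onset_day) && day >= tr$atresia_onset_day
      if (atretic && !tr$ever_dominant) excluded <- excluded + v
    }
    expect_equal(total_classed + excluded, per_follicle, tolerance = 1e-10)
  }
})

test_that("summed dominant diameters include new and regressing dominants", {
  dom <- follicle_track("d1", 0:4, c(9, 12, 10, 9, 8))
  newdom <- follicle_track("d2", 2:4, c(7, 9, 11))
  small <- follicle_track("s", 0:4, c(4, 4, 4, 4, 4))
  expect_equal(summed_dominant_diameters(list(dom), 1), 12)
  expect_equal(summed_dominant_diameters(list(dom, newdom, small), 3), 9 + 9)
  expect_equal(summed_dominant_diameters(list(small), 2), 0)
})
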