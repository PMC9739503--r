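# Synthetic estrous-cycle generator: follicular waves with growth, deviation
# and atresia, a CL-driven P4 profile, and E2 observations with the study's
# sampling-gap structure. Every output is reproducible from the seed.

#' Specification of a synthetic estrous cycle
#'
#' Defaults emulate a 23-day three-wave bovine estrous cycle: waves of 4
#' follicles emerge at 4--5 mm on days 1, 9 and 17 and grow at 1.2 mm/day;
#' deviation occurs near 8.5 mm, after which one follicle per wave (two in
#' the last wave under `double_ovulation`) continues towards a 14 mm maximum
#' while subordinates shrink at 1 mm/day; dominants of non-final waves
#' regress during the luteal P4 plateau so the 90% atresia rule fires within
#' a day or two of dominance loss. P4 (scaled 0--1) rises from `rise_start`,
#' plateaus at `plateau_level` and decays after `luteolysis_day`.
#'
#' @param cycle_length Cycle length in days (default 23).
#' @param n_waves Number of follicular waves (default 3).
#' @param wave_emergence_days Emergence day of each wave (default 1, 9, 17).
#' @param follicles_per_wave Follicles per wave, 3--6 (default 4).
#' @param growth_rate Pre-deviation growth (mm/day, default 1.2).
#' @param deviation_diameter Diameter at deviation (mm, default 8.5).
#' @param max_dominant_diameter Maximum dominant diameter (mm, default 14).
#' @param atresia_shrink_rate Shrink rate of regressing follicles (mm/day,
#'   default 1).
#' @param double_ovulation Two dominants in the final wave? Default `FALSE`.
#' @param p4_rise_start,p4_plateau_level,p4_luteolysis_day,p4_decay_rate
#'   P4 profile: rise start day, plateau level (scaled), luteolysis day, and
#'   post-luteolysis exponential decay rate (per day).
#' @param noise_frac_measured,noise_frac_simulated Observation noise
#'   variance fractions (variance = fraction x value, the same
#'   value-proportional form as the inference noise model). The defaults
#'   (0.01, 0.05) correspond to a 15--20% assay coefficient of variation at
#'   mid-range hormone values, typical of field E2/P4 immunoassays; the
#'   larger fractions used as inference *assumptions* are set in
#'   [build_training_set()].
#' @param diameter_jitter_sd Optional per-scan diameter jitter (mm, default
#'   0 = deterministic tracks).
#' @param seed Integer seed governing all randomness.
#' @return Object of class `synthetic_cycle_spec`.
#' @export
synthetic_cycle_spec <- function(cycle_length = 23, n_waves = 3,
                                 wave_emergence_days = NULL,
                                 follicles_per_wave = 4,
                                 growth_rate = 1.2,
                                 deviation_diameter = 8.5,
                                 max_dominant_diameter = 14,
                                 atresia_shrink_rate = 1,
                                 double_ovulation = FALSE,
                                 p4_rise_start = 3, p4_plateau_level = 1,
                                 p4_luteolysis_day = 17, p4_decay_rate = 1.5,
                                 noise_frac_measured = 0.01,
                                 noise_frac_simulated = 0.05,
                                 diameter_jitter_sd = 0,
                                 seed = 1L) {
  if (is.null(wave_emergence_days)) {
    wave_emergence_days <- switch(as.character(n_waves),
                                  "1" = c(1), "2" = c(1, 11),
                                  "3" = c(1, 9, 17),
                                  seq(1, cycle_length - 6,
                                      length.out = n_waves))
  }
  stopifnot(length(wave_emergence_days) == n_waves,
            follicles_per_wave >= 3, follicles_per_wave <= 6,
            growth_rate > 0, atresia_shrink_rate > 0,
            deviation_diameter > 5,
            max_dominant_diameter > deviation_diameter)
  if (any(wave_emergence_days >= cycle_length)) {
    stop("wave emergence after cycle end", call. = FALSE)
  }
  structure(list(cycle_length = cycle_length, n_waves = n_waves,
                 wave_emergence_days = wave_emergence_days,
                 follicles_per_wave = follicles_per_wave,
                 growth_rate = growth_rate,
                 deviation_diameter = deviation_diameter,
                 max_dominant_diameter = max_dominant_diameter,
                 atresia_shrink_rate = atresia_shrink_rate,
                 double_ovulation = double_ovulation,
                 p4_rise_start = p4_rise_start,
                 p4_plateau_level = p4_plateau_level,
                 p4_luteolysis_day = p4_luteolysis_day,
                 p4_decay_rate = p4_decay_rate,
                 noise_frac_measured = noise_frac_measured,
                 noise_frac_simulated = noise_frac_simulated,
                 diameter_jitter_sd = diameter_jitter_sd,
                 seed = as.integer(seed)),
            class = "synthetic_cycle_spec")
}

# Piecewise-linear diameter path of one follicle. Grows from emergence at
# `start_diam`; dominants continue to `max_diam` then (if regressing) hold
# briefly and shrink; subordinates shrink from the deviation point.
follicle_path <- function(days, emerge_day, start_diam, grow, shrink,
                          peak_diam, regress_day = NA) {
  diam <- numeric(length(days))
  for (k in seq_along(days)) {
    t <- days[k]
    if (t < emerge_day) { diam[k] <- 0; next }
    d_grow <- start_diam + grow * (t - emerge_day)
    d <- min(d_grow, peak_diam)
    if (!is.na(regress_day) && t > regress_day) {
      peak_at_regress <- min(start_diam + grow * (regress_day - emerge_day),
                             peak_diam)
      d <- max(peak_at_regress - shrink * (t - regress_day), 0)
    }
    diam[k] <- d
  }
  diam
}

#' Generate a synthetic estrous cycle
#'
#' Builds daily follicle tracks, the scaled P4 profile and a CL-size series
#' (a monotone transform of P4, emitted for interface completeness) from a
#' [synthetic_cycle_spec()]. Follicles below 2 mm are not recorded
#' (ultrasound detection floor).
#'
#' @param spec A [synthetic_cycle_spec()].
#' @return List with `tracks` (list of [follicle_track()]), `tracks_df`
#'   (long data frame `day`, `follicle_id`, `diameter_mm`), `p4` (data frame
#'   `time_days`, `value_scaled`), `cl` (data frame `time_days`, `size_mm`)
#'   and `spec`.
#' @export
generate_cycle <- function(spec = synthetic_cycle_spec()) {
  stopifnot(inherits(spec, "synthetic_cycle_spec"))
  set.seed(spec$seed)
  days <- 0:spec$cycle_length
  rows <- list()
  fid <- 0L
  for (w in seq_len(spec$n_waves)) {
    emerge <- spec$wave_emergence_days[w]
    final_wave <- w == spec$n_waves
    n_dom <- if (final_wave && spec$double_ovulation) 2L else 1L
    # deterministic start diameters spread over the 4-5 mm emergence range
    starts <- seq(5, 4, length.out = spec$follicles_per_wave)
    # time at which the future dominant reaches the deviation diameter
    dev_time <- emerge + (spec$deviation_diameter - starts[1]) / spec$growth_rate
    for (j in seq_len(spec$follicles_per_wave)) {
      fid <- fid + 1L
      dominant <- j <= n_dom
      if (dominant) {
        # non-final dominants lose functional dominance ~6 days after wave
        # emergence (luteal-phase regression); the 90% rule then fires
        # within 1-2 days at the default shrink rate
        regress <- if (final_wave) NA else max(dev_time + 1, emerge + 6)
        diam <- follicle_path(days, emerge, starts[j], spec$growth_rate,
                              spec$atresia_shrink_rate,
                              spec$max_dominant_diameter, regress)
      } else {
        # subordinates lose support at deviation and shrink
        diam <- follicle_path(days, emerge, starts[j], spec$growth_rate,
                              spec$atresia_shrink_rate,
                              spec$deviation_diameter - 0.8, dev_time)
      }
      if (spec$diameter_jitter_sd > 0) {
        diam <- pmax(diam + stats::rnorm(length(diam), 0,
                                         spec$diameter_jitter_sd), 0)
      }
      keep <- diam >= 2  # ultrasound detection floor
      if (!any(keep)) next
      rows[[length(rows) + 1L]] <- data.frame(
        day = days[keep], follicle_id = sprintf("f%02d", fid),
        diameter_mm = round(diam[keep], 2), stringsAsFactors = FALSE)
    }
  }
  tracks_df <- do.call(rbind, rows)
  tracks_df <- tracks_df[order(tracks_df$follicle_id, tracks_df$day), ]
  rownames(tracks_df) <- NULL
  tracks <- tracks_from_df(tracks_df)
  # P4: smooth rise from rise_start to plateau, exponential fall after
  # luteolysis; scaled so the cycle maximum is plateau_level.
  t_grid <- seq(0, spec$cycle_length, by = 0.25)
  rise <- 1 / (1 + exp(-(t_grid - (spec$p4_rise_start + 3)) / 1.2))
  fall <- ifelse(t_grid <= spec$p4_luteolysis_day, 1,
                 exp(-spec$p4_decay_rate * (t_grid - spec$p4_luteolysis_day)))
  p4 <- rise * fall
  p4 <- p4 / max(p4) * spec$p4_plateau_level
  p4_df <- data.frame(time_days = t_grid, value_scaled = p4)
  cl_df <- data.frame(time_days = t_grid, size_mm = 10 + 15 * p4 / max(p4))
  list(tracks = tracks, tracks_df = tracks_df, p4 = p4_df, cl = cl_df,
       spec = spec)
}

#' Generate E2 observations with the study's sampling-gap structure
#'
#' Forward-simulates E2 with [simulate_e2()] under `true_params`, then
#' samples it at 8-hour intervals inside the measured windows only (E2 was
#' assayed from day 0 to day 6 and from day 15 to cycle end); P4 is sampled
#' 8-hourly inside the windows and daily elsewhere. Gaussian noise with
#' variance = `noise fraction x value` is added to both (fractions taken
#' from the cycle spec; 0 disables noise).
#'
#' @param true_params An [e2_params()] used as ground truth.
#' @param cycle A [generate_cycle()] result.
#' @param measured_windows List of `c(start, end)` day windows (default
#'   `list(c(0, 6), c(15, cycle_length))`).
#' @param seed Seed for the observation noise (default: `spec$seed + 1`).
#' @param form Model form for the forward simulation.
#' @return List with `e2_measured` (data frame `time_days`, `value_scaled`,
#'   `source = "measured"`), `p4_sampled`, `e2_truth` (noise-free full
#'   trajectory) and `true_params`.
#' @export
generate_observations <- function(true_params, cycle,
                                  measured_windows = NULL, seed = NULL,
                                  form = "reduced") {
  spec <- cycle$spec
  if (is.null(measured_windows)) {
    measured_windows <- list(c(0, 6), c(15, spec$cycle_length))
  }
  if (is.null(seed)) seed <- spec$seed + 1L
  t_span <- c(0, spec$cycle_length)
  truth <- simulate_e2(true_params, cycle$tracks, cycle$p4, t_span,
                       form = form, scale = "data")
  in_window <- function(t) any(vapply(measured_windows,
                                      function(w) t >= w[1] & t <= w[2],
                                      logical(1)))
  t_8h <- seq(0, spec$cycle_length, by = 1 / 3)
  e2_times <- t_8h[vapply(t_8h, in_window, logical(1))]
  e2_vals <- stats::approx(truth$time_days, truth$value_scaled,
                           xout = e2_times, rule = 2)$y
  p4_daily <- setdiff(0:spec$cycle_length, round(e2_times, 6))
  p4_times <- sort(unique(c(e2_times, p4_daily)))
  p4_vals <- stats::approx(cycle$p4$time_days, cycle$p4$value_scaled,
                           xout = p4_times, rule = 2)$y
  set.seed(seed)
  nf <- spec$noise_frac_measured
  if (nf > 0) {
    # variance = fraction x value, with a 0.05 assay floor on the value
    # (matching the training-set variance rule)
    e2_vals <- pmax(e2_vals + stats::rnorm(length(e2_vals), 0,
                                           sqrt(nf * pmax(e2_vals, 0.05))), 0)
    p4_vals <- pmax(p4_vals + stats::rnorm(length(p4_vals), 0,
                                           sqrt(nf * pmax(p4_vals, 0.05)) * 0.5),
                    0)
  }
  list(e2_measured = data.frame(time_days = e2_times,
                                value_scaled = e2_vals,
                                source = "measured",
                                stringsAsFactors = FALSE),
       p4_sampled = data.frame(time_days = p4_times,
                               value_scaled = p4_vals,
                               source = "measured",
                               stringsAsFactors = FALSE),
       e2_truth = truth, true_params = true_params)
}
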