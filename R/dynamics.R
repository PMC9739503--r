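# The E2 ordinary differential equation in its three forms and its forward
# simulation. State: scaled E2 (0-1). Forcing: per-class granulosa volumes
# (mm^3) and scaled P4, both interpolated between scan days.

#' Parameters of the E2 production model
#'
#' Holds every rate of the three model forms. `e1`, `e2`, `e3` are the
#' IGF1-branch production rates (per mm^3 granulosa per day on the scaled
#' hormone axis) for the recruited, secondary and dominant classes; `e4` and
#' the decay rate `m` govern the exponentially declining production of
#' atretic dominants. `a1`, `a2`, `a3`, `a4` and `m2` are the corresponding
#' P4-branch rates (the reduced form keeps only `a3`). `hill` carries the
#' Hill regulator constants, `alpha_E2` the clearance rate and `E2_0` the
#' initial condition. `e_atr`/`a_atr` are the optional 11 per-atresia-day
#' constants of the full form (ages 1..11; `NULL` means derive none).
#'
#' Defaults are the identified values of the reduced model: production rates
#' e1 = 18.7470, e2 = 39.0060, e3 = 468.1235, e4 = 619.5579, a3 = 127.543
#' (unscaled, i.e. per mm^3); T = 0.0020, n = 54.5738, TI = 1.3409,
#' nI = 2.7371, alpha_E2 = 3.9160, E2_0 = 0.8298, m = 0.2319.
#'
#' @param e1,e2,e3,e4 IGF1-branch production rates (>= 0).
#' @param a1,a2,a3,a4 P4-branch production rates (>= 0).
#' @param m,m2 Exponential decay rates of atretic production (per day, >= 0).
#' @param T,n,TI,nI Hill regulator constants (> 0).
#' @param alpha_E2 E2 clearance rate (per day, > 0).
#' @param E2_0 Initial scaled E2 (>= 0).
#' @param e_atr,a_atr Optional numeric vectors of 11 per-atresia-day rates
#'   (full model); ages beyond 11 reuse the last value.
#' @return Object of class `e2_params`.
#' @export
e2_params <- function(e1 = 18.7470, e2 = 39.0060, e3 = 468.1235,
                      e4 = 619.5579, a1 = 0, a2 = 0, a3 = 127.543, a4 = 0,
                      m = 0.2319, m2 = 0.2319,
                      T = 0.0020, n = 54.5738, TI = 1.3409, nI = 2.7371,
                      alpha_E2 = 3.9160, E2_0 = 0.8298,
                      e_atr = NULL, a_atr = NULL) {
  rates <- c(e1, e2, e3, e4, a1, a2, a3, a4, m, m2)
  stopifnot(all(rates >= 0), alpha_E2 > 0, E2_0 >= 0,
            T > 0, n > 0, TI > 0, nI > 0)
  if (!is.null(e_atr)) stopifnot(length(e_atr) == 11L, all(e_atr >= 0))
  if (!is.null(a_atr)) stopifnot(length(a_atr) == 11L, all(a_atr >= 0))
  structure(list(e1 = e1, e2 = e2, e3 = e3, e4 = e4,
                 a1 = a1, a2 = a2, a3 = a3, a4 = a4,
                 m = m, m2 = m2,
                 hill = list(T = T, n = n, TI = TI, nI = nI),
                 alpha_E2 = alpha_E2, E2_0 = E2_0,
                 e_atr = e_atr, a_atr = a_atr),
            class = "e2_params")
}

#' Replace fields of an e2_params object
#'
#' @param params An [e2_params()] object.
#' @param ... Named scalar replacements, e.g. `e3 = 500`, `T = 0.01`.
#' @return A new `e2_params`.
#' @export
update_e2_params <- function(params, ...) {
  stopifnot(inherits(params, "e2_params"))
  upd <- list(...)
  flat <- list(e1 = params$e1, e2 = params$e2, e3 = params$e3, e4 = params$e4,
               a1 = params$a1, a2 = params$a2, a3 = params$a3, a4 = params$a4,
               m = params$m, m2 = params$m2,
               T = params$hill$T, n = params$hill$n,
               TI = params$hill$TI, nI = params$hill$nI,
               alpha_E2 = params$alpha_E2, E2_0 = params$E2_0,
               e_atr = params$e_atr, a_atr = params$a_atr)
  bad <- setdiff(names(upd), names(flat))
  if (length(bad)) stop("unknown e2_params fields: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  flat[names(upd)] <- upd
  do.call(e2_params, flat)
}

#' Scaling factors for class production rates
#'
#' Maximum granulosa volume of each class over the study cycle; dividing the
#' unscaled production rates by these puts them on a 0--1 volume-fraction
#' scale. Defaults: ReF 10, SeF 15, DmF 65, AtrDmF 39 (mm^3).
#'
#' @param ReF_max,SeF_max,DmF_max,AtrDmF_max Class maxima (mm^3, > 0).
#' @return Object of class `scaling_factors`.
#' @export
scaling_factors <- function(ReF_max = 10, SeF_max = 15, DmF_max = 65,
                            AtrDmF_max = 39) {
  stopifnot(ReF_max > 0, SeF_max > 0, DmF_max > 0, AtrDmF_max > 0)
  structure(list(ReF_max = ReF_max, SeF_max = SeF_max,
                 DmF_max = DmF_max, AtrDmF_max = AtrDmF_max),
            class = "scaling_factors")
}

#' Scale class production rates by class volume maxima
#'
#' Divides each class production rate by its class scaling factor:
#' e1 by `ReF_max`, e2 by `SeF_max`, e3 and a3 by `DmF_max`, e4 by
#' `AtrDmF_max` (and the P4-branch a1, a2, a4 analogously).
#'
#' @param params An [e2_params()] with unscaled rates.
#' @param s A [scaling_factors()].
#' @return An `e2_params` with scaled rates (other fields untouched).
#' @export
#' @examples
#' p <- scale_production_rates(e2_params(), scaling_factors())
#' p$e3  # 468.1235 / 65 = 7.2019
scale_production_rates <- function(params, s = scaling_factors()) {
  stopifnot(inherits(params, "e2_params"), inherits(s, "scaling_factors"))
  update_e2_params(params,
                   e1 = params$e1 / s$ReF_max, a1 = params$a1 / s$ReF_max,
                   e2 = params$e2 / s$SeF_max, a2 = params$a2 / s$SeF_max,
                   e3 = params$e3 / s$DmF_max, a3 = params$a3 / s$DmF_max,
                   e4 = params$e4 / s$AtrDmF_max, a4 = params$a4 / s$AtrDmF_max,
                   e_atr = if (is.null(params$e_atr)) NULL else
                     params$e_atr / s$AtrDmF_max,
                   a_atr = if (is.null(params$a_atr)) NULL else
                     params$a_atr / s$AtrDmF_max)
}

#' Undo [scale_production_rates()]
#'
#' @inheritParams scale_production_rates
#' @return An `e2_params` with unscaled rates.
#' @export
unscale_production_rates <- function(params, s = scaling_factors()) {
  stopifnot(inherits(params, "e2_params"), inherits(s, "scaling_factors"))
  update_e2_params(params,
                   e1 = params$e1 * s$ReF_max, a1 = params$a1 * s$ReF_max,
                   e2 = params$e2 * s$SeF_max, a2 = params$a2 * s$SeF_max,
                   e3 = params$e3 * s$DmF_max, a3 = params$a3 * s$DmF_max,
                   e4 = params$e4 * s$AtrDmF_max, a4 = params$a4 * s$AtrDmF_max,
                   e_atr = if (is.null(params$e_atr)) NULL else
                     params$e_atr * s$AtrDmF_max,
                   a_atr = if (is.null(params$a_atr)) NULL else
                     params$a_atr * s$AtrDmF_max)
}

# Shared term assembly. volumes: list(ReF, SeF, DmF, atretic_dominants)
# where atretic_dominants is a data frame or plain list with fields volume,
# delay, active (and age for the full form). Returns the Hill factors
# evaluated at time t plus the atretic fields.
e2_rhs_terms <- function(t, volumes, p4, params) {
  if (volumes$ReF < 0 || volumes$SeF < 0 || volumes$DmF < 0 ||
      (length(volumes$atretic_dominants$volume) &&
       any(volumes$atretic_dominants$volume < 0))) {
    stop("negative granulosa volume in forcing", call. = FALSE)
  }
  igf1 <- igf1_from_p4(p4, warn_range = FALSE)
  igf1 <- max(igf1, 0)  # polynomial can dip below 0 when extrapolating
  list(hp = hill_positive(igf1, params$hill$TI, params$hill$nI),
       hm = hill_negative(p4, params$hill$T, params$hill$n),
       atr = volumes$atretic_dominants)
}

# Sum of active atretic volumes weighted by exp(-rate*(t - delay_i)); the
# decay clock starts at each follicle's atresia onset (delta = 1 from onset).
atretic_exp_sum <- function(t, atr, rate) {
  if (!length(atr$volume)) return(0)
  act <- atr$active & t >= atr$delay
  if (!any(act)) return(0)
  sum(atr$volume[act] * exp(-rate * (t - atr$delay[act])))
}

#' Right-hand side of the reduced E2 model
#'
#' `dE2/dt = (e1 ReF + e2 SeF + e3 DmF + e4 sum_i AtrDmF_i delta_i
#' exp(-m (t - delay_i))) H+(IGF1(P4)) + a3 DmF H-(P4) - alpha_E2 E2`,
#' with IGF1 derived from P4 via [igf1_from_p4()]. `delta_i` switches the
#' i-th atretic dominant on from its atresia onset, where the exponential
#' clock starts at 1.
#'
#' @param t Time (days).
#' @param e2 Current scaled E2.
#' @param volumes List with `ReF`, `SeF`, `DmF` (mm^3) and
#'   `atretic_dominants`, a data frame with columns `volume`, `delay`,
#'   `active` (as produced by [classify_day()]).
#' @param p4 Scaled P4 at `t`.
#' @param params An [e2_params()].
#' @return dE2/dt (per day).
#' @export
e2_rhs_reduced <- function(t, e2, volumes, p4, params) {
  tm <- e2_rhs_terms(t, volumes, p4, params)
  prod_igf <- params$e1 * volumes$ReF + params$e2 * volumes$SeF +
    params$e3 * volumes$DmF + params$e4 * atretic_exp_sum(t, tm$atr, params$m)
  prod_igf * tm$hp + params$a3 * volumes$DmF * tm$hm - params$alpha_E2 * e2
}

#' Right-hand side of the exponential-atresia E2 model
#'
#' As [e2_rhs_reduced()] plus the full P4 branch:
#' `(a1 ReF + a2 SeF + a3 DmF + a4 sum_i AtrDmF_i delta_i
#' exp(-m2 (t - delay_i))) H-(P4)`. Setting `a1 = a2 = a4 = 0` recovers the
#' reduced form exactly.
#'
#' @inheritParams e2_rhs_reduced
#' @return dE2/dt (per day).
#' @export
e2_rhs_exponential <- function(t, e2, volumes, p4, params) {
  tm <- e2_rhs_terms(t, volumes, p4, params)
  prod_igf <- params$e1 * volumes$ReF + params$e2 * volumes$SeF +
    params$e3 * volumes$DmF + params$e4 * atretic_exp_sum(t, tm$atr, params$m)
  prod_p4 <- params$a1 * volumes$ReF + params$a2 * volumes$SeF +
    params$a3 * volumes$DmF + params$a4 * atretic_exp_sum(t, tm$atr, params$m2)
  prod_igf * tm$hp + prod_p4 * tm$hm - params$alpha_E2 * e2
}

#' Right-hand side of the full per-atresia-day E2 model
#'
#' Atretic production uses independent per-age constants instead of an
#' exponential: an atretic dominant of integer atresia age `k` (days since
#' onset plus one, so age 1 on the onset day) contributes with rates
#' `e_atr[k]` and `a_atr[k]`; ages beyond 11 are clamped to 11 with a
#' warning. With geometrically decaying constants
#' `e_atr[k] = e4 exp(-m (k - 1))` this reproduces the exponential form at
#' integer days.
#'
#' @inheritParams e2_rhs_reduced
#' @param volumes As in [e2_rhs_reduced()], with an additional integer
#'   column `age` (days since atresia onset + 1) in `atretic_dominants`.
#' @return dE2/dt (per day).
#' @export
e2_rhs_full <- function(t, e2, volumes, p4, params) {
  tm <- e2_rhs_terms(t, volumes, p4, params)
  e_atr <- if (is.null(params$e_atr)) params$e4 * exp(-params$m * (0:10)) else params$e_atr
  a_atr <- if (is.null(params$a_atr)) params$a4 * exp(-params$m2 * (0:10)) else params$a_atr
  atr <- tm$atr
  sum_e <- sum_a <- 0
  if (length(atr$volume)) {
    act <- atr$active & t >= atr$delay
    if (any(act)) {
      age <- atr$age[act]
      if (any(age < 1)) stop("atresia age below 1", call. = FALSE)
      if (any(age > 11)) {
        warning("atresia age beyond 11 days; clamping to the day-11 rate",
                call. = FALSE)
        age <- pmin(age, 11L)
      }
      sum_e <- sum(e_atr[age] * atr$volume[act])
      sum_a <- sum(a_atr[age] * atr$volume[act])
    }
  }
  prod_igf <- params$e1 * volumes$ReF + params$e2 * volumes$SeF +
    params$e3 * volumes$DmF + sum_e
  prod_p4 <- params$a1 * volumes$ReF + params$a2 * volumes$SeF +
    params$a3 * volumes$DmF + sum_a
  prod_igf * tm$hp + prod_p4 * tm$hm - params$alpha_E2 * e2
}

#' Build a forcing function from follicle tracks
#'
#' Pre-computes, for a list of tracks, continuous-time class-volume forcing:
#' `ReF(t)`, `SeF(t)`, `DmF(t)` are classified daily with [classify_day()]
#' and linearly interpolated between days ("linear") or held constant over
#' each day ("constant"); each atretic dominant's volume is interpolated
#' from its own track.
#'
#' @param tracks List of [follicle_track()] objects.
#' @param days Day grid on which to classify (default: integer span of the
#'   tracks).
#' @param thresholds A [class_thresholds()].
#' @param q A [granulosa_quadratic()].
#' @param t0 Start of the calculations.
#' @param interp `"linear"` or `"constant"` between-day interpolation.
#' @param scale `NULL` for raw mm^3 volumes (to pair with unscaled
#'   production rates), a [scaling_factors()] to divide each class volume by
#'   its class maximum (to pair with scaled rates), or `"data"` to derive
#'   the class maxima from the tracks themselves via
#'   [compute_scaling_factors()].
#' @return A function `f(t)` returning the `volumes` list that the RHS
#'   functions expect (with atretic `age` column for the full form);
#'   attribute `"scaling"` records the factors used (or `NULL`).
#' @export
class_volume_forcing <- function(tracks, days = NULL,
                                 thresholds = class_thresholds(),
                                 q = granulosa_quadratic(), t0 = 0,
                                 interp = c("linear", "constant"),
                                 scale = NULL) {
  interp <- match.arg(interp)
  if (identical(scale, "data")) {
    scale <- compute_scaling_factors(tracks, thresholds = thresholds, q = q)
  }
  if (!is.null(scale)) stopifnot(inherits(scale, "scaling_factors"))
  if (is.null(days)) {
    lo <- floor(min(vapply(tracks, function(tr) min(tr$days), numeric(1))))
    hi <- ceiling(max(vapply(tracks, function(tr) max(tr$days), numeric(1))))
    days <- seq(lo, hi)
  }
  daily <- lapply(days, classify_day, tracks = tracks,
                  thresholds = thresholds, q = q, t0 = t0)
  meth <- if (interp == "linear") "linear" else "constant"
  div <- if (is.null(scale)) c(ReF = 1, SeF = 1, DmF = 1, Atr = 1) else
    c(ReF = scale$ReF_max, SeF = scale$SeF_max, DmF = scale$DmF_max,
      Atr = scale$AtrDmF_max)
  mk <- function(field) {
    v <- vapply(daily, function(x) x[[field]], numeric(1)) / div[[field]]
    stats::approxfun(days, v, method = meth, rule = 2)
  }
  ref_f <- mk("ReF"); sef_f <- mk("SeF"); dmf_f <- mk("DmF")
  # atretic dominants: per-follicle volume interpolants over their atretic span
  atr_tracks <- Filter(function(tr) tr$ever_dominant &&
                         !is.na(tr$atresia_onset_day), tracks)
  atr_ids <- vapply(atr_tracks, function(tr) as.character(tr$follicle_id),
                    character(1))
  atr_onset <- vapply(atr_tracks, function(tr) tr$atresia_onset_day,
                      numeric(1))
  atr_last <- vapply(atr_tracks, function(tr) max(tr$days), numeric(1))
  atr_volfun <- lapply(atr_tracks, function(tr) {
    vols <- granulosa_volume_from_diameter(tr$diameters, q,
                                           warn_range = FALSE) / div[["Atr"]]
    stats::approxfun(tr$days, vols, rule = 2)
  })
  n_atr <- length(atr_tracks)
  out <- function(t) {
    if (n_atr) {
      active <- t >= atr_onset & t <= atr_last
      vol <- numeric(n_atr)
      for (i in which(active)) vol[i] <- atr_volfun[[i]](t)
      atr_list <- list(follicle_id = atr_ids, volume = vol,
                       delay = atr_onset - t0, active = active,
                       age = pmax(1L, as.integer(floor(t - atr_onset)) + 1L))
    } else {
      atr_list <- list(follicle_id = character(), volume = numeric(),
                       delay = numeric(), active = logical(),
                       age = integer())
    }
    list(ReF = ref_f(t), SeF = sef_f(t), DmF = dmf_f(t),
         atretic_dominants = atr_list)
  }
  attr(out, "scaling") <- scale
  attr(out, "components") <- list(
    ref_f = ref_f, sef_f = sef_f, dmf_f = dmf_f,
    atr = list(onset = atr_onset, last = atr_last, volfun = atr_volfun),
    t0 = t0)
  out
}

#' Derive class scaling factors from a dataset
#'
#' The scaling factor of each class is the maximum summed granulosa volume
#' that the class attains over the scanned days (for atretic dominants, the
#' maximum single-follicle atretic volume), mirroring the use of in-dataset
#' class maxima to put production rates on a 0--1 volume-fraction scale.
#'
#' @param tracks List of [follicle_track()] objects.
#' @param days Day grid (default: integer span of the tracks).
#' @param thresholds A [class_thresholds()].
#' @param q A [granulosa_quadratic()].
#' @return A [scaling_factors()] with the observed class maxima.
#' @export
compute_scaling_factors <- function(tracks, days = NULL,
                                    thresholds = class_thresholds(),
                                    q = granulosa_quadratic()) {
  if (is.null(days)) {
    lo <- floor(min(vapply(tracks, function(tr) min(tr$days), numeric(1))))
    hi <- ceiling(max(vapply(tracks, function(tr) max(tr$days), numeric(1))))
    days <- seq(lo, hi)
  }
  daily <- lapply(days, classify_day, tracks = tracks,
                  thresholds = thresholds, q = q)
  mx <- function(field) max(vapply(daily, function(x) x[[field]], numeric(1)))
  atr_max <- max(c(0, unlist(lapply(daily, function(x)
    x$atretic_dominants$volume))))
  scaling_factors(ReF_max = max(mx("ReF"), 1e-9),
                  SeF_max = max(mx("SeF"), 1e-9),
                  DmF_max = max(mx("DmF"), 1e-9),
                  AtrDmF_max = max(atr_max, 1e-9))
}

# Vectorised total production rate P(t) of the reduced/exponential forms
# (the E2 ODE is linear: dE2/dt = P(t) - alpha_E2 * E2, with P independent
# of E2). comp: the "components" attribute of a class_volume_forcing result.
production_rate_at <- function(tgrid, params, comp, p4_fun, form,
                               side = c("right", "left")) {
  side <- match.arg(side)
  p4 <- pmax(p4_fun(tgrid), 0)
  igf1 <- pmax(igf1_from_p4(p4, warn_range = FALSE), 0)
  hp <- hill_positive(igf1, params$hill$TI, params$hill$nI)
  hm <- hill_negative(p4, params$hill$T, params$hill$n)
  ref <- comp$ref_f(tgrid); sef <- comp$sef_f(tgrid); dmf <- comp$dmf_f(tgrid)
  atr_e <- atr_a <- numeric(length(tgrid))
  for (i in seq_along(comp$atr$onset)) {
    # the delta switch makes P discontinuous at onset/disappearance; the
    # requested one-sided limit keeps the trapezoid exact across jumps that
    # fall on grid points
    act <- if (side == "right") {
      tgrid >= comp$atr$onset[i] & tgrid < comp$atr$last[i]
    } else {
      tgrid > comp$atr$onset[i] & tgrid <= comp$atr$last[i]
    }
    if (!any(act)) next
    v <- comp$atr$volfun[[i]](tgrid[act])
    dtau <- tgrid[act] - comp$atr$onset[i]
    atr_e[act] <- atr_e[act] + v * exp(-params$m * dtau)
    atr_a[act] <- atr_a[act] + v * exp(-params$m2 * dtau)
  }
  prod_igf <- params$e1 * ref + params$e2 * sef + params$e3 * dmf +
    params$e4 * atr_e
  prod_p4 <- if (form == "reduced") params$a3 * dmf else
    params$a1 * ref + params$a2 * sef + params$a3 * dmf + params$a4 * atr_a
  prod_igf * hp + prod_p4 * hm
}

# Exact solution of dE2/dt = P(t) - alpha*E2 for P piecewise linear on a
# uniform grid, via the exponential-trapezoid recurrence
#   E2_{k+1} = e^{-a h} E2_k + c1 P_R[k] + c2 P_L[k+1],
# evaluated with a vectorised linear filter. P_R/P_L are the right/left
# limits of P at the grid points (they differ only at jump discontinuities).
integrate_linear_e2 <- function(P_right, P_left, h, alpha, e2_0) {
  th <- alpha * h
  em <- exp(-th)
  phi1 <- (1 - em) / alpha                       # int e^{-a(h-u)} du
  J <- h * phi1 - (1 - em * (1 + th)) / alpha^2  # int u e^{-a(h-u)} du
  c2 <- J / h
  c1 <- phi1 - c2
  n <- length(P_right)
  b <- c1 * P_right[-n] + c2 * P_left[-1]
  e2 <- stats::filter(b, em, method = "recursive", init = e2_0)
  c(e2_0, as.numeric(e2))
}

#' Simulate the E2 trajectory
#'
#' Integrates the chosen model form from `E2(0) = E2_0`, with class-volume
#' and P4 forcing piecewise-linearly interpolated between scan days. Two
#' integration methods are provided: `"lsoda"`, the adaptive solver
#' (relative tolerance 1e-8 by default), and `"linear"`, an exact
#' exponential-trapezoid recurrence exploiting the linearity of the ODE in
#' E2 (the production term does not depend on E2), on a fixed fine grid —
#' orders of magnitude faster and used by the fitting and sampling routines.
#' The two agree to about 1e-4 on smooth forcing; `"linear"` requires a
#' forcing function built by [class_volume_forcing()] and the reduced or
#' exponential form.
#'
#' @param params An [e2_params()].
#' @param tracks List of [follicle_track()] objects, or a pre-built forcing
#'   function from [class_volume_forcing()].
#' @param p4_series Data frame with columns `time_days`, `value_scaled`, or
#'   a function of `t`.
#' @param t_span Length-2 numeric `c(t0, t1)` (days).
#' @param form `"reduced"`, `"exponential"` or `"full"`.
#' @param dt Output resolution in days (default 0.125, i.e. 3-hourly).
#' @param thresholds,q,scale Passed to [class_volume_forcing()] when
#'   `tracks` is a track list (`scale = "data"` pairs scaled production
#'   rates with volume-fraction forcing).
#' @param method `"lsoda"` (adaptive, default) or `"linear"` (fast exact
#'   recurrence; `dt` is its grid spacing, default 0.01 day).
#' @param rtol,atol Integrator tolerances (`"lsoda"` only).
#' @return Data frame with columns `time_days`, `value_scaled`, `source`
#'   (all `"simulated"`).
#' @export
simulate_e2 <- function(params, tracks, p4_series, t_span,
                        form = c("reduced", "exponential", "full"),
                        dt = NULL, thresholds = class_thresholds(),
                        q = granulosa_quadratic(), scale = NULL,
                        method = c("lsoda", "linear"),
                        rtol = 1e-8, atol = 1e-10) {
  form <- match.arg(form)
  method <- match.arg(method)
  stopifnot(inherits(params, "e2_params"), length(t_span) == 2L,
            t_span[2] > t_span[1])
  forcing <- if (is.function(tracks)) tracks else
    class_volume_forcing(tracks, thresholds = thresholds, q = q,
                         t0 = t_span[1], scale = scale)
  p4_fun <- if (is.function(p4_series)) p4_series else
    stats::approxfun(p4_series$time_days, p4_series$value_scaled, rule = 2)
  if (method == "linear") {
    comp <- attr(forcing, "components")
    if (is.null(comp)) {
      stop("method = 'linear' needs a forcing built by class_volume_forcing()",
           call. = FALSE)
    }
    if (form == "full") {
      stop("method = 'linear' supports the reduced and exponential forms only",
           call. = FALSE)
    }
    if (is.null(dt)) dt <- 0.01
    n <- ceiling((t_span[2] - t_span[1]) / dt)
    times <- seq(t_span[1], t_span[2], length.out = n + 1)
    P_right <- production_rate_at(times, params, comp, p4_fun, form, "right")
    P_left <- production_rate_at(times, params, comp, p4_fun, form, "left")
    e2 <- integrate_linear_e2(P_right, P_left, times[2] - times[1],
                              params$alpha_E2, params$E2_0)
    return(data.frame(time_days = times, value_scaled = e2,
                      source = "simulated", stringsAsFactors = FALSE))
  }
  rhs_fun <- switch(form, reduced = e2_rhs_reduced,
                    exponential = e2_rhs_exponential, full = e2_rhs_full)
  deriv <- function(t, y, parms) {
    list(rhs_fun(t, y[1], forcing(t), p4_fun(t), params))
  }
  if (is.null(dt)) dt <- 0.125
  times <- seq(t_span[1], t_span[2], by = dt)
  if (times[length(times)] < t_span[2]) times <- c(times, t_span[2])
  sol <- deSolve::ode(y = c(E2 = params$E2_0), times = times, func = deriv,
                      parms = NULL, method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop("simulate_e2: integrator failed (istate ",
         attr(sol, "istate")[1], ")", call. = FALSE)
  }
  data.frame(time_days = as.numeric(sol[, "time"]),
             value_scaled = as.numeric(sol[, "E2"]),
             source = "simulated", stringsAsFactors = FALSE)
}
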