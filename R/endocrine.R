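# Hormone sub-models: P4 -> IGF1 surrogate polynomial, Hill regulators and
# the single-equation summed-diameter E2 baseline.

#' Default IGF1 polynomial coefficients
#'
#' Degree-5 polynomial mapping scaled progesterone (P4, 0--1) to scaled IGF1,
#' highest degree first. Fitted to digitized IGF1/P4 profiles from normal
#' estrous cycles of dairy cows.
#'
#' @return Numeric vector `c(k5, k4, k3, k2, k1, k0)`.
#' @export
igf1_coefficients_default <- function() {
  c(k5 = 18.311, k4 = -59.062, k3 = 68.983, k2 = -34.283, k1 = 5.9711,
    k0 = 0.6839)
}

#' IGF1 surrogate from scaled progesterone
#'
#' Evaluates the degree-5 IGF1(P4) polynomial by Horner's scheme. The
#' polynomial is defined on scaled P4 in \[0, 1\]; values outside that range
#' are accepted with a warning since the polynomial is unconstrained there.
#' A clamp of the *output* to \[0, 1\] is available (off by default).
#'
#' @param p4 Scaled progesterone (0--1), vectorised.
#' @param coeffs 6 coefficients, highest degree first.
#' @param clamp Clamp the output into \[0, 1\]? Default `FALSE`.
#' @param warn_range Warn when `p4` leaves \[0, 1\]? Default `TRUE`.
#' @return Scaled IGF1.
#' @export
#' @examples
#' igf1_from_p4(0)    # constant term
#' igf1_from_p4(0.5)
igf1_from_p4 <- function(p4, coeffs = igf1_coefficients_default(),
                         clamp = FALSE, warn_range = TRUE) {
  stopifnot(is.numeric(p4), all(is.finite(p4)), length(coeffs) == 6L)
  if (warn_range && length(p4) && any(p4 < 0 | p4 > 1)) {
    warning("scaled P4 outside [0, 1]; the IGF1 polynomial extrapolates",
            call. = FALSE)
  }
  out <- rep(0, length(p4))
  for (k in coeffs) out <- out * p4 + k
  if (clamp) out <- pmin(pmax(out, 0), 1)
  out
}

#' Negative Hill function (P4 inhibition)
#'
#' `H-(x; T, n) = T^n / (T^n + x^n)`, the inhibitory regulator used for the
#' suppression of E2 production at high P4. Computed in log space so that the
#' large fitted exponent (n around 55) cannot overflow: with
#' `r = n*(log(x) - log(T))`, `H- = 1/(1 + exp(r))`.
#'
#' @param x Scaled P4 (non-negative), vectorised.
#' @param T Half-saturation threshold (> 0).
#' @param n Hill exponent (> 0).
#' @return Values in (0, 1]; `x = 0` gives 1, `x = T` gives 0.5.
#' @export
hill_negative <- function(x, T = 0.0020, n = 54.5738) {
  stopifnot(is.numeric(x), T > 0, n > 0)
  if (any(x < 0)) stop("hill_negative: x must be non-negative", call. = FALSE)
  out <- numeric(length(x))
  pos <- x > 0
  out[!pos] <- 1
  if (any(pos)) {
    r <- n * (log(x[pos]) - log(T))
    out[pos] <- 1 / (1 + exp(pmin(r, 700)))
    big <- r > 700  # exp saturates; use the asymptotic tail exp(-r)
    out[pos][big] <- exp(-r[big])
  }
  out
}

#' Positive Hill function (IGF1 stimulation)
#'
#' `H+(x; TI, nI) = x^nI / (TI^nI + x^nI)`, the stimulatory regulator for the
#' promotion of E2 production by IGF1. Log-space evaluation as in
#' [hill_negative()] via the identity `H+(x) = H-(TI; x, nI)` complement.
#'
#' @param x Scaled IGF1 (non-negative), vectorised.
#' @param TI Half-saturation threshold (> 0).
#' @param nI Hill exponent (> 0).
#' @return Values in \[0, 1); `x = 0` gives 0, `x = TI` gives 0.5.
#' @export
hill_positive <- function(x, TI = 1.3409, nI = 2.7371) {
  stopifnot(is.numeric(x), TI > 0, nI > 0)
  if (any(x < 0)) stop("hill_positive: x must be non-negative", call. = FALSE)
  out <- numeric(length(x))
  pos <- x > 0
  if (any(pos)) {
    r <- nI * (log(TI) - log(x[pos]))  # H+ = 1/(1 + (TI/x)^nI)
    out[pos] <- 1 / (1 + exp(pmin(r, 700)))
    big <- r > 700
    out[pos][big] <- exp(-r[big])
  }
  out
}

#' Parameters of the summed-diameter E2 baseline
#'
#' The baseline single-equation E2 model drives production by the squared sum
#' of dominant-follicle diameters: `dE2/dt = cFollE2 * Foll^2 - cE2 * E2`.
#'
#' @param cFollE2 Production rate per squared mm of summed diameter (>= 0).
#' @param cE2 Clearance rate per day (> 0).
#' @return Object of class `boer_params`.
#' @export
boer_params <- function(cFollE2, cE2) {
  stopifnot(is.numeric(cFollE2), is.numeric(cE2),
            cFollE2 >= 0, cE2 > 0)
  structure(list(cFollE2 = cFollE2, cE2 = cE2), class = "boer_params")
}

#' Right-hand side of the summed-diameter E2 baseline
#'
#' @param e2 Current scaled E2 (>= 0).
#' @param foll Summed dominant-follicle diameters (mm, >= 0); see
#'   [summed_dominant_diameters()].
#' @param p A [boer_params()] object.
#' @return dE2/dt (per day).
#' @export
boer_e2_rhs <- function(e2, foll, p) {
  stopifnot(inherits(p, "boer_params"))
  p$cFollE2 * foll^2 - p$cE2 * e2
}

#' Simulate the summed-diameter E2 baseline
#'
#' Integrates the baseline ODE with `Foll(t)` supplied as a time series,
#' linearly interpolated between observations (held constant outside them).
#'
#' @param p A [boer_params()] object.
#' @param foll_times,foll_values The `Foll(t)` series (days, mm).
#' @param e2_0 Initial scaled E2.
#' @param times Output time grid (days).
#' @return Data frame with columns `time_days`, `value_scaled`.
#' @export
simulate_boer_e2 <- function(p, foll_times, foll_values, e2_0, times) {
  stopifnot(inherits(p, "boer_params"), length(foll_times) == length(foll_values))
  foll_fun <- stats::approxfun(foll_times, foll_values, rule = 2)
  rhs <- function(t, y, parms) list(boer_e2_rhs(y[1], foll_fun(t), p))
  sol <- deSolve::ode(y = c(E2 = e2_0), times = times, func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-8, atol = 1e-10)
  data.frame(time_days = sol[, "time"], value_scaled = sol[, "E2"])
}
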