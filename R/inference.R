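# Parameter identification and Bayesian uncertainty quantification:
# weighted nonlinear least squares, log-uniform prior over log10-parameters,
# Gaussian likelihood with value-proportional variances, adaptive
# random-walk Metropolis, credible regions and prediction bands.

#' Assemble a training set of measured and gap-filled E2 observations
#'
#' Merges measured E2 observations with gap-filling simulated values (e.g.
#' from the summed-diameter baseline) into one weighted training set.
#' Measured points get weight 5 and noise variance 0.10 x value; simulated
#' points get weight 1 and variance 0.50 x value (all configurable). The
#' variance floor guards degenerate zero-valued observations.
#'
#' @param measured Data frame `time_days`, `value_scaled` of measured E2.
#' @param filled Optional data frame of gap-filling simulated E2 (disjoint
#'   time points).
#' @param weight_measured,weight_simulated Observation weights.
#' @param var_frac_measured,var_frac_simulated Noise variance as a fraction
#'   of the observed value.
#' @param value_floor Floor (on the 0--1 scale) for the value entering the
#'   variance rule, so near-zero observations keep a realistic assay noise
#'   floor (default 0.05).
#' @return Object of class `training_set`: data frame with columns
#'   `time_days`, `value_scaled`, `source`, `weight`, `sigma2`, time-sorted.
#' @export
build_training_set <- function(measured, filled = NULL,
                               weight_measured = 5, weight_simulated = 1,
                               var_frac_measured = 0.10,
                               var_frac_simulated = 0.50,
                               value_floor = 0.05) {
  stopifnot(weight_measured > 0, weight_simulated > 0,
            var_frac_measured > 0, var_frac_simulated > 0, value_floor > 0)
  mk <- function(df, src, w, vf) {
    if (is.null(df) || !nrow(df)) return(NULL)
    data.frame(time_days = df$time_days, value_scaled = df$value_scaled,
               source = src, weight = w,
               sigma2 = vf * pmax(abs(df$value_scaled), value_floor),
               stringsAsFactors = FALSE)
  }
  out <- rbind(mk(measured, "measured", weight_measured, var_frac_measured),
               mk(filled, "simulated", weight_simulated, var_frac_simulated))
  if (is.null(out) || !nrow(out)) stop("empty training set", call. = FALSE)
  if (anyDuplicated(out$time_days)) {
    stop("measured and simulated time points must be disjoint", call. = FALSE)
  }
  out <- out[order(out$time_days), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("training_set", "data.frame")
  out
}

#' Fit the summed-diameter baseline to measured E2 segments
#'
#' Estimates (`cFollE2`, `cE2`) of the baseline `dE2/dt = cFollE2 Foll^2 -
#' cE2 E2` by least squares against the measured E2 points, with `Foll(t)`
#' from [summed_dominant_diameters()]. Used to gap-fill the unmeasured
#' middle of the cycle before fitting the granulosa-volume model.
#'
#' @param measured Data frame `time_days`, `value_scaled` of measured E2.
#' @param tracks List of [follicle_track()] objects.
#' @param t_span Simulation span `c(t0, t1)`.
#' @param thresholds A [class_thresholds()].
#' @param init Initial `c(cFollE2, cE2)`.
#' @return List with `params` ([boer_params()]), `e2_0` and `sse`.
#' @export
fit_boer_baseline <- function(measured, tracks, t_span,
                              thresholds = class_thresholds(),
                              init = c(cFollE2 = 0.005, cE2 = 1)) {
  days <- seq(t_span[1], t_span[2], by = 0.25)
  foll <- vapply(days, summed_dominant_diameters, numeric(1),
                 tracks = tracks, thresholds = thresholds)
  e2_0 <- measured$value_scaled[which.min(measured$time_days)]
  resid_fun <- function(theta) {
    th <- exp(theta)  # positivity via log parameterisation
    sim <- simulate_boer_e2(boer_params(th[1], th[2]), days, foll,
                            e2_0, days)
    pred <- stats::approx(sim$time_days, sim$value_scaled,
                          xout = measured$time_days, rule = 2)$y
    pred - measured$value_scaled
  }
  fit <- minpack.lm::nls.lm(par = log(init), fn = resid_fun,
                            control = minpack.lm::nls.lm.control(maxiter = 100))
  th <- exp(fit$par)
  list(params = boer_params(unname(th[1]), unname(th[2])), e2_0 = e2_0,
       sse = sum(fit$fvec^2))
}

#' Gap-fill E2 between measured windows with the baseline model
#'
#' Fits the summed-diameter baseline to the measured segments and simulates
#' the gap, returning filled points on a daily grid strictly between the
#' last early-window and first late-window measurements.
#'
#' @inheritParams fit_boer_baseline
#' @param gap_dt Spacing of the filled points (days, default 1).
#' @return Data frame `time_days`, `value_scaled` of simulated gap values.
#' @export
gap_fill_boer <- function(measured, tracks, t_span,
                          thresholds = class_thresholds(), gap_dt = 1) {
  fit <- fit_boer_baseline(measured, tracks, t_span, thresholds)
  gaps <- sort(measured$time_days)
  dgap <- diff(gaps)
  if (!length(dgap) || max(dgap) <= gap_dt) {
    return(data.frame(time_days = numeric(), value_scaled = numeric()))
  }
  i <- which.max(dgap)
  lo <- gaps[i]; hi <- gaps[i + 1]
  fill_t <- seq(lo + gap_dt, hi - gap_dt / 2, by = gap_dt)
  days <- seq(t_span[1], t_span[2], by = 0.25)
  foll <- vapply(days, summed_dominant_diameters, numeric(1),
                 tracks = tracks, thresholds = thresholds)
  sim <- simulate_boer_e2(fit$params, days, foll, fit$e2_0, days)
  data.frame(time_days = fill_t,
             value_scaled = pmax(stats::approx(sim$time_days, sim$value_scaled,
                                               xout = fill_t, rule = 2)$y, 0))
}

# Pick the fast linear-path simulator when the forcing supports it.
sim_method_for <- function(forcing, form) {
  if (!is.null(attr(forcing, "components")) && form != "full") "linear"
  else "lsoda"
}

# Canonical MCMC parameter order (initial E2 is fitted but excluded here).
theta_names_mcmc <- function() {
  c("e1", "e2", "e3", "a3", "n", "T", "TI", "nI", "alpha_E2", "m", "e4")
}

# params + named theta vector (natural scale) -> e2_params
apply_theta <- function(params, theta) {
  do.call(update_e2_params, c(list(params), as.list(theta)))
}

#' Weighted nonlinear least-squares fit of the E2 model
#'
#' Minimises `sum_i w_i (E2_model(t_i; theta) - y_i)^2` over a named subset
#' of model parameters with a bound-constrained Levenberg--Marquardt solver
#' (residuals weighted by `sqrt(w_i)`). Parameters not listed in
#' `theta_init` stay at their values in `params`.
#'
#' @param training A [build_training_set()] result.
#' @param params An [e2_params()] supplying the fixed parameters and the
#'   model context.
#' @param forcing Forcing function from [class_volume_forcing()] (or a track
#'   list).
#' @param p4_series P4 series data frame or function.
#' @param t_span Simulation span.
#' @param theta_init Named numeric vector of starting values for the free
#'   parameters (subset of [theta_names_mcmc()] plus `"E2_0"`).
#' @param lower,upper Named bounds (defaults: `theta_init/10`,
#'   `theta_init*10`).
#' @param form Model form for [simulate_e2()].
#' @param rtol Integrator tolerance during fitting (default 1e-6 for speed;
#'   tighten for final runs).
#' @param method Simulation method (`NULL` = pick automatically).
#' @param extra_starts Optional list of additional named start vectors; the
#'   best converged objective wins. Useful because the sharp P4 Hill
#'   threshold creates local minima in its threshold parameter.
#' @return Object of class `wnls_fit`: list with `theta` (named, natural
#'   scale), `objective` (weighted SSE), `converged`, `message`, `niter`.
#' @export
wnls_fit <- function(training, params, forcing, p4_series, t_span,
                     theta_init, lower = NULL, upper = NULL,
                     form = "reduced", rtol = 1e-6, method = NULL,
                     extra_starts = NULL) {
  stopifnot(inherits(training, "training_set"), inherits(params, "e2_params"),
            length(theta_init) >= 1L, !is.null(names(theta_init)))
  if (is.null(lower)) lower <- theta_init / 10
  if (is.null(upper)) upper <- theta_init * 10
  stopifnot(all(is.finite(lower)), all(is.finite(upper)),
            all(theta_init >= lower), all(theta_init <= upper))
  forcing_fun <- if (is.function(forcing)) forcing else
    class_volume_forcing(forcing, t0 = t_span[1])
  if (is.null(method)) method <- sim_method_for(forcing_fun, form)
  sw <- sqrt(training$weight)
  resid_fun <- function(theta) {
    names(theta) <- names(theta_init)
    p <- apply_theta(params, theta)
    sim <- simulate_e2(p, forcing_fun, p4_series, t_span, form = form,
                       method = method,
                       dt = if (method == "linear") NULL else 0.005,
                       rtol = rtol, atol = 1e-8)
    pred <- stats::approx(sim$time_days, sim$value_scaled,
                          xout = training$time_days, rule = 2)$y
    sw * (pred - training$value_scaled)
  }
  one_fit <- function(start) {
    start <- pmin(pmax(start, lower), upper)
    minpack.lm::nls.lm(par = start, fn = resid_fun,
                       lower = lower, upper = upper,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 200, ftol = 1e-10, ptol = 1e-10,
                         epsfcn = 1e-6))
  }
  fits <- lapply(c(list(theta_init), extra_starts), one_fit)
  obj <- vapply(fits, function(f) sum(f$fvec^2), numeric(1))
  fit <- fits[[which.min(obj)]]
  theta <- fit$par
  names(theta) <- names(theta_init)
  structure(list(theta = theta, objective = sum(fit$fvec^2),
                 converged = fit$info %in% 1:4, message = fit$message,
                 niter = fit$niter),
            class = "wnls_fit")
}

#' Weighted SSE of a model trajectory against a training set
#'
#' @param training A [build_training_set()] result.
#' @param sim Simulated trajectory (`time_days`, `value_scaled`).
#' @return `sum_i w_i (pred_i - y_i)^2`.
#' @export
weighted_sse <- function(training, sim) {
  pred <- stats::approx(sim$time_days, sim$value_scaled,
                        xout = training$time_days, rule = 2)$y
  sum(training$weight * (pred - training$value_scaled)^2)
}

#' Log-uniform prior over log10-parameters
#'
#' Each component `L_j = log10(theta_j)` is uniform on the interval between
#' `0.6 * Lhat_j` and `1.6 * Lhat_j`, where `Lhat_j = log10(thetahat_j)` is
#' the least-squares estimate (endpoints ordered, so negative logs work).
#' Intervals narrower than `min_width` log10-units (which occur when
#' `thetahat_j` is near 1) are widened symmetrically to `min_width`.
#'
#' @param theta_log Numeric vector of log10-parameters.
#' @param theta_hat_log log10 of the WNLS point estimates, same length.
#' @param min_width Minimum interval width in log10 units (default 0.2).
#' @return 0 if inside the support (an unnormalised flat density), else
#'   `-Inf`.
#' @export
log_prior <- function(theta_log, theta_hat_log, min_width = 0.2) {
  stopifnot(length(theta_log) == length(theta_hat_log))
  b <- prior_bounds(theta_hat_log, min_width)
  if (all(theta_log >= b$lower & theta_log <= b$upper)) 0 else -Inf
}

#' Prior support bounds in log10 space
#'
#' @inheritParams log_prior
#' @return List with vectors `lower`, `upper`.
#' @export
prior_bounds <- function(theta_hat_log, min_width = 0.2) {
  lo <- pmin(0.6 * theta_hat_log, 1.6 * theta_hat_log)
  hi <- pmax(0.6 * theta_hat_log, 1.6 * theta_hat_log)
  narrow <- (hi - lo) < min_width
  if (any(narrow)) {
    mid <- (hi + lo) / 2
    lo[narrow] <- mid[narrow] - min_width / 2
    hi[narrow] <- mid[narrow] + min_width / 2
  }
  list(lower = lo, upper = hi)
}

#' Gaussian log-likelihood of the training data
#'
#' `sum_i [ -0.5 log(2 pi sigma_i^2) - (y_i(theta) - y_{d,i})^2 /
#' (2 sigma_i^2) ]` with per-point noise variances from the training set
#' (0.10 x value for measured points, 0.50 x value for simulated ones by
#' default).
#'
#' @param theta Named parameter vector (natural scale).
#' @param training A [build_training_set()] result.
#' @param params,forcing,p4_series,t_span,form,rtol As in [wnls_fit()].
#' @return Log-likelihood; `-Inf` (with a warning) if the simulation fails.
#' @export
log_likelihood <- function(theta, training, params, forcing, p4_series,
                           t_span, form = "reduced", rtol = 1e-6,
                           method = NULL) {
  if (is.null(method)) method <- sim_method_for(forcing, form)
  p <- try(apply_theta(params, theta), silent = TRUE)
  if (inherits(p, "try-error")) return(-Inf)
  sim <- try(simulate_e2(p, forcing, p4_series, t_span, form = form,
                         method = method,
                         dt = if (method == "linear") NULL else 0.005,
                         rtol = rtol, atol = 1e-8),
             silent = TRUE)
  if (inherits(sim, "try-error")) {
    warning("model simulation failed; log-likelihood = -Inf", call. = FALSE)
    return(-Inf)
  }
  pred <- stats::approx(sim$time_days, sim$value_scaled,
                        xout = training$time_days, rule = 2)$y
  sum(-0.5 * log(2 * pi * training$sigma2) -
        (pred - training$value_scaled)^2 / (2 * training$sigma2))
}

#' Adaptive random-walk Metropolis sampling of the posterior
#'
#' Samples log10-parameter vectors from `log_posterior = log_prior +
#' log_likelihood` with a Gaussian random-walk proposal whose scale (and,
#' after enough accepted moves, covariance) adapts during burn-in towards an
#' acceptance rate of about 0.3; the proposal is frozen for the retained
#' draws so the chain is a valid Metropolis sampler. Fully reproducible
#' given `seed`.
#'
#' @param log_post Function of a log10-parameter vector returning the
#'   unnormalised log posterior density.
#' @param theta_start_log Starting log10-parameter vector (finite density).
#' @param n_draws Number of retained draws (default 1000).
#' @param burn_in Adaptation/warm-up iterations (default 500).
#' @param thin Keep every `thin`-th post-burn-in draw (default 1).
#' @param init_scale Initial per-component proposal s.d. in log10 units.
#' @param seed Integer RNG seed.
#' @return Object of class `posterior_draws`: list with `draws` (matrix,
#'   `n_draws` x d, log10 scale), `acceptance_rate`, `log_post` values and
#'   `theta_names`.
#' @export
mcmc_sample <- function(log_post, theta_start_log, n_draws = 1000,
                        burn_in = 500, thin = 1, init_scale = 0.05,
                        seed = 1) {
  stopifnot(n_draws >= 1, burn_in >= 0, thin >= 1)
  d <- length(theta_start_log)
  lp0 <- log_post(theta_start_log)
  if (!is.finite(lp0)) {
    stop("mcmc_sample: log posterior not finite at the start point",
         call. = FALSE)
  }
  set.seed(seed)
  n_total <- burn_in + n_draws * thin
  cur <- theta_start_log
  lp_cur <- lp0
  log_s <- 0                      # log of the global scale multiplier
  base_sd <- rep(init_scale, d)   # per-component proposal shape
  chol_shape <- diag(base_sd, d)
  draws <- matrix(NA_real_, n_draws, d)
  lps <- numeric(n_draws)
  n_acc <- 0L
  hist_buf <- matrix(NA_real_, n_total, d)
  kept <- 0L
  for (i in seq_len(n_total)) {
    step <- exp(log_s) * as.numeric(chol_shape %*% stats::rnorm(d))
    prop <- cur + step
    lp_prop <- log_post(prop)
    acc <- is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp_cur
    if (acc) {
      cur <- prop
      lp_cur <- lp_prop
      if (i > burn_in) n_acc <- n_acc + 1L
    }
    hist_buf[i, ] <- cur
    if (i <= burn_in) {
      # Robbins-Monro scale tuning towards acceptance 0.3, plus a
      # Haario-style empirical-covariance proposal shape once the chain
      # has moved enough
      log_s <- log_s + (as.numeric(acc) - 0.3) / sqrt(1 + i / 10)
      if (i %% 100L == 0L && i >= 200L && d > 1L) {
        emp <- stats::cov(hist_buf[seq_len(i), , drop = FALSE])
        if (all(diag(emp) > 1e-12)) {
          ch <- try(chol(emp + diag(1e-10, d)), silent = TRUE)
          if (!inherits(ch, "try-error")) {
            chol_shape <- t(ch) * (2.38 / sqrt(d))
            log_s <- 0
          }
        }
      }
    }
    if (i > burn_in && (i - burn_in) %% thin == 0L) {
      kept <- kept + 1L
      draws[kept, ] <- cur
      lps[kept] <- lp_cur
    }
  }
  acc_rate <- n_acc / (n_draws * thin)
  if (acc_rate == 0 && n_draws * thin >= 100) {
    stop("mcmc_sample: zero acceptance over the sampling run", call. = FALSE)
  }
  nm <- names(theta_start_log)
  if (!is.null(nm)) colnames(draws) <- nm
  structure(list(draws = draws, acceptance_rate = acc_rate,
                 log_post = lps, theta_names = nm),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("Posterior draws: %d x %d, acceptance rate %.2f\n",
              nrow(x$draws), ncol(x$draws), x$acceptance_rate))
  invisible(x)
}

#' Equal-tailed credible intervals (and pairwise regions) from draws
#'
#' Per-parameter equal-tailed quantile intervals at the requested level;
#' optionally the convex hulls of the central `level` fraction of draws for
#' each parameter pair (for plotting two-dimensional credible regions).
#'
#' @param draws A [mcmc_sample()] result or a draws matrix (log10 scale).
#' @param level Credibility level in (0, 1), e.g. 0.90 or 0.95.
#' @param pairwise Also return pairwise convex-hull regions? Default `FALSE`.
#' @return List with `intervals` (data frame `parameter`, `lower`, `upper`,
#'   `median`) and, if requested, `pairs` (named list of hull-point
#'   matrices).
#' @export
credible_region <- function(draws, level = 0.90, pairwise = FALSE) {
  if (inherits(draws, "posterior_draws")) draws <- draws$draws
  stopifnot(is.matrix(draws), nrow(draws) >= 1)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  a <- (1 - level) / 2
  qs <- apply(draws, 2, stats::quantile, probs = c(a, 0.5, 1 - a),
              names = FALSE)
  nm <- colnames(draws)
  if (is.null(nm)) nm <- paste0("theta", seq_len(ncol(draws)))
  out <- list(intervals = data.frame(parameter = nm, lower = qs[1, ],
                                     median = qs[2, ], upper = qs[3, ],
                                     stringsAsFactors = FALSE))
  if (pairwise && ncol(draws) >= 2) {
    lp_dist <- rowSums(scale(draws, center = TRUE, scale = TRUE)^2)
    keep <- lp_dist <= stats::quantile(lp_dist, level)
    pairs <- list()
    for (i in seq_len(ncol(draws) - 1)) {
      j <- i + 1
      pts <- draws[keep, c(i, j), drop = FALSE]
      hull <- grDevices::chull(pts)
      pairs[[paste(nm[i], nm[j], sep = "~")]] <- pts[hull, , drop = FALSE]
    }
    out$pairs <- pairs
  }
  out
}

#' Posterior prediction band for the E2 trajectory
#'
#' Simulates the E2 trajectory for every posterior draw and returns, per
#' time point, the equal-tailed interval at the requested level. Draws whose
#' simulation fails are dropped with a logged count.
#'
#' @param draws A [mcmc_sample()] result (log10 scale, named columns).
#' @param params,forcing,p4_series,t_span,form As in [wnls_fit()].
#' @param t_grid Output time grid (days).
#' @param level Band level (default 0.90).
#' @param rtol Integrator tolerance per draw.
#' @return Data frame `time_days`, `lower`, `median`, `upper`; attribute
#'   `n_failed` counts dropped draws.
#' @export
prediction_band <- function(draws, params, forcing, p4_series, t_span,
                            t_grid = NULL, level = 0.90, form = "reduced",
                            rtol = 1e-6, method = NULL) {
  if (is.null(method)) method <- sim_method_for(forcing, form)
  if (inherits(draws, "posterior_draws")) draws <- draws$draws
  stopifnot(is.matrix(draws), nrow(draws) >= 1, !is.null(colnames(draws)))
  if (is.null(t_grid)) t_grid <- seq(t_span[1], t_span[2], by = 0.25)
  trajs <- matrix(NA_real_, nrow(draws), length(t_grid))
  n_failed <- 0L
  for (k in seq_len(nrow(draws))) {
    theta <- 10^draws[k, ]
    sim <- try({
      p <- apply_theta(params, theta)
      simulate_e2(p, forcing, p4_series, t_span, form = form,
                  method = method,
                  dt = if (method == "linear") NULL else 0.005,
                  rtol = rtol, atol = 1e-8)
    }, silent = TRUE)
    if (inherits(sim, "try-error")) { n_failed <- n_failed + 1L; next }
    trajs[k, ] <- stats::approx(sim$time_days, sim$value_scaled,
                                xout = t_grid, rule = 2)$y
  }
  ok <- stats::complete.cases(trajs)
  if (!any(ok)) stop("prediction_band: all draws failed", call. = FALSE)
  if (n_failed > 0) {
    message(sprintf("prediction_band: dropped %d failed draw(s)", n_failed))
  }
  a <- (1 - level) / 2
  qs <- apply(trajs[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(a, 0.5, 1 - a), names = FALSE)
  out <- data.frame(time_days = t_grid, lower = qs[1, ], median = qs[2, ],
                    upper = qs[3, ])
  attr(out, "n_failed") <- n_failed
  out
}

#' Build the log-posterior closure for the E2 model
#'
#' Convenience wrapper tying [log_prior()] and [log_likelihood()] together
#' over a named subset of parameters in log10 space (Bayes' rule with
#' constant evidence).
#'
#' @param training,params,forcing,p4_series,t_span,form,rtol As in
#'   [log_likelihood()].
#' @param theta_hat Named WNLS point estimates (natural scale) defining the
#'   prior support.
#' @param min_width Passed to [log_prior()].
#' @return Function of a log10-parameter vector returning the log posterior.
#' @export
make_log_posterior <- function(training, params, forcing, p4_series, t_span,
                               theta_hat, form = "reduced", rtol = 1e-6,
                               min_width = 0.2, method = NULL) {
  theta_hat_log <- log10(theta_hat)
  nm <- names(theta_hat)
  if (is.null(method)) method <- sim_method_for(forcing, form)
  function(theta_log) {
    lp <- log_prior(theta_log, theta_hat_log, min_width)
    if (!is.finite(lp)) return(-Inf)
    theta <- 10^theta_log
    names(theta) <- nm
    lp + log_likelihood(theta, training, params, forcing, p4_series,
                        t_span, form = form, rtol = rtol, method = method)
  }
}
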