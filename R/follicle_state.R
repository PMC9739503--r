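# Follicle tracks and their translation into the model's forcing terms:
# atresia detection (90% rule), dominance, class membership and summed
# granulosa volumes per day.

#' Class thresholds for follicle binning
#'
#' Healthy follicles are binned by diameter into recruited (ReF, below
#' `ref_upper`), secondary (SeF, `ref_upper` to `dmf_lower` inclusive) and
#' dominant (DmF, above `dmf_lower`). Boundary values are assigned half-open:
#' `[0, ref_upper) -> ReF`, `[ref_upper, dmf_lower] -> SeF`,
#' `(dmf_lower, Inf) -> DmF`. A follicle is atretic once its diameter falls
#' below `atresia_fraction` of its running maximum.
#'
#' @param ref_upper Upper diameter bound of the recruited class (mm).
#' @param dmf_lower Lower diameter bound of the dominant class (mm).
#' @param atresia_fraction Fraction of the running maximum below which a
#'   follicle is called atretic.
#' @return Object of class `class_thresholds`.
#' @export
class_thresholds <- function(ref_upper = 5, dmf_lower = 8,
                             atresia_fraction = 0.9) {
  stopifnot(ref_upper > 0, dmf_lower >= ref_upper,
            atresia_fraction > 0, atresia_fraction < 1)
  structure(list(ref_upper = ref_upper, dmf_lower = dmf_lower,
                 atresia_fraction = atresia_fraction),
            class = "class_thresholds")
}

#' Construct a follicle track
#'
#' One follicle's daily diameter series with derived atresia status and
#' dominance history.
#'
#' @param follicle_id Identifier (character or numeric).
#' @param days Strictly increasing time points (days).
#' @param diameters Diameters in mm, same length as `days`, non-negative.
#' @param thresholds A [class_thresholds()] used to derive atresia onset and
#'   the ever-dominant flag.
#' @return Object of class `follicle_track` with fields `follicle_id`,
#'   `days`, `diameters`, `max_diameter`, `atresia_onset_day` (NA if never),
#'   `ever_dominant` (diameter exceeded `dmf_lower` before atresia onset).
#' @export
follicle_track <- function(follicle_id, days, diameters,
                           thresholds = class_thresholds()) {
  stopifnot(length(days) == length(diameters), length(days) >= 1L,
            all(is.finite(days)), all(is.finite(diameters)))
  if (is.unsorted(days, strictly = TRUE)) {
    stop("follicle_track: days must be strictly increasing", call. = FALSE)
  }
  if (any(diameters < 0)) {
    stop("follicle_track: diameters must be non-negative", call. = FALSE)
  }
  onset <- detect_atresia_days(days, diameters, thresholds$atresia_fraction)
  pre_atresia <- if (is.na(onset)) rep(TRUE, length(days)) else days < onset
  structure(list(
    follicle_id = follicle_id,
    days = days,
    diameters = diameters,
    max_diameter = max(diameters),
    atresia_onset_day = onset,
    ever_dominant = any(diameters[pre_atresia] > thresholds$dmf_lower)
  ), class = "follicle_track")
}

#' @export
print.follicle_track <- function(x, ...) {
  cat(sprintf("Follicle %s: %d scans (day %g-%g), max %.1f mm, %s%s\n",
              as.character(x$follicle_id), length(x$days),
              min(x$days), max(x$days), x$max_diameter,
              if (is.na(x$atresia_onset_day)) "never atretic"
              else sprintf("atretic from day %g", x$atresia_onset_day),
              if (x$ever_dominant) ", ever-dominant" else ""))
  invisible(x)
}

# Earliest day on which diameter < fraction * running max; NA if never.
detect_atresia_days <- function(days, diameters, atresia_fraction) {
  run_max <- cummax(diameters)
  hit <- diameters < atresia_fraction * run_max
  if (any(hit)) days[which(hit)[1L]] else NA_real_
}

#' Detect atresia onset by the 90% rule
#'
#' A follicle is regarded as atretic from the first scan day on which its
#' diameter is smaller than `atresia_fraction` (default 90%) of its maximum
#' diameter observed up to that day.
#'
#' @param track A [follicle_track()].
#' @param atresia_fraction Fraction of the running maximum (default 0.9).
#' @return The onset day, or `NA` if the rule never fires.
#' @export
#' @examples
#' tr <- follicle_track("f1", 1:5, c(10, 11, 12, 11.5, 10.7))
#' detect_atresia(tr)  # day 5
detect_atresia <- function(track, atresia_fraction = 0.9) {
  stopifnot(inherits(track, "follicle_track"))
  detect_atresia_days(track$days, track$diameters, atresia_fraction)
}

#' Delay of an atretic dominant follicle
#'
#' The time lag between the start of the calculations `t0` and the first day
#' on which the follicle is atretic; it anchors the exponential decay clock
#' of the atretic production term.
#'
#' @param track A [follicle_track()] with a detected atresia onset.
#' @param t0 Start of the calculations (day, default 0).
#' @return `atresia_onset_day - t0` (days).
#' @export
compute_delay <- function(track, t0 = 0) {
  stopifnot(inherits(track, "follicle_track"))
  if (is.na(track$atresia_onset_day)) {
    stop("compute_delay: track has no atresia onset", call. = FALSE)
  }
  track$atresia_onset_day - t0
}

# Linearly interpolated diameter at time t; NA outside the scanned span.
track_diameter_at <- function(track, t) {
  if (t < min(track$days) || t > max(track$days)) return(NA_real_)
  if (length(track$days) == 1L) return(track$diameters)
  stats::approx(track$days, track$diameters, xout = t)$y
}

#' Classify follicles and sum granulosa volumes for one day
#'
#' Bins every follicle present on `day` into exactly one of: recruited (ReF),
#' secondary (SeF), dominant (DmF), atretic dominant, or excluded (atretic
#' never-dominant follicles, which are dropped from all production terms by
#' default). Volumes come from [granulosa_volume_from_diameter()]; diameters
#' between scan days are linearly interpolated.
#'
#' @param tracks List of [follicle_track()] objects (distinct ids).
#' @param day Day (may be fractional) at which to classify.
#' @param thresholds A [class_thresholds()].
#' @param q A [granulosa_quadratic()] volume model.
#' @param t0 Start of the calculations, for the atretic delays.
#' @param keep_atretic_subordinates Keep atretic never-dominant follicles in
#'   their size class instead of excluding them? Default `FALSE`.
#' @return Object of class `daily_class_volumes`: list with `day`, `ReF`,
#'   `SeF`, `DmF` (mm^3) and `atretic_dominants`, a data frame with columns
#'   `follicle_id`, `volume`, `delay`, `active`.
#' @export
classify_day <- function(tracks, day, thresholds = class_thresholds(),
                         q = granulosa_quadratic(), t0 = 0,
                         keep_atretic_subordinates = FALSE) {
  ids <- vapply(tracks, function(tr) as.character(tr$follicle_id), character(1))
  if (anyDuplicated(ids)) {
    stop("classify_day: duplicate follicle_id", call. = FALSE)
  }
  ReF <- SeF <- DmF <- 0
  atr <- list()
  for (tr in tracks) {
    d <- track_diameter_at(tr, day)
    if (is.na(d)) next
    vol <- granulosa_volume_from_diameter(d, q, warn_range = FALSE)
    atretic <- !is.na(tr$atresia_onset_day) && day >= tr$atresia_onset_day
    if (!atretic) {
      if (d < thresholds$ref_upper) ReF <- ReF + vol
      else if (d <= thresholds$dmf_lower) SeF <- SeF + vol
      else DmF <- DmF + vol
    } else if (tr$ever_dominant) {
      atr[[length(atr) + 1L]] <- data.frame(
        follicle_id = as.character(tr$follicle_id),
        volume = vol,
        delay = tr$atresia_onset_day - t0,
        active = TRUE,
        stringsAsFactors = FALSE)
    } else if (keep_atretic_subordinates) {
      if (d < thresholds$ref_upper) ReF <- ReF + vol
      else if (d <= thresholds$dmf_lower) SeF <- SeF + vol
      else DmF <- DmF + vol
    }
    # else: atretic never-dominant follicle, excluded from all classes
  }
  atr_df <- if (length(atr)) do.call(rbind, atr) else
    data.frame(follicle_id = character(), volume = numeric(),
               delay = numeric(), active = logical(),
               stringsAsFactors = FALSE)
  structure(list(day = day, ReF = ReF, SeF = SeF, DmF = DmF,
                 atretic_dominants = atr_df),
            class = "daily_class_volumes")
}

#' Summed dominant-follicle diameters (baseline forcing)
#'
#' Sum of the diameters, on a given day, of every follicle that has ever
#' exceeded the dominant threshold — new and regressing dominants alike.
#' This is the `Foll` forcing of the summed-diameter baseline E2 model.
#'
#' @inheritParams classify_day
#' @return Summed diameter in mm.
#' @export
summed_dominant_diameters <- function(tracks, day,
                                      thresholds = class_thresholds()) {
  tot <- 0
  for (tr in tracks) {
    if (!tr$ever_dominant) next
    d <- track_diameter_at(tr, day)
    if (!is.na(d)) tot <- tot + d
  }
  tot
}
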