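# Follicle geometry: shell volumes and the diameter -> granulosa-volume map.
# Convention: shell formulas take RADII (mm); all tabular/ultrasound-facing
# interfaces use DIAMETERS (mm).

#' Default quadratic coefficients for granulosa volume vs follicle diameter
#'
#' Coefficients (c2, c1, c0) of the least-squares quadratic relating follicle
#' diameter (mm) to granulosa-layer volume (mm^3), estimated from histology of
#' 98 bovine ovarian follicles. Valid over the fitted diameter range of about
#' 2--20 mm.
#'
#' @return Named numeric vector with elements `c2`, `c1`, `c0`.
#' @export
#' @examples
#' granulosa_quadratic_default()
granulosa_quadratic_default <- function() {
  c(c2 = 0.1741, c1 = -0.1407, c0 = 0.1288)
}

#' Granulosa cell density
#'
#' Average number of granulosa cells per cubic millimetre of granulosa layer,
#' determined by histological cell counting.
#'
#' @return Cells per mm^3 (scalar).
#' @export
granulosa_cell_density_default <- function() 2320445

#' Construct a quadratic diameter -> granulosa volume model
#'
#' @param c2,c1,c0 Coefficients of `c2*d^2 + c1*d + c0` where `d` is follicle
#'   diameter in mm and the value is granulosa volume in mm^3.
#' @return An object of class `granulosa_quadratic`.
#' @export
granulosa_quadratic <- function(c2 = 0.1741, c1 = -0.1407, c0 = 0.1288) {
  stopifnot(is.numeric(c2), is.numeric(c1), is.numeric(c0),
            length(c2) == 1L, length(c1) == 1L, length(c0) == 1L,
            is.finite(c2), is.finite(c1), is.finite(c0))
  structure(list(c2 = c2, c1 = c1, c0 = c0), class = "granulosa_quadratic")
}

#' @export
print.granulosa_quadratic <- function(x, ...) {
  cat(sprintf("Granulosa volume model: VG(d) = %g d^2 + %g d + %g  [mm^3, d in mm]\n",
              x$c2, x$c1, x$c0))
  invisible(x)
}

#' Spherical shell volume of the granulosa layer
#'
#' Volume of a spherical shell of inner radius `rA` (the antrum) and thickness
#' `rG` (the granulosa layer): (4/3) pi rG (rG^2 + 3 rA rG + 3 rA^2),
#' algebraically identical to (4/3) pi ((rA + rG)^3 - rA^3).
#'
#' @param rA Antrum radius (mm), non-negative. Vectorised.
#' @param rG Granulosa thickness (mm), non-negative. Vectorised.
#' @return Shell volume in mm^3.
#' @export
#' @examples
#' spherical_shell_volume(rA = 1, rG = 0.05)
spherical_shell_volume <- function(rA, rG) {
  stopifnot(is.numeric(rA), is.numeric(rG))
  if (any(rA < 0) || any(rG < 0)) {
    stop("spherical_shell_volume: radii must be non-negative", call. = FALSE)
  }
  (4 / 3) * pi * rG * (rG^2 + 3 * rA * rG + 3 * rA^2)
}

#' Ellipsoidal shell volume from two measured axes
#'
#' Histology sections record two antrum semi-axes and two granulosa
#' thicknesses; the unmeasured third axis is taken as the arithmetic mean of
#' the two measured ones (for both antrum and granulosa). The granulosa
#' volume is the outer ellipsoid (semi-axes `rA_k + rG_k`) minus the antrum
#' ellipsoid. Reduces to [spherical_shell_volume()] when the measured axes
#' are equal.
#'
#' @param rA1,rA2 Antrum semi-axes (mm).
#' @param rG1,rG2 Granulosa thicknesses along the same axes (mm).
#' @return Shell volume in mm^3.
#' @export
#' @examples
#' ellipsoid_shell_volume(1, 2, 0.1, 0.1)
ellipsoid_shell_volume <- function(rA1, rA2, rG1, rG2) {
  stopifnot(is.numeric(rA1), is.numeric(rA2), is.numeric(rG1), is.numeric(rG2))
  if (any(c(rA1, rA2, rG1, rG2) < 0)) {
    stop("ellipsoid_shell_volume: measurements must be non-negative", call. = FALSE)
  }
  rA3 <- (rA1 + rA2) / 2
  rG3 <- (rG1 + rG2) / 2
  outer <- (4 / 3) * pi * (rA1 + rG1) * (rA2 + rG2) * (rA3 + rG3)
  inner <- (4 / 3) * pi * rA1 * rA2 * rA3
  outer - inner
}

#' Granulosa volume from follicle diameter
#'
#' Evaluates the quadratic granulosa-volume model at a follicle diameter.
#' The regression was fitted over diameters of roughly 2--20 mm; evaluation
#' outside that range extrapolates and triggers a warning (the small positive
#' value at d = 0 is an artifact of the regression, deliberately untruncated).
#'
#' @param d Follicle diameter in mm (vectorised), non-negative.
#' @param q A [granulosa_quadratic()] model (default: fitted coefficients).
#' @param warn_range Warn when `d` is outside `[2, 20]` mm? Default `TRUE`.
#' @return Granulosa volume in mm^3.
#' @export
#' @examples
#' granulosa_volume_from_diameter(10)
granulosa_volume_from_diameter <- function(d, q = granulosa_quadratic(),
                                           warn_range = TRUE) {
  stopifnot(is.numeric(d), inherits(q, "granulosa_quadratic"))
  if (any(d < 0)) stop("diameter must be non-negative", call. = FALSE)
  if (warn_range && length(d) && any(d < 2 | d > 20)) {
    warning("diameter outside the fitted range [2, 20] mm; extrapolating",
            call. = FALSE)
  }
  q$c2 * d^2 + q$c1 * d + q$c0
}

#' Fit the quadratic granulosa-volume model by least squares
#'
#' Ordinary least-squares fit of `volume ~ diameter + diameter^2` to
#' (diameter, volume) pairs, as used to derive the default coefficients from
#' ellipsoidal shell volumes of sectioned follicles.
#'
#' @param diameter Follicle diameters (mm), at least 3 distinct values.
#' @param volume Granulosa volumes (mm^3), same length.
#' @return A [granulosa_quadratic()] with the fitted coefficients.
#' @export
fit_granulosa_quadratic <- function(diameter, volume) {
  stopifnot(is.numeric(diameter), is.numeric(volume),
            length(diameter) == length(volume))
  if (length(unique(diameter)) < 3L) {
    stop("fit_granulosa_quadratic: need at least 3 distinct diameters",
         call. = FALSE)
  }
  fit <- stats::lm(volume ~ diameter + I(diameter^2))
  cf <- stats::coef(fit)
  granulosa_quadratic(c2 = unname(cf["I(diameter^2)"]),
                      c1 = unname(cf["diameter"]),
                      c0 = unname(cf["(Intercept)"]))
}

#' Granulosa cell count from volume
#'
#' Convenience product of granulosa volume and cell density.
#'
#' @param volume_mm3 Granulosa volume (mm^3).
#' @param density Cells per mm^3; defaults to [granulosa_cell_density_default()].
#' @return Estimated cell count.
#' @export
granulosa_cell_count <- function(volume_mm3,
                                 density = granulosa_cell_density_default()) {
  stopifnot(is.numeric(volume_mm3), is.numeric(density), density > 0)
  volume_mm3 * density
}
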