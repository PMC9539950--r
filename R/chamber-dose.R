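## Chamber dose equation and calibration-coefficient determination.

#' Temperature-pressure correction factor
#'
#' Converts an air-filled (vented) chamber reading to reference air-density
#' conditions: `k_TP = (273.15 + T) / (273.15 + T_ref) * P_ref / P`.
#' Reference conditions default to the common calibration-lab convention of
#' 20 degrees Celsius and 1013.25 hPa.
#'
#' @param temperature chamber temperature in degrees Celsius.
#' @param pressure ambient pressure in hPa (> 0).
#' @param ref_temperature,ref_pressure reference conditions.
#' @return Dimensionless correction factor.
#' @examples
#' k_tp(25, 1013.25)  # 298.15 / 293.15
#' @export
k_tp <- function(temperature, pressure, ref_temperature = 20,
                 ref_pressure = 1013.25) {
  if (any(temperature <= -273.15) || any(ref_temperature <= -273.15))
    stop("k_tp: absolute temperature must be positive")
  if (any(pressure <= 0) || any(ref_pressure <= 0))
    stop("k_tp: pressure must be positive")
  (273.15 + temperature) / (273.15 + ref_temperature) *
    ref_pressure / pressure
}

#' Chamber dose from collected charge
#'
#' TRS-398-style dose equation
#' `D = M * N * k_TP * k_h * k_elec * k_pol * k_s`: collected charge times
#' the calibration coefficient times the multiplicative correction factors.
#' Humidity, electrometer, polarity and recombination factors default to 1;
#' in the UHDR workflow saturation is handled by the ICE, so `k_s` is left
#' at 1 here to avoid double-correcting.
#'
#' @param charge_nc collected charge M in nC.
#' @param coefficient calibration coefficient in Gy/nC (a number or a
#'   `"calibration_coefficient"` object).
#' @param k_tp,k_h,k_elec,k_pol,k_s dimensionless correction factors (> 0).
#' @return Dose in Gy.
#' @export
dose_from_charge <- function(charge_nc, coefficient, k_tp = 1, k_h = 1,
                             k_elec = 1, k_pol = 1, k_s = 1) {
  if (inherits(coefficient, "calibration_coefficient"))
    coefficient <- coefficient$value
  stopifnot(is.numeric(coefficient), all(coefficient > 0),
            all(c(k_tp, k_h, k_elec, k_pol, k_s) > 0))
  charge_nc * coefficient * k_tp * k_h * k_elec * k_pol * k_s
}

#' Fit a calibration coefficient from a linearity series
#'
#' Through-origin ordinary least squares of the (temperature-pressure
#' corrected) collected charge against the delivered dose; the calibration
#' coefficient is the reciprocal of the fitted slope (Gy/nC). A chamber that
#' receives no dose collects no charge, hence the origin constraint; a
#' free-intercept refit is reported as a diagnostic.
#'
#' @param dose_gy delivered doses in Gy (>= 3 points, not all equal to 0).
#' @param charge_nc corrected collected charges in nC.
#' @param beam_label free-text label of the beam quality.
#' @return An object of class `"calibration_coefficient"`: `value` (Gy/nC),
#'   `slope` (nC/Gy), `fit_r2`, `intercept_diagnostic` (free-intercept slope
#'   and intercept), `n`, `beam_label`.
#' @examples
#' d <- 1:10
#' fit_calibration_coefficient(d, d / 8.197)
#' @export
fit_calibration_coefficient <- function(dose_gy, charge_nc,
                                        beam_label = "") {
  stopifnot(length(dose_gy) == length(charge_nc), length(dose_gy) >= 3,
            all(is.finite(dose_gy)), all(is.finite(charge_nc)))
  fit <- lm(charge_nc ~ 0 + dose_gy)
  slope <- unname(coef(fit)[1])
  if (!is.finite(slope) || slope <= 0)
    stop("fit_calibration_coefficient: non-positive fitted slope")
  ssres <- sum(residuals(fit)^2)
  r2 <- 1 - ssres / sum(charge_nc^2)  # through-origin convention
  free <- lm(charge_nc ~ dose_gy)
  structure(list(value = 1 / slope, slope = slope, fit_r2 = r2,
                 intercept_diagnostic = list(
                   intercept = unname(coef(free)[1]),
                   slope = unname(coef(free)[2])),
                 n = length(dose_gy), beam_label = beam_label),
            class = "calibration_coefficient")
}

#' Known calibration coefficient
#'
#' Wraps an externally determined calibration coefficient (e.g. from a
#' reference beam) in the same class returned by
#' [fit_calibration_coefficient()], so it can be passed to [compute_ice()].
#'
#' @param value coefficient in Gy/nC (> 0).
#' @param beam_label free-text label.
#' @return An object of class `"calibration_coefficient"`.
#' @export
calibration_coefficient <- function(value, beam_label = "") {
  stopifnot(is.numeric(value), length(value) == 1, value > 0)
  structure(list(value = value, slope = 1 / value, fit_r2 = NA_real_,
                 intercept_diagnostic = NULL, n = 0L,
                 beam_label = beam_label),
            class = "calibration_coefficient")
}

#' @export
print.calibration_coefficient <- function(x, ...) {
  cat(sprintf("Calibration coefficient%s: %.4g Gy/nC",
              if (nzchar(x$beam_label)) paste0(" (", x$beam_label, ")")
              else "", x$value))
  if (!is.na(x$fit_r2))
    cat(sprintf("  [n = %d, R^2 = %.6f]", x$n, x$fit_r2))
  cat("\n")
  invisible(x)
}
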