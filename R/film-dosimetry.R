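## Film dosimetry: ROI extraction, degree-5 calibration, uncertainty budget.

#' Solid-water to water conversion factor
#'
#' Multiplicative factor converting a dose measured in RW3 solid-water slabs
#' to absorbed dose to water, applied when the calibration table is built.
#' @export
rw3_water_factor <- 0.985

#' Mean pixel value in a circular region of interest
#'
#' Averages the pixels of a scanned film whose centers fall strictly inside
#' a circle of the given physical diameter, matching the 2-mm sensitive area
#' of the micro chamber. The mask radius in pixels is
#' `diameter_mm / 2 * dpi / 25.4`.
#'
#' @param pixel_array numeric matrix of pixel intensities.
#' @param center circle center as `c(row, col)` in pixel coordinates.
#' @param diameter_mm ROI diameter in mm.
#' @param dpi scan resolution in dots per inch (> 0).
#' @return List with `mean`, `sd` and `n` (pixel count) of the ROI.
#' @examples
#' roi_mean(matrix(1, 60, 60), c(30, 30), diameter_mm = 2, dpi = 300)
#' @export
roi_mean <- function(pixel_array, center, diameter_mm, dpi) {
  stopifnot(is.matrix(pixel_array), is.numeric(pixel_array),
            length(center) == 2, diameter_mm > 0, dpi > 0)
  r_px <- diameter_mm / 2 * dpi / 25.4
  if (center[1] - r_px < 0.5 || center[1] + r_px > nrow(pixel_array) + 0.5 ||
      center[2] - r_px < 0.5 || center[2] + r_px > ncol(pixel_array) + 0.5)
    stop("roi_mean: mask does not fit inside the pixel array")
  rows <- matrix(seq_len(nrow(pixel_array)), nrow(pixel_array),
                 ncol(pixel_array))
  cols <- matrix(seq_len(ncol(pixel_array)), nrow(pixel_array),
                 ncol(pixel_array), byrow = TRUE)
  inside <- (rows - center[1])^2 + (cols - center[2])^2 < r_px^2
  if (!any(inside)) stop("roi_mean: no pixel center falls inside the mask")
  px <- pixel_array[inside]
  list(mean = mean(px), sd = if (length(px) > 1) sd(px) else 0,
       n = length(px))
}

#' Uncertainty budget of labeled relative-SD components
#'
#' A budget is a set of labeled relative standard deviations (in percent)
#' with a combination rule — quadratic (root-sum-square, for independent
#' components) or arithmetic (plain sum, conservative) — and a coverage
#' factor used for expansion.
#'
#' @param components named numeric vector of relative SDs in percent
#'   (non-negative).
#' @param rule `"quadratic"` or `"arithmetic"`.
#' @param coverage_k coverage factor (>= 1) applied on expansion.
#' @return An object of class `"uncertainty_budget"`.
#' @seealso [combine_budget()]
#' @export
uncertainty_budget <- function(components,
                               rule = c("quadratic", "arithmetic"),
                               coverage_k = 1) {
  rule <- match.arg(rule)
  if (!length(components)) stop("uncertainty_budget: no components")
  if (!is.numeric(components) || any(!is.finite(components)) ||
      any(components < 0))
    stop("uncertainty_budget: components must be finite, non-negative")
  if (coverage_k < 1) stop("uncertainty_budget: coverage_k must be >= 1")
  if (is.null(names(components)))
    names(components) <- paste0("component_", seq_along(components))
  structure(list(components = components, rule = rule,
                 coverage_k = coverage_k), class = "uncertainty_budget")
}

#' Combine an uncertainty budget
#'
#' Quadratic rule: square root of the sum of squared components. Arithmetic
#' rule: plain sum. With `expand = TRUE` the result is multiplied by the
#' budget's coverage factor. Values are relative SDs in percent; reports
#' conventionally quote them to one decimal.
#'
#' @param budget an [uncertainty_budget()].
#' @param expand multiply by the coverage factor? Default `FALSE`.
#' @return Combined relative SD in percent (exact; round for reporting).
#' @examples
#' combine_budget(uncertainty_budget(c(film = 0.5, chamber = 1.5, roi = 3)))
#' @export
combine_budget <- function(budget, expand = FALSE) {
  stopifnot(inherits(budget, "uncertainty_budget"))
  x <- budget$components
  out <- switch(budget$rule,
                quadratic = sqrt(sum(x^2)),
                arithmetic = sum(x))
  if (expand) out <- out * budget$coverage_k
  out
}

#' @export
print.uncertainty_budget <- function(x, ...) {
  cat(sprintf("Uncertainty budget (%s rule, k = %g):\n", x$rule,
              x$coverage_k))
  for (nm in names(x$components))
    cat(sprintf("  %-24s %5.1f %%\n", nm, x$components[[nm]]))
  cat(sprintf("  combined: %.1f %%  (expanded: %.1f %%)\n",
              combine_budget(x), combine_budget(x, expand = TRUE)))
  invisible(x)
}

## Default film dose budgets: below 15 Gy the quadratic sum of the
## inter-film, reference-chamber and ROI-inhomogeneity terms (3.4%); above
## 15 Gy the inter-channel deviation joins (6.0%).
film_budget_low <- function() {
  uncertainty_budget(c(interfilm = 0.5, reference_chamber = 1.5,
                       roi_inhomogeneity = 3.0))
}

film_budget_high <- function() {
  uncertainty_budget(c(film_dose_low = combine_budget(film_budget_low()),
                       channel_deviation = 5.0))
}

#' Fit a degree-5 film calibration
#'
#' Least-squares degree-5 polynomial of dose as a function of net optical
#' density, the standard radiochromic-film calibration family. When the
#' table contains duplicate films per dose point the mean net optical
#' density per point is used. The fitted curve must be strictly increasing
#' over the observed netOD range, otherwise the calibration is rejected.
#'
#' By default the least squares are weighted by `1/dose^2` (relative-error
#' loss). Film dose uncertainties are relative, and over a 0.1-30 Gy
#' calibration an unweighted fit leaves the low-dose end essentially
#' unconstrained in absolute terms, letting the polynomial oscillate below
#' the lowest knots: with realistic noise roughly one calibration in eight
#' is then rejected as non-monotone. Relative weighting removes this failure
#' mode without changing any noiseless identity. Set `weighting = "none"`
#' for the plain unweighted fit.
#'
#' @param table data frame with columns `netod` and `dose_gy` (a `point`
#'   column, as produced by [generate_film_calibration_set()], groups
#'   duplicate films).
#' @param channel color channel label (default `"red"`).
#' @param budget_low,budget_high uncertainty budgets attached to doses at or
#'   below / above `breakpoint_gy`.
#' @param breakpoint_gy budget breakpoint in Gy (default 15); the computed
#'   dose is compared half-open: `dose <= breakpoint` uses the low budget.
#' @param weighting `"relative"` (weights `1/dose^2`, default) or `"none"`.
#' @return An object of class `"film_calibration"` with `coefficients`
#'   (length 6, increasing powers of netOD), `valid_od_range`,
#'   `valid_dose_range`, `budget_low`, `budget_high`, `breakpoint_gy`,
#'   `channel`, and `r2`.
#' @export
fit_film_calibration <- function(table, channel = "red",
                                 budget_low = film_budget_low(),
                                 budget_high = film_budget_high(),
                                 breakpoint_gy = 15,
                                 weighting = c("relative", "none")) {
  weighting <- match.arg(weighting)
  stopifnot(is.data.frame(table), all(c("netod", "dose_gy") %in% names(table)))
  if ("point" %in% names(table)) {
    agg <- stats::aggregate(cbind(netod, dose_gy) ~ point, data = table, mean)
  } else {
    agg <- data.frame(netod = table$netod, dose_gy = table$dose_gy)
  }
  if (length(unique(agg$netod)) < 7)
    stop("fit_film_calibration: need >= 7 distinct netOD values for a ",
         "degree-5 fit with margin")
  dup <- duplicated(round(agg$netod, 10)) |
    duplicated(round(agg$netod, 10), fromLast = TRUE)
  if (any(dup)) {
    spread <- tapply(agg$dose_gy, round(agg$netod, 10),
                     function(d) diff(range(d)) / mean(d))
    if (any(spread > 0.02, na.rm = TRUE))
      warning("duplicate netOD values with conflicting doses (> 2%)")
  }
  if (any(agg$dose_gy <= 0))
    stop("fit_film_calibration: non-positive dose in the table")
  w <- if (weighting == "relative") 1 / agg$dose_gy^2
       else rep(1, nrow(agg))
  fit <- lm(dose_gy ~ poly(netod, 5, raw = TRUE), data = agg, weights = w)
  cf <- unname(coef(fit))
  od_range <- range(agg$netod)
  grid <- seq(od_range[1], od_range[2], length.out = 512)
  dgrid <- .poly5_deriv(cf, grid)
  if (any(dgrid <= 0))
    stop("fit_film_calibration: fitted curve is not strictly increasing on ",
         "the calibrated netOD range; calibration rejected")
  pred <- .poly5(cf, grid)
  structure(list(coefficients = cf, channel = channel,
                 valid_od_range = od_range,
                 valid_dose_range = range(pred),
                 budget_low = budget_low, budget_high = budget_high,
                 breakpoint_gy = breakpoint_gy,
                 r2 = 1 - sum(residuals(fit)^2) /
                   sum((agg$dose_gy - mean(agg$dose_gy))^2),
                 knots = agg), class = "film_calibration")
}

.poly5 <- function(cf, x) {
  cf[1] + cf[2] * x + cf[3] * x^2 + cf[4] * x^3 + cf[5] * x^4 + cf[6] * x^5
}

.poly5_deriv <- function(cf, x) {
  cf[2] + 2 * cf[3] * x + 3 * cf[4] * x^2 + 4 * cf[5] * x^3 +
    5 * cf[6] * x^4
}

#' @export
print.film_calibration <- function(x, ...) {
  cat(sprintf("Film calibration (%s channel): dose = P5(netOD)\n", x$channel))
  cat(sprintf("  valid netOD %.3f-%.3f, dose %.2f-%.1f Gy, R^2 = %.6f\n",
              x$valid_od_range[1], x$valid_od_range[2],
              x$valid_dose_range[1], x$valid_dose_range[2], x$r2))
  invisible(x)
}

#' Convert net optical density to dose
#'
#' Evaluates the calibration polynomial and attaches the relative SD from
#' the budget matching the computed dose regime (at or below the breakpoint:
#' low budget, typically 3.4%; above: high budget, typically 6%).
#' Extrapolation outside the calibrated netOD range is refused.
#'
#' @param cal a [film_calibration()][fit_film_calibration()].
#' @param netod net optical density value(s) inside `cal$valid_od_range`.
#' @return Data frame with columns `netod`, `dose_gy`, `rel_sd_pct`.
#' @export
od_to_dose <- function(cal, netod) {
  stopifnot(inherits(cal, "film_calibration"))
  lo <- cal$valid_od_range[1] - 1e-12
  hi <- cal$valid_od_range[2] + 1e-12
  if (any(netod < lo | netod > hi))
    stop(sprintf(paste0("od_to_dose: netOD outside calibrated range ",
                        "[%.4f, %.4f]; extrapolation refused"),
                 cal$valid_od_range[1], cal$valid_od_range[2]))
  dose <- .poly5(cal$coefficients, netod)
  sd_pct <- ifelse(dose <= cal$breakpoint_gy,
                   combine_budget(cal$budget_low),
                   combine_budget(cal$budget_high))
  data.frame(netod = netod, dose_gy = dose, rel_sd_pct = sd_pct)
}
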