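## GUM-style Monte-Carlo uncertainty propagation: saturation-slope SD and
## fitted-curve envelope. Jitters are relative (percent of each point's
## value), matching the relative uncertainty budgets, and independent
## across points and axes.

#' Monte-Carlo propagation settings
#'
#' @param n_draws_slope draws for the slope SD (default 5000).
#' @param n_draws_curve draws for the curve envelope (default 1000).
#' @param sd_x relative SD on the dose axis, percent (default 4.2, the
#'   below-15-Gy dose budget).
#' @param sd_x_high relative SD on the dose axis above the breakpoint,
#'   percent (default 6.5); used by the curve envelope.
#' @param sd_y_slope relative SD on the charge axis for the slope MC,
#'   percent (default 0.4, the charge repeatability).
#' @param sd_y_curve relative SD on the ICE axis for the envelope MC,
#'   percent (default 5.8, the expanded ICE budget).
#' @param breakpoint_gy dose-regime breakpoint, Gy (default 15).
#' @param seed integer seed for the draws.
#' @return An object of class `"mc_spec"`.
#' @export
mc_spec <- function(n_draws_slope = 5000, n_draws_curve = 1000, sd_x = 4.2,
                    sd_x_high = 6.5, sd_y_slope = 0.4, sd_y_curve = 5.8,
                    breakpoint_gy = 15, seed = 1L) {
  stopifnot(n_draws_slope >= 100, n_draws_curve >= 100,
            sd_x >= 0, sd_x_high >= 0, sd_y_slope >= 0, sd_y_curve >= 0)
  structure(list(n_draws_slope = as.integer(n_draws_slope),
                 n_draws_curve = as.integer(n_draws_curve),
                 sd_x = sd_x, sd_x_high = sd_x_high,
                 sd_y_slope = sd_y_slope, sd_y_curve = sd_y_curve,
                 breakpoint_gy = breakpoint_gy, seed = as.integer(seed)),
            class = "mc_spec")
}

#' Monte-Carlo SD of the saturation slope
#'
#' Around each anchor point a 2-D Gaussian cloud is generated (relative SDs
#' `sd_x` on dose, `sd_y_slope` on charge); each draw jitters every point
#' once and refits the through-origin line. The returned value is the SD of
#' the fitted slopes relative to their mean, in percent.
#'
#' @param dose_gy anchor doses (positive; a full anchor design has >= 3
#'   points, but reduced designs down to a single point are accepted for
#'   sensitivity studies).
#' @param charge_nc anchor charges.
#' @param spec an [mc_spec()].
#' @return Relative SD of the slope, percent.
#' @export
mc_slope_sd <- function(dose_gy, charge_nc, spec = mc_spec()) {
  stopifnot(inherits(spec, "mc_spec"), length(dose_gy) == length(charge_nc),
            length(dose_gy) >= 1)
  if (any(!is.finite(dose_gy)) || any(dose_gy <= 0))
    stop("mc_slope_sd: degenerate anchors (non-positive dose)")
  n <- length(dose_gy)
  with_substream(spec$seed, 11L, {
    slopes <- vapply(seq_len(spec$n_draws_slope), function(i) {
      x <- dose_gy * (1 + rnorm(n, 0, spec$sd_x / 100))
      y <- charge_nc * (1 + rnorm(n, 0, spec$sd_y_slope / 100))
      sum(x * y) / sum(x^2)  # through-origin OLS slope
    }, numeric(1))
    100 * sd(slopes) / mean(slopes)
  })
}

#' Monte-Carlo envelope of the fitted ICE curve
#'
#' Around each experimental ICE point a 2-D Gaussian cloud is generated
#' (relative SDs: the dose-regime budget on DPP, the expanded ICE budget on
#' ICE); each draw jitters every point once and refits the logistic model,
#' giving one curve per draw. The envelope is the pointwise SD of the drawn
#' curves over a DPP query grid, relative to their pointwise mean, in
#' percent. Draws whose refit fails to converge are dropped and counted;
#' more than `max_fail_frac` failures abort with diagnostics.
#'
#' @param ice_points data frame with `dpp_gy` and `ice` ([compute_ice()]).
#' @param spec an [mc_spec()].
#' @param grid DPP query grid in Gy; default 40 log-spaced points over the
#'   observed DPP range.
#' @param max_fail_frac tolerated refit failure fraction (default 0.10).
#' @return Data frame with `dpp_gy`, `ice_mean`, `sd_pct`; attributes
#'   `n_failed` and `mc_spec`.
#' @export
mc_curve_envelope <- function(ice_points, spec = mc_spec(), grid = NULL,
                              max_fail_frac = 0.10) {
  stopifnot(inherits(spec, "mc_spec"), is.data.frame(ice_points),
            all(c("dpp_gy", "ice") %in% names(ice_points)))
  dpp <- ice_points$dpp_gy
  ice <- ice_points$ice
  if (is.null(grid))
    grid <- exp(seq(log(min(dpp)), log(max(dpp)), length.out = 40))
  sd_x <- ifelse(dpp > spec$breakpoint_gy, spec$sd_x_high, spec$sd_x) / 100
  n <- length(dpp)
  base <- fit_logistic(dpp, ice)  # refits start from the base fit
  st <- list(alpha = base$alpha, beta = base$beta, gamma = base$gamma)
  with_substream(spec$seed, 22L, {
    curves <- matrix(NA_real_, spec$n_draws_curve, length(grid))
    failed <- 0L
    for (i in seq_len(spec$n_draws_curve)) {
      x <- dpp * (1 + rnorm(n, 0, sd_x))
      y <- ice * (1 + rnorm(n, 0, spec$sd_y_curve / 100))
      fit <- try(suppressWarnings(fit_logistic(x, y, start = st)),
                 silent = TRUE)
      if (inherits(fit, "try-error")) failed <- failed + 1L
      else curves[i, ] <- evaluate_logistic(fit, grid)
    }
    if (failed > max_fail_frac * spec$n_draws_curve)
      stop(sprintf(paste0("mc_curve_envelope: %d of %d refits failed ",
                          "(> %.0f%% tolerated)"),
                   failed, spec$n_draws_curve, 100 * max_fail_frac))
    ok <- stats::complete.cases(curves)
    m <- colMeans(curves[ok, , drop = FALSE])
    s <- apply(curves[ok, , drop = FALSE], 2, sd)
    out <- data.frame(dpp_gy = grid, ice_mean = m, sd_pct = 100 * s / m)
    attr(out, "n_failed") <- failed
    attr(out, "mc_spec") <- spec
    out
  })
}
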