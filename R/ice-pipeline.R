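## ICE pipeline: from a UHDR session to ICE-vs-DPP points and the fitted
## logistic recombination model, per pulse duration.

#' Condense a k_F duplicate table
#'
#' Per beam condition, the mean of the duplicate depth-dose transfer
#' factors and their relative SD. The pooled uncertainty (attribute
#' `pooled_sd_pct`) is the root-mean-square of the per-condition relative
#' SDs, an unbiased pooling of two-point spreads.
#'
#' @param duplicates data frame as from [generate_kf_table()]: columns
#'   `ssd_m`, `grid_tension_v`, `pulse_duration_us`, `replicate`, `kf`.
#' @return Data frame with `ssd_m`, `grid_tension_v`, `pulse_duration_us`,
#'   `kf_mean`, `kf_sd_rel_pct`; attribute `pooled_sd_pct`.
#' @export
kf_table <- function(duplicates) {
  stopifnot(is.data.frame(duplicates),
            all(c("ssd_m", "grid_tension_v", "pulse_duration_us", "kf") %in%
                  names(duplicates)))
  key <- interaction(duplicates$ssd_m, duplicates$grid_tension_v,
                     duplicates$pulse_duration_us, drop = TRUE)
  if (any(tabulate(key) < 2))
    stop("kf_table: every condition needs >= 2 replicates")
  agg <- do.call(rbind, lapply(split(duplicates, key), function(d) {
    data.frame(ssd_m = d$ssd_m[1], grid_tension_v = d$grid_tension_v[1],
               pulse_duration_us = d$pulse_duration_us[1],
               kf_mean = mean(d$kf),
               kf_sd_rel_pct = 100 * sd(d$kf) / mean(d$kf))
  }))
  rownames(agg) <- NULL
  attr(agg, "pooled_sd_pct") <- sqrt(mean(agg$kf_sd_rel_pct^2))
  agg
}

#' Look up a condition's mean k_F
#'
#' @param tbl table from [kf_table()].
#' @param ssd,grid_tension,pulse_duration condition identifiers.
#' @return Mean k_F for the condition; error if the condition is absent.
#' @export
kf_lookup <- function(tbl, ssd, grid_tension, pulse_duration) {
  i <- which(abs(tbl$ssd_m - ssd) < 1e-9 &
               abs(tbl$grid_tension_v - grid_tension) < 1e-9 &
               abs(tbl$pulse_duration_us - pulse_duration) < 1e-9)
  if (length(i) != 1)
    stop(sprintf("kf_lookup: no k_F for condition (SSD %g m, GT %g V, %g us)",
                 ssd, grid_tension, pulse_duration))
  tbl$kf_mean[i]
}

#' Beam-monitor correction of chamber charges
#'
#' Normalizes the shot-to-shot beam-output variation using the beam-current
#' transformer: within each condition, the shots without a film are rescaled
#' to the film-companion shot's beam output,
#' `Q_corr = Q * BCT_companion / BCT`, while the companion itself is left
#' unchanged.
#'
#' @param session session data frame (see [generate_uhdr_session()]); must
#'   contain one film-companion row per condition with a positive BCT signal.
#' @return The session with an added `charge_corr_nc` column.
#' @export
bct_correct <- function(session) {
  need <- c("condition", "film_companion", "charge_nc", "bct_signal")
  stopifnot(is.data.frame(session), all(need %in% names(session)))
  if (any(!is.finite(session$bct_signal) | session$bct_signal <= 0))
    stop("bct_correct: zero or missing BCT signal")
  out <- session
  out$charge_corr_nc <- NA_real_
  for (cond in unique(session$condition)) {
    i <- which(session$condition == cond)
    comp <- i[session$film_companion[i]]
    if (length(comp) != 1)
      stop("bct_correct: condition ", cond,
           " must have exactly one film-companion shot")
    out$charge_corr_nc[i] <- session$charge_nc[i] *
      session$bct_signal[comp] / session$bct_signal[i]
    out$charge_corr_nc[comp] <- session$charge_nc[comp]
  }
  out
}

## Assemble per-shot analysis points from a BCT-corrected session: the
## per-pulse, temperature-pressure-corrected charge, and the DPP at chamber
## depth transferred from the companion film's surface dose via k_F.
chamber_points <- function(session, kf, ref_temperature = 20,
                           ref_pressure = 1013.25) {
  if (!"charge_corr_nc" %in% names(session))
    session <- bct_correct(session)
  rows <- lapply(split(session, session$condition), function(d) {
    comp <- which(d$film_companion)
    film <- d$film_dose_gy[comp]
    if (!is.finite(film) || film <= 0)
      stop("chamber_points: condition ", d$condition[1],
           " has no usable film-companion dose")
    kfv <- kf_lookup(kf, d$ssd_m[1], d$grid_tension_v[1],
                     d$pulse_duration_us[1])
    dpp <- film / d$n_pulses[1] * kfv
    if (dpp <= 0) stop("chamber_points: non-positive DPP")
    ktp <- k_tp(d$temperature_c, d$pressure_hpa,
                ref_temperature, ref_pressure)
    data.frame(condition = d$condition, ssd_m = d$ssd_m,
               grid_tension_v = d$grid_tension_v,
               pulse_duration_us = d$pulse_duration_us, shot = d$shot,
               dpp_gy = dpp,
               q_pp_nc = d$charge_corr_nc * ktp / d$n_pulses)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Saturation-charge anchoring at the reference SSD
#'
#' At the largest SSD the dose per pulse is small enough that recombination
#' is negligible, identified by per-pulse charges below 20 pC. Fitting those
#' anchor charges against DPP with a through-origin line gives the
#' saturation charge `Q_sat(DPP) = slope * DPP`; the reciprocal slope is the
#' chamber's calibration coefficient in the pulsed beam.
#'
#' @param points per-shot analysis points with columns `ssd_m`, `dpp_gy`,
#'   `q_pp_nc` (temperature-pressure- and BCT-corrected per-pulse charge),
#'   e.g. from the session assembly inside [run_fit()].
#' @param ref_ssd reference SSD in m (default 2).
#' @param charge_threshold_nc anchor acceptance threshold in nC (default
#'   0.020 = 20 pC); points at or above it are excluded with a warning.
#' @return A `"calibration_coefficient"` whose `value` is Gy/nC; the anchor
#'   points used are attached as attribute `anchors`.
#' @export
fit_qsat <- function(points, ref_ssd = 2, charge_threshold_nc = 0.020) {
  stopifnot(is.data.frame(points),
            all(c("ssd_m", "dpp_gy", "q_pp_nc") %in% names(points)))
  anchors <- points[abs(points$ssd_m - ref_ssd) < 1e-9, , drop = FALSE]
  if (!nrow(anchors))
    stop("fit_qsat: no points at the reference SSD of ", ref_ssd, " m")
  over <- anchors$q_pp_nc >= charge_threshold_nc
  if (any(over)) {
    warning(sum(over), " anchor point(s) at or above ",
            1000 * charge_threshold_nc, " pC excluded from the Q_sat fit")
    anchors <- anchors[!over, , drop = FALSE]
  }
  if (nrow(anchors) < 3)
    stop("fit_qsat: fewer than 3 anchor points below the charge threshold")
  out <- fit_calibration_coefficient(anchors$dpp_gy, anchors$q_pp_nc,
                                     beam_label = sprintf(
                                       "UHDR anchors at SSD %g m", ref_ssd))
  attr(out, "anchors") <- anchors
  out
}

#' Compute ICE points from anchored charges
#'
#' The ion collection efficiency of each shot is the ratio of the collected
#' (corrected) charge to the saturation charge at its dose per pulse:
#' `ICE = q_pp * N / DPP` with `N` the saturation calibration coefficient in
#' Gy/nC. Relative uncertainties are attached from the configured budgets:
#' the expanded ICE budget on the efficiency axis and the dose-regime budget
#' (below/above the breakpoint) on the DPP axis. Values slightly above 1
#' (noise excursions of the saturation plateau) are retained but flagged;
#' they would bias the low-DPP plateau if clipped.
#'
#' @param points per-shot analysis points (`dpp_gy`, `q_pp_nc`, plus
#'   identifiers).
#' @param qsat a `"calibration_coefficient"` (fitted by [fit_qsat()] or a
#'   known [calibration_coefficient()]).
#' @param sd_ice_pct relative SD attached to ICE, percent (default 5.8, the
#'   k = 2 expanded charge + saturation budget).
#' @param sd_dpp_low_pct,sd_dpp_high_pct relative SD attached to DPP below /
#'   above `breakpoint_gy` (defaults 4.2 and 6.5).
#' @param breakpoint_gy dose-regime breakpoint (default 15 Gy).
#' @param max_ice tolerated upper excursion (default 1.05); larger values
#'   raise a warning.
#' @return Data frame of ICE points: identifiers, `dpp_gy`, `ice`,
#'   `sd_ice_pct`, `sd_dpp_pct`, `flagged` (ICE > 1).
#' @export
compute_ice <- function(points, qsat, sd_ice_pct = 5.8,
                        sd_dpp_low_pct = 4.2, sd_dpp_high_pct = 6.5,
                        breakpoint_gy = 15, max_ice = 1.05) {
  stopifnot(is.data.frame(points),
            all(c("dpp_gy", "q_pp_nc") %in% names(points)))
  if (inherits(qsat, "calibration_coefficient")) qsat <- qsat$value
  stopifnot(is.numeric(qsat), qsat > 0)
  if (any(points$dpp_gy <= 0)) stop("compute_ice: non-positive DPP")
  out <- points
  out$ice <- points$q_pp_nc * qsat / points$dpp_gy
  if (any(out$ice <= 0)) stop("compute_ice: non-positive ICE")
  out$sd_ice_pct <- sd_ice_pct
  out$sd_dpp_pct <- ifelse(out$dpp_gy <= breakpoint_gy,
                           sd_dpp_low_pct, sd_dpp_high_pct)
  out$flagged <- out$ice > 1
  if (any(out$ice > max_ice))
    warning(sum(out$ice > max_ice), " ICE value(s) above ", max_ice,
            "; check the saturation anchoring")
  out
}

#' Evaluate the logistic recombination model
#'
#' `ICE(DPP) = (1 + (DPP/gamma)^alpha)^(-beta)`: equal to 1 at DPP = 0,
#' strictly decreasing, and tending to 0 as DPP grows, for positive
#' parameters.
#'
#' @param model a [logistic_ice_model()].
#' @param dpp dose per pulse in Gy (>= 0), vectorized.
#' @return ICE values in (0, 1].
#' @examples
#' m <- logistic_ice_model(0.76, 0.61, 5.12)
#' evaluate_logistic(m, c(0, 1, 10, 30))
#' @export
evaluate_logistic <- function(model, dpp) {
  stopifnot(inherits(model, "logistic_ice_model"), all(dpp >= 0))
  (1 + (dpp / model$gamma)^model$alpha)^(-model$beta)
}

#' Fit the logistic recombination model
#'
#' Unweighted nonlinear least squares of ICE against DPP with the logistic
#' model, parameters constrained positive, started from a small multi-start
#' grid (`alpha` in 0.5/1/2, `beta` in 0.3/0.6/1, `gamma` in median
#' DPP/1/5 Gy) with the lowest-SSR converged fit retained. Requires at
#' least 6 points spanning at least two decades of DPP, and a visible
#' recombination signal (an all-saturated input leaves `gamma`
#' unidentifiable).
#'
#' @param dpp dose-per-pulse values in Gy, or a data frame of ICE points
#'   (columns `dpp_gy`, `ice`) as returned by [compute_ice()].
#' @param ice ICE values (omit when `dpp` is a data frame).
#' @param pulse_duration pulse duration label in microseconds.
#' @param min_signal minimum required recombination depth: error if
#'   `min(ice)` exceeds `1 - min_signal` (default 0.05).
#' @param start optional `list(alpha, beta, gamma)` starting point tried
#'   before the multi-start grid; when it converges the grid is skipped.
#'   Used to seed Monte-Carlo refits from the base fit.
#' @return A [logistic_ice_model()] with the fit's `r2`
#'   (`1 - SS_res/SS_tot` on the supplied ICE values).
#' @export
fit_logistic <- function(dpp, ice = NULL, pulse_duration = NA_real_,
                         min_signal = 0.05, start = NULL) {
  if (is.data.frame(dpp)) {
    stopifnot(all(c("dpp_gy", "ice") %in% names(dpp)))
    if ("pulse_duration_us" %in% names(dpp) && is.na(pulse_duration) &&
        length(unique(dpp$pulse_duration_us)) == 1)
      pulse_duration <- dpp$pulse_duration_us[1]
    ice <- dpp$ice
    dpp <- dpp$dpp_gy
  }
  stopifnot(length(dpp) == length(ice), all(is.finite(dpp)),
            all(is.finite(ice)), all(dpp > 0), all(ice > 0))
  if (length(dpp) < 6)
    stop("fit_logistic: need at least 6 points")
  if (log10(max(dpp) / min(dpp)) < 2)
    stop("fit_logistic: points must span at least two decades of DPP")
  if (min(ice) > 1 - min_signal)
    stop("fit_logistic: no recombination signal (all ICE near 1); ",
         "gamma is unidentifiable")
  one_fit <- function(st)
    try(minpack.lm::nlsLM(
      ice ~ (1 + (dpp / gamma)^alpha)^(-beta), start = st,
      lower = rep(1e-4, 3),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)), silent = TRUE)
  if (!is.null(start)) {
    fit <- one_fit(start[c("alpha", "beta", "gamma")])
    if (!inherits(fit, "try-error")) {
      cf <- coef(fit)
      ssr <- sum(residuals(fit)^2)
      sstot <- sum((ice - mean(ice))^2)
      return(logistic_ice_model(cf[["alpha"]], cf[["beta"]], cf[["gamma"]],
                                pulse_duration = pulse_duration,
                                r2 = if (sstot > 0) 1 - ssr / sstot
                                     else NA_real_))
    }
  }
  starts <- expand.grid(alpha = c(0.5, 1, 2), beta = c(0.3, 0.6, 1),
                        gamma = c(median(dpp), 1, 5))
  best <- NULL
  tried <- character(0)
  for (i in seq_len(nrow(starts))) {
    st <- as.list(starts[i, ])
    tried <- c(tried, sprintf("(%.3g, %.3g, %.3g)", st$alpha, st$beta,
                              st$gamma))
    fit <- one_fit(st)
    if (!inherits(fit, "try-error")) {
      ssr <- sum(residuals(fit)^2)
      if (is.null(best) || ssr < best$ssr - 1e-14)
        best <- list(fit = fit, ssr = ssr)
    }
  }
  if (is.null(best))
    stop("fit_logistic: no start converged; tried starts ",
         paste(tried, collapse = ", "))
  cf <- coef(best$fit)
  sstot <- sum((ice - mean(ice))^2)
  r2 <- if (sstot > 0) 1 - best$ssr / sstot else NA_real_
  logistic_ice_model(cf[["alpha"]], cf[["beta"]], cf[["gamma"]],
                     pulse_duration = pulse_duration, r2 = r2)
}

#' Recombination correction factor from an ICE value
#'
#' The efficiency is the reciprocal of the product of the recombination and
#' polarity correction factors, `ICE = 1 / (k_s * k_pol)`; with the polarity
#' factor assumed (or measured) this returns `k_s = 1 / (ICE * k_pol)`.
#'
#' @param ice ion collection efficiency (> 0), vectorized.
#' @param k_pol polarity correction factor (default 1).
#' @return Recombination correction factor(s) `k_s`.
#' @export
saturation_factors <- function(ice, k_pol = 1) {
  stopifnot(all(ice > 0), all(k_pol > 0))
  1 / (ice * k_pol)
}

#' Plot ICE points and fitted curves
#'
#' Log-DPP plot of the ICE points with the fitted logistic curves overlaid,
#' one color per pulse duration.
#'
#' @param x data frame of ICE points ([compute_ice()]).
#' @param models optional named list of [logistic_ice_model()] keyed by
#'   pulse duration.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot_ice <- function(x, models = NULL, ...) {
  stopifnot(is.data.frame(x), all(c("dpp_gy", "ice") %in% names(x)))
  w <- if ("pulse_duration_us" %in% names(x)) x$pulse_duration_us else 1
  cols <- setNames(seq_along(unique(w)) + 1, sort(unique(w)))
  graphics::plot(x$dpp_gy, x$ice, log = "x", col = cols[as.character(w)],
                 xlab = "Dose per pulse (Gy)",
                 ylab = "Ion collection efficiency", ylim = c(0, 1.05), ...)
  if (!is.null(models)) {
    grid <- exp(seq(log(min(x$dpp_gy)), log(max(x$dpp_gy)),
                    length.out = 200))
    for (nm in names(models))
      graphics::lines(grid, evaluate_logistic(models[[nm]], grid),
                      col = cols[nm])
  }
  invisible(x)
}
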