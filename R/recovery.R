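## Replicate parameter-recovery experiments: generate noisy ICE curves from
## a known logistic model and refit, to characterize what the fit recovers
## under the measurement uncertainty budgets.

#' Replicate logistic parameter-recovery experiment
#'
#' Generates `n_rep` synthetic ICE curves from a known logistic model —
#' log-spaced DPP points with relative Gaussian noise on both axes: the ICE
#' budget on the efficiency, the dose-regime budget (below/above the
#' breakpoint) on the DPP — and refits the model to each, recording the
#' recovered parameters and the coefficient of determination of each fit on
#' its own noisy points.
#'
#' @param model generating [logistic_ice_model()].
#' @param n_rep number of replicate experiments (default 100).
#' @param n_points DPP points per experiment (default 30).
#' @param dpp_range DPP range in Gy (default 0.01-30, log-spaced).
#' @param sd_ice_pct relative ICE noise, percent (default 2.9, the combined
#'   charge + saturation budget).
#' @param sd_dpp_low_pct,sd_dpp_high_pct relative DPP noise below / above
#'   the breakpoint, percent (defaults 4.2 / 6.5).
#' @param breakpoint_gy dose-regime breakpoint (default 15 Gy).
#' @param seed integer seed.
#' @return Data frame with one row per replicate: `alpha`, `beta`, `gamma`,
#'   `r2`, `converged`.
#' @export
recovery_experiment <- function(model, n_rep = 100, n_points = 30,
                                dpp_range = c(0.01, 30), sd_ice_pct = 2.9,
                                sd_dpp_low_pct = 4.2, sd_dpp_high_pct = 6.5,
                                breakpoint_gy = 15, seed = 1L) {
  stopifnot(inherits(model, "logistic_ice_model"), n_rep >= 1,
            n_points >= 6)
  dpp0 <- exp(seq(log(dpp_range[1]), log(dpp_range[2]),
                  length.out = n_points))
  ice0 <- evaluate_logistic(model, dpp0)
  sd_x <- ifelse(dpp0 > breakpoint_gy, sd_dpp_high_pct,
                 sd_dpp_low_pct) / 100
  with_substream(seed, 33L, {
    rows <- lapply(seq_len(n_rep), function(i) {
      x <- dpp0 * (1 + rnorm(n_points, 0, sd_x))
      y <- ice0 * (1 + rnorm(n_points, 0, sd_ice_pct / 100))
      fit <- try(suppressWarnings(fit_logistic(x, y)), silent = TRUE)
      if (inherits(fit, "try-error"))
        data.frame(alpha = NA_real_, beta = NA_real_, gamma = NA_real_,
                   r2 = NA_real_, converged = FALSE)
      else
        data.frame(alpha = fit$alpha, beta = fit$beta, gamma = fit$gamma,
                   r2 = fit$r2, converged = TRUE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Summarize a recovery experiment
#'
#' Mean, Monte-Carlo standard error of the mean, and median of each
#' recovered parameter over the converged replicates.
#'
#' @param rec data frame from [recovery_experiment()].
#' @return Data frame with one row per parameter (`alpha`, `beta`, `gamma`,
#'   `r2`): `mean`, `se`, `median`, `n`.
#' @export
summarize_recovery <- function(rec) {
  stopifnot(is.data.frame(rec),
            all(c("alpha", "beta", "gamma", "r2") %in% names(rec)))
  rec <- rec[rec$converged, , drop = FALSE]
  do.call(rbind, lapply(c("alpha", "beta", "gamma", "r2"), function(p) {
    v <- rec[[p]]
    data.frame(parameter = p, mean = mean(v), se = sd(v) / sqrt(length(v)),
               median = median(v), n = length(v))
  }))
}
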