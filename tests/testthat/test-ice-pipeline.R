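# ICE pipeline: k_F condensation, BCT correction, saturation anchoring,
# ICE computation, and the logistic recombination model.

test_that("kf_table condenses duplicates and rejects missing conditions", {
  d <- data.frame(ssd_m = c(2, 2), grid_tension_v = 150,
                  pulse_duration_us = 3, replicate = 1:2, kf = c(1, 1))
  t1 <- kf_table(d)
  expect_equal(t1$kf_mean, 1)
  expect_equal(t1$kf_sd_rel_pct, 0)
  expect_error(kf_lookup(t1, 0.5, 150, 3), "no k_F")
  expect_equal(kf_lookup(t1, 2, 150, 3), 1)
  expect_error(kf_table(d[1, ]), ">= 2 replicates")
})

test_that("BCT correction rescales to the companion's beam output", {
  s <- data.frame(condition = 1, film_companion = c(TRUE, FALSE, FALSE),
                  charge_nc = c(1, 1, 1), bct_signal = c(10, 10, 20))
  out <- bct_correct(s)
  expect_equal(out$charge_corr_nc, c(1, 1, 0.5))
  s$bct_signal <- c(10, 10, 0)
  expect_error(bct_correct(s), "BCT signal")
  s2 <- data.frame(condition = 1, film_companion = rep(FALSE, 3),
                   charge_nc = 1, bct_signal = 1)
  expect_error(bct_correct(s2), "exactly one film-companion")
})

test_that("saturation anchoring excludes over-threshold charges", {
  dpp <- c(0.05, 0.1, 0.15, 0.2)
  pts <- data.frame(ssd_m = 2, dpp_gy = dpp, q_pp_nc = dpp / 8.197)
  expect_warning(fit_qsat(pts), "excluded")  # 0.2 Gy -> 24.4 pC > 20 pC
  cc <- suppressWarnings(fit_qsat(pts))
  expect_equal(cc$value, 8.197, tolerance = 1e-12)
  expect_equal(1 / cc$value, 0.12200, tolerance = 1e-4)  # Q_sat(1 Gy), nC
  expect_equal(nrow(attr(cc, "anchors")), 3)
  expect_error(suppressWarnings(fit_qsat(pts[4, ])),
               "fewer than 3|no points")
  expect_error(fit_qsat(pts, ref_ssd = 0.5), "no points")
})

test_that("zero-noise anchors recover the coefficient to within 1%", {
  tr <- zero_truth()
  g <- replica_grid()
  s <- generate_uhdr_session(tr, g)
  pts <- chamber_points(bct_correct(s), kf_table(generate_kf_table(tr, g)))
  cc <- fit_qsat(pts)
  expect_lt(abs(cc$value / tr$calib_coefficient - 1), 0.01)
})

test_that("compute_ice applies the saturation identity and budgets", {
  pts <- data.frame(dpp_gy = c(1, 1, 20, 1),
                    q_pp_nc = c(1 / 8.197, 0.0610, 1, 1.02 / 8.197))
  ice <- compute_ice(pts, calibration_coefficient(8.197))
  expect_equal(ice$ice[1], 1)
  expect_equal(ice$ice[2], 0.0610 * 8.197, tolerance = 1e-12)  # 0.50002
  expect_equal(ice$sd_ice_pct, rep(5.8, 4))
  expect_equal(ice$sd_dpp_pct, c(4.2, 4.2, 6.5, 4.2))
  expect_equal(ice$flagged, c(FALSE, FALSE, FALSE, TRUE))
  expect_warning(
    compute_ice(data.frame(dpp_gy = 1, q_pp_nc = 1.1 / 8.197),
                calibration_coefficient(8.197)), "above 1.05")
  expect_error(compute_ice(data.frame(dpp_gy = -1, q_pp_nc = 1),
                           calibration_coefficient(8.197)), "non-positive")
})

test_that("zero-noise session reproduces the true ICE pointwise", {
  tr <- zero_truth()
  g <- small_grid()
  pts <- chamber_points(bct_correct(generate_uhdr_session(tr, g)),
                        kf_table(generate_kf_table(tr, g)))
  ice <- compute_ice(pts, calibration_coefficient(tr$calib_coefficient))
  for (w in c(1, 3)) {
    i <- ice$pulse_duration_us == w
    expect_equal(ice$ice[i],
                 evaluate_logistic(tr$ice_models[[as.character(w)]],
                                   ice$dpp_gy[i]),
                 tolerance = 1e-10)
  }
})

test_that("evaluate_logistic matches the closed form and its limits", {
  m1 <- ref_model_1us(); m3 <- ref_model_3us()
  expect_equal(evaluate_logistic(m1, 0), 1)
  expect_equal(evaluate_logistic(m1, 1), (1 + (1 / 5.12)^0.76)^(-0.61))
  expect_equal(evaluate_logistic(m1, 1), 0.8565, tolerance = 1e-4)
  expect_equal(evaluate_logistic(m3, 10), 0.6184, tolerance = 1e-4)
  d <- exp(seq(log(1e-3), log(100), length.out = 200))
  v <- evaluate_logistic(m1, d)
  expect_true(all(diff(v) < 0))             # strictly decreasing
  expect_lt(evaluate_logistic(m1, 1e8), 1e-3)  # -> 0 at large DPP
})

test_that("the short-pulse curve lies below the long-pulse curve", {
  d <- exp(seq(log(0.2), log(30), length.out = 100))
  expect_true(all(evaluate_logistic(ref_model_1us(), d) <
                    evaluate_logistic(ref_model_3us(), d)))
})

test_that("fit_logistic recovers exact parameters from noiseless points", {
  d <- exp(seq(log(0.01), log(30), length.out = 12))
  fit <- fit_logistic(d, logistic_oracle(d, 0.76, 0.61, 5.12),
                      pulse_duration = 1)
  expect_equal(fit$alpha, 0.76, tolerance = 1e-6)
  expect_equal(fit$beta, 0.61, tolerance = 1e-6)
  expect_equal(fit$gamma, 5.12, tolerance = 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_equal(fit$pulse_duration, 1)
})

test_that("fit_logistic recovers random positive parameter triples", {
  set.seed(77)
  d <- exp(seq(log(0.01), log(30), length.out = 15))
  for (rep in 1:100) {
    a <- stats::runif(1, 0.4, 2); b <- stats::runif(1, 0.2, 1.2)
    g <- stats::runif(1, 0.5, 10)
    y <- logistic_oracle(d, a, b, g)
    if (min(y) > 0.95) next  # no recombination signal at these parameters
    fit <- fit_logistic(d, y)
    expect_equal(c(fit$alpha, fit$beta, fit$gamma), c(a, b, g),
                 tolerance = 1e-4)
  }
})

test_that("fit_logistic rejects unusable inputs", {
  d <- exp(seq(log(0.01), log(30), length.out = 10))
  expect_error(fit_logistic(d[1:5], logistic_oracle(d[1:5], 1, 0.5, 3)),
               "at least 6")
  d2 <- seq(1, 5, length.out = 10)
  expect_error(fit_logistic(d2, logistic_oracle(d2, 1, 0.5, 3)),
               "two decades")
  expect_error(fit_logistic(d, rep(0.999, 10)), "unidentifiable")
})

test_that("saturation factors are the reciprocal of ICE times k_pol", {
  expect_equal(saturation_factors(1), 1)
  expect_equal(saturation_factors(0.5), 2)
  expect_equal(saturation_factors(0.55), 1 / 0.55, tolerance = 1e-12)
  expect_equal(saturation_factors(0.5, k_pol = 2), 1)
  expect_error(saturation_factors(0))
})

test_that("noisy end-to-end pipeline recovers the generating curves", {
  # full chain at the beam line's noise levels: the fitted curves (not the
  # sloppy individual parameters) are the stable recovery target
  tr <- default_truth(seed = 21)
  g <- replica_grid()
  fit <- suppressWarnings(suppressMessages(
    run_fit(generate_uhdr_session(tr, g),
            generate_film_calibration_set(tr),
            generate_kf_table(tr, g),
            mc = mc_spec(n_draws_curve = 150))))
  d <- exp(seq(log(0.2), log(30), length.out = 50))
  for (w in c("1", "3")) {
    truth_curve <- evaluate_logistic(tr$ice_models[[w]], d)
    fit_curve <- evaluate_logistic(fit$models[[w]], d)
    expect_lt(max(abs(fit_curve - truth_curve)), 0.05)
    expect_gt(fit$models[[w]]$r2, 0.9)
  }
  expect_lt(abs(fit$qsat$value / tr$calib_coefficient - 1), 0.05)
})
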