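# Synthetic generator: zero-noise identities, seeded reproducibility, and
# convergence of empirical SDs to the configured noise levels.

test_that("noise and beam-config constructors validate their invariants", {
  expect_error(noise_spec(shot_sd = -0.01), "in \\[0, 0.2\\]")
  expect_error(noise_spec(shot_sd = 0.25), "in \\[0, 0.2\\]")
  expect_error(noise_spec(shot_sd = 0.004, residual_sd = 0.01),
               "residual_sd")
  expect_error(beam_config(ssd = 2, grid_tension = 150, pulse_duration = 3,
                           n_pulses = 0, dpp_true = 1), "n_pulses")
  expect_error(beam_config(ssd = 2, grid_tension = 150, pulse_duration = 3,
                           n_pulses = 1, dpp_true = -1))
  expect_error(logistic_ice_model(0, 0.5, 1), "> 0")
})

test_that("zero-noise film calibration inverts exactly through the truth", {
  tab <- generate_film_calibration_set(zero_truth())
  expect_equal(nrow(tab), 20L)  # 10 dose points x 2 films
  by_pt <- split(tab, tab$point)
  for (d in by_pt) {
    expect_equal(d$netod[1], d$netod[2])          # duplicate films identical
    expect_equal(film_dose_from_od(d$netod[1]), d$dose_gy[1],
                 tolerance = 1e-10)
  }
  expect_error(generate_film_calibration_set(zero_truth(), doses = c(0, 1)),
               "strictly positive")
  expect_error(generate_film_calibration_set(zero_truth(),
                                             doses = c(2, 1, 3)),
               "ascending")
})

test_that("zero-noise session satisfies the charge and film identities", {
  tr <- zero_truth()
  grid <- small_grid()
  s <- generate_uhdr_session(tr, grid)
  expect_equal(nrow(s), 3L * length(grid))
  for (ci in unique(s$condition)) {
    d <- s[s$condition == ci, ]
    cfg <- grid[[ci]]
    model <- tr$ice_models[[as.character(cfg$pulse_duration)]]
    q_ideal <- d$charge_nc * k_tp(d$temperature_c, d$pressure_hpa)
    ice_implied <- q_ideal * tr$calib_coefficient /
      (cfg$n_pulses * cfg$dpp_true)
    expect_equal(ice_implied,
                 rep(evaluate_logistic(model, cfg$dpp_true), 3),
                 tolerance = 1e-12)
    kf <- kf_ground_truth(cfg$ssd, cfg$grid_tension, cfg$pulse_duration)
    expect_equal(d$film_dose_gy[d$film_companion],
                 cfg$n_pulses * cfg$dpp_true / kf, tolerance = 1e-12)
  }
  expect_error(
    generate_uhdr_session(tr, list(beam_config(0.5, 150, 5, 1, 1))),
    "no ICE model")
})

test_that("zero-noise k_F duplicates are identical; lookups resolve", {
  k <- generate_kf_table(zero_truth(), small_grid())
  expect_true(all(tapply(k$kf, interaction(k$ssd_m, k$grid_tension_v,
                                           k$pulse_duration_us, drop = TRUE),
                         function(x) diff(range(x)) == 0)))
  tbl <- kf_table(k)
  expect_true(all(tbl$kf_sd_rel_pct == 0))
  expect_equal(attr(tbl, "pooled_sd_pct"), 0)
})

test_that("seeded generation is bit-reproducible and substreams differ", {
  tr <- default_truth(seed = 42)
  g <- small_grid()
  expect_identical(generate_uhdr_session(tr, g),
                   generate_uhdr_session(tr, g))
  expect_identical(generate_film_calibration_set(tr),
                   generate_film_calibration_set(tr))
  expect_identical(generate_kf_table(tr, g), generate_kf_table(tr, g))
  tr2 <- default_truth(seed = 43)
  expect_false(identical(generate_uhdr_session(tr2, g),
                         generate_uhdr_session(tr, g)))
  # generator calls do not disturb the caller's RNG stream
  set.seed(1); a <- rnorm(1)
  set.seed(1); invisible(generate_uhdr_session(tr, g)); b <- rnorm(1)
  expect_identical(a, b)
})

test_that("generated quantities are strictly positive under default noise", {
  tr <- default_truth(seed = 3)
  g <- small_grid()
  s <- generate_uhdr_session(tr, g)
  expect_true(all(s$charge_nc > 0))
  expect_true(all(s$bct_signal > 0))
  expect_true(all(s$film_dose_gy[s$film_companion] > 0))
  expect_true(all(generate_kf_table(tr, g)$kf > 0))
  tab <- generate_film_calibration_set(tr)
  expect_true(all(tab$netod > 0) && all(tab$dose_gy > 0))
})

test_that("inter-film SD converges to 0.5% over many replicate pairs", {
  # 10^4 dose points around 5 Gy; pooled pair SD estimates film_interfilm_sd
  # with relative MC error 1/sqrt(2n)
  tr <- default_truth(seed = 11)
  tab <- generate_film_calibration_set(
    tr, doses = seq(5, 5.5, length.out = 10000))
  pair_sd <- tapply(seq_len(nrow(tab)), tab$point, function(i) {
    od <- tab$netod[i]
    sd(od) / mean(od)
  })
  pooled <- sqrt(mean(pair_sd^2))
  mc_band <- 3 * 0.005 / sqrt(2 * 10000)
  expect_lt(abs(pooled - 0.005), mc_band)
})

test_that("k_F duplicate SD converges to 2.5% over many conditions", {
  grid <- lapply(seq(120, 300, length.out = 10000), function(gt)
    beam_config(ssd = 0.5, grid_tension = gt, pulse_duration = 3,
                n_pulses = 1, dpp_true = 1))
  k <- generate_kf_table(default_truth(seed = 5), grid)
  tbl <- kf_table(k)
  pooled <- attr(tbl, "pooled_sd_pct")
  mc_band <- 3 * 2.5 / sqrt(2 * 10000)
  expect_lt(abs(pooled - 2.5), mc_band)
})

test_that("BCT correction reduces the shot SD from 1.0% to 0.4%", {
  # 1000 single-pulse shots at a low-DPP condition (flat ICE isolates the
  # beam-output variability); SD of a sample of n=1000 carries a relative
  # MC error of 1/sqrt(2(n-1))
  s <- generate_uhdr_session(default_truth(seed = 9),
                             list(anchor_config(dpp = 0.02)),
                             n_shots = 1000)
  q_raw <- s$charge_nc * k_tp(s$temperature_c, s$pressure_hpa)
  sd_raw <- sd(q_raw) / mean(q_raw)
  corr <- bct_correct(s)
  i <- !corr$film_companion
  q_corr <- corr$charge_corr_nc[i] * k_tp(corr$temperature_c[i],
                                          corr$pressure_hpa[i])
  sd_corr <- sd(q_corr) / mean(q_corr)
  band <- 3 / sqrt(2 * 999)
  expect_lt(abs(sd_raw - 0.010), 0.010 * band + 2e-4)
  expect_lt(abs(sd_corr - 0.004), 0.004 * band + 2e-4)
})
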