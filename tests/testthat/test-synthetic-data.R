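test_that("configuration invariants are enforced", {
  expect_error(synth_config(csd_onset = 50, csd_offset = 40), "csd_onset")
  expect_error(synth_config(csd_offset = 110, ac_hyper_start = 107),
               "DC shift")
  expect_error(synth_config(ac_hyper_end = 700), "past the recording")
  expect_error(synth_config(shared_coupling = 1.2), "shared_coupling")
  expect_error(synth_config(dt = 0), "dt")
  expect_error(synth_config(noise_band = c(45, 0.5)), "noise_band")
})

test_that("default configuration yields 1,200,000 samples per channel", {
  rec <- generate_csd_pair(synth_config(seed = 1L))
  expect_s3_class(rec, "raw_recording")
  expect_length(rec$left, 1200000L)
  expect_length(rec$right, 1200000L)
  expect_identical(rec$t0_index, 600001L)
})

test_that("a fixed seed reproduces the recording bit for bit", {
  cfg <- small_csd_config(seed = 7L)
  a <- generate_csd_pair(cfg)
  b <- generate_csd_pair(cfg)
  expect_identical(a$left, b$left)
  expect_identical(a$right, b$right)
  cfg2 <- small_csd_config(seed = 8L)
  expect_false(identical(generate_csd_pair(cfg2)$left, a$left))
})

test_that("fully decoupled channels show near-zero windowed MI and TE", {
  cfg <- small_csd_config(seed = 3L, shared_coupling = 0, drive_gain = 0,
                          ac_gain = 1, dc_amplitude = 0)
  det <- detrend(generate_csd_pair(cfg))
  # analysis-scale windows: 20 s at the full 1-kHz rate
  ser <- compute_series(det, window_grid(20, 2, 2))
  expect_lt(max(abs(ser$mi)), 0.03)
  expect_lt(max(abs(ser$te_l2r)), 0.03)
  expect_lt(max(abs(ser$te_r2l)), 0.03)
})

test_that("with symmetric shared drive the two TE directions agree on average", {
  cfg <- small_csd_config(seed = 5L, drive_gain = 0,
                          decouple_start = 39, decouple_end = 40)
  det <- detrend(generate_csd_pair(cfg))
  ser <- compute_series(det, window_grid(10, 4, 3),
                        measures = c("te_l2r", "te_r2l"))
  expect_lt(abs(mean(ser$te_l2r) - mean(ser$te_r2l)), 0.01)
})

test_that("Gaussian pair matches its closed-form mutual information", {
  expect_equal(gaussian_mi_theory(0), 0)
  expect_equal(gaussian_mi_theory(0.9), 0.8303656, tolerance = 1e-6)
  p <- generate_gaussian_pair(0.5, 20000, seed = 2L)
  expect_equal(cor(p$left, p$right), 0.5, tolerance = 0.02)
  expect_lt(abs(mi_ksg(p$left, p$right) - gaussian_mi_theory(0.5)), 0.02)
  expect_error(generate_gaussian_pair(1.0, 1000), "rho")
  expect_error(generate_gaussian_pair(0.5, 50), "n must")
})

test_that("coupled AR pair is directional and matches its closed form", {
  expect_equal(ar_te_theory(0.5, 0.5), 0.1348318, tolerance = 1e-6)
  expect_equal(ar_te_theory(0.5, 0), 0)
  ar0 <- generate_coupled_ar(0.6, 0, 20000, seed = 2L)
  expect_lt(abs(te_ksg(ar0$right, ar0$left)), 0.01)
  expect_lt(abs(te_ksg(ar0$left, ar0$right)), 0.01)
  expect_error(generate_coupled_ar(1.1, 0.5, 5000), "AR coefficients")
})

test_that("rail artifacts are additive, validated, and exactly reversible", {
  rec <- raw_recording(rnorm(5000, sd = 1e-4), rnorm(5000, sd = 1e-4),
                       dt = 0.001, t0_index = 2500L)
  expect_identical(inject_rail_artifact(rec, list()), rec)
  one <- inject_rail_artifact(rec, list(c(0.5, 1.5)), sign = -1, rail = 10)
  tm <- recording_time(rec)
  span <- tm >= 0.5 & tm < 1.5
  expect_equal(one$left[span], rec$left[span] - 10)
  expect_identical(one$left[!span], rec$left[!span])
  expect_error(
    inject_rail_artifact(rec, list(c(0, 1), c(0.5, 1.5))), "overlapping")
  fixed <- repair_saturation(one, rail = 10)
  expect_equal(fixed$left, rec$left)
})
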