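test_that("time-domain features match hand-computed values", {
  f <- time_domain_features(rep(1000, 300))
  expect_equal(f$hr, 60)
  expect_equal(f$rri, 1000)
  expect_equal(f$sdnn, 0)
  expect_equal(f$rmssd, 0)

  g <- time_domain_features(c(1000, 990, 1010, 1000))
  expect_equal(g$sdnn, sqrt(200 / 3), tolerance = 1e-12)
  expect_equal(g$rmssd, sqrt((100 + 400 + 100) / 3), tolerance = 1e-12)

  alt <- rep(c(1000, 1010), 150)
  h <- time_domain_features(alt)
  expect_equal(h$rmssd, 10, tolerance = 1e-3)
  expect_equal(h$sdnn, 5, tolerance = 0.02)

  expect_error(time_domain_features(c(1000, 1000)), "3 beats")
})

test_that("HR and RRI satisfy hr = 60000/rri, and deviations scale linearly", {
  set.seed(1)
  rr <- 900 + rnorm(200, 0, 25)
  f <- time_domain_features(rr)
  expect_equal(f$hr, 60000 / f$rri)
  g <- time_domain_features(mean(rr) + 3 * (rr - mean(rr)))
  expect_equal(g$sdnn, 3 * f$sdnn, tolerance = 1e-10)
  expect_equal(g$rmssd, 3 * f$rmssd, tolerance = 1e-10)
})

test_that("resampling interpolates linearly on a 4 Hz grid", {
  s <- beat_series(0:299, rep(1000, 300))
  x <- resample_tachogram(s, 0, 300)
  expect_length(x, 1200)
  expect_true(all(x == 1000))

  two <- beat_series(c(0, 1), c(1000, 1100))
  y <- resample_tachogram(two, 0, 1)
  expect_equal(y[3], 1050)  # sample at t = 0.5
  expect_error(resample_tachogram(beat_series(0, 1000), 0, 10), "2 beats")
})

test_that("Welch windowing and normalization are correct", {
  expect_equal(welch_psd(rnorm(1200))$n_windows, 15)
  expect_error(welch_psd(rnorm(100)), "256")

  set.seed(2)
  x <- rnorm(1200, 0, 30)
  ps <- welch_psd(x)
  expect_equal(sum(ps$psd) * ps$df, var(x), tolerance = 0.1)

  flat <- welch_psd(rep(500, 1200))
  expect_lt(max(flat$psd), 1e-20)
})

test_that("band powers localize pure tones and integrate their variance", {
  t <- (0:1199) / 4
  hf_tone <- 1000 + 50 * sin(2 * pi * 0.25 * t)
  bp <- band_powers(welch_psd(hf_tone))
  expect_gte(bp$hf / bp$tp, 0.9)
  expect_equal(bp$hf, 50^2 / 2, tolerance = 0.15)

  lf_tone <- 1000 + 50 * sin(2 * pi * 0.10 * t)
  bl <- band_powers(welch_psd(lf_tone))
  expect_gte(bl$lf / bl$tp, 0.9)
  expect_lte(bl$hf / bl$tp, 0.05)

  # moving the tone from 0.10 to 0.25 Hz moves >= 90% of power LF -> HF
  expect_gte(bl$lf / bl$tp - bp$lf / bp$tp, 0.9)
})

test_that("total power is exactly the sum of the three bands", {
  set.seed(3)
  for (i in 1:5) {
    bp <- band_powers(welch_psd(rnorm(1200, 0, 20)))
    expect_identical(bp$tp, bp$vlf + bp$lf + bp$hf)
  }
})

test_that("zero HF power yields a flagged missing ratio", {
  # tone entirely below the HF band, so HF bins hold only leakage;
  # construct a literal zero-HF PSD instead
  ps <- welch_psd(rnorm(1200))
  ps$psd[ps$freq >= 0.15] <- 0
  expect_warning(bp <- band_powers(ps), "LF/HF")
  expect_true(is.na(bp$lf_hf))
})

test_that("phase features average the two segments arithmetically", {
  p <- modulation_profile(noise_sd = 3)
  s <- generate_tachogram(p, duration = 14400, seed = 12)
  clean <- filter_ectopic(s)
  grid <- segment_series(clean)
  f1 <- segment_features(clean, grid, 1)
  f2 <- segment_features(clean, grid, 2)
  ph <- phase_features(clean, grid, "early")
  for (nm in names(ph)) {
    expect_equal(ph[[nm]], (f1[[nm]] + f2[[nm]]) / 2, tolerance = 1e-12)
  }
  # the ratio is averaged as a ratio, not recomputed from averaged powers
  expect_equal(ph$lf_hf, (f1$lf_hf + f2$lf_hf) / 2)
})

test_that("delta features subtract early from middle", {
  a <- list(hr = 60, rri = 1000, sdnn = 10, rmssd = 20, vlf = 100,
            lf = 200, hf = 300, tp = 600, lf_hf = 2 / 3)
  expect_true(all(unlist(delta_features(a, a)) == 0))
  b <- a
  b$sdnn <- 25
  d <- delta_features(a, b)
  expect_equal(d$d_sdnn, 15)
  b$lf_hf <- NA_real_
  expect_true(is.na(delta_features(a, b)$d_lf_hf))
})

test_that("amplitude rising early->middle gives positive deltas", {
  p <- modulation_profile(base_rr = 900, amp_hf = 30, amp_lf = 25,
                          noise_sd = 3,
                          traj_hf = c(1, 2, 1), traj_lf = c(1, 1.7, 1.2))
  s <- generate_tachogram(p, duration = 14400, seed = 23)
  f <- session_features(s)
  expect_gt(f$d_hf, 0)
  expect_gt(f$d_lf, 0)
  expect_gt(f$middle_hf, f$early_hf)
})

test_that("delta scaling divides by the reporting units", {
  df <- data.frame(d_hf = 250, d_tp = 1000, d_rri = 50, d_hr = 2)
  sc <- scale_delta_features(df)
  expect_equal(sc$d_hf, 2.5)
  expect_equal(sc$d_tp, 10)
  expect_equal(sc$d_rri, 0.5)
  expect_equal(sc$d_hr, 2)
})
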