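test_that("high-pass preprocessing removes DC, keeps 2.4 Hz, kills 0.1 Hz", {
  n <- 15000; t <- (0:(n - 1)) / 500
  dc <- preprocess_pulsatile(cv_ts(rep(3.7, n), 500))
  expect_lt(max(abs(ts_values(dc))), 1e-8 * 3.7)
  pass <- preprocess_pulsatile(cv_ts(sin(2 * pi * 2.4 * t), 500))
  expect_lt(abs(max(abs(ts_values(pass)[4000:11000])) - 1), 0.02)
  stopb <- preprocess_pulsatile(cv_ts(sin(2 * pi * 0.1 * t), 500))
  expect_lt(max(abs(ts_values(stopb)[4000:11000])), 0.01)
  expect_error(preprocess_pulsatile(cv_ts(rep(1, 100), rate = 2)),
               "cv_imp_rate_too_low")
  expect_error(preprocess_pulsatile(cv_ts(rep(1, 100), rate = 500)),
               "cv_imp_too_short")
})

test_that("window segmentation count obeys floor((T - 30)/15) + 1", {
  for (rate in c(100, 500)) {
    cases <- list(c(30, 1), c(44.9, 1), c(120, 7), c(600, 39))
    for (cs in cases) {
      ts <- cv_ts(rep(0, round(cs[1] * rate)), rate)
      w <- segment_windows(ts, 30, 15)
      expect_identical(nrow(w), as.integer(cs[2]))
      expect_equal(w$start, seq(0, by = 15, length.out = cs[2]))
    }
  }
  expect_error(segment_windows(cv_ts(rep(0, 100), 100), 30, 15),
               "cv_imp_too_short")
})

test_that("spectrum amplitudes are exact for exact-bin sinusoids", {
  t <- (0:14999) / 500
  sp <- compute_spectrum(sin(2 * pi * 2.4 * t), 500)
  expect_equal(sp$amp[73], 1, tolerance = 1e-12)     # bin 72 is index 73
  expect_lt(max(sp$amp[-73]), 1e-10)
  expect_true(all(compute_spectrum(rep(0, 15000), 500)$amp == 0))
  sp2 <- compute_spectrum(2 * sin(2 * pi * 2.4 * t) + 0.5 * sin(2 * pi * 4.8 * t), 500)
  expect_equal(sp2$amp[73], 2, tolerance = 1e-12)
  expect_equal(sp2$amp[145], 0.5, tolerance = 1e-12)
})

test_that("cardiac peak finding locates the fundamental and harmonic", {
  t <- (0:14999) / 500
  sp <- compute_spectrum(sin(2 * pi * 2.4 * t) + 0.5 * sin(2 * pi * 4.8 * t), 500)
  pk <- find_cardiac_peaks(sp)
  expect_identical(c(pk$fund, pk$harm), c(73L, 145L))
  expect_equal(pk$f0, 2.4)

  # harmonic above the fundamental band limit is still found
  sp2 <- compute_spectrum(sin(2 * pi * 3.9 * t) + 0.4 * sin(2 * pi * 7.8 * t), 500)
  pk2 <- find_cardiac_peaks(sp2)
  expect_equal(sp2$freq[pk2$fund], 3.9)
  expect_equal(sp2$freq[pk2$harm], 7.8)

  # perfectly flat spectrum has no local maximum -> rejected, not an error
  flat <- list(freq = sp$freq, amp = rep(1, length(sp$amp)))
  expect_false(find_cardiac_peaks(flat)$ok)
})

test_that("window SNR matches a brute-force band re-summation", {
  set.seed(33)
  t <- (0:14999) / 500
  x <- 0.8 * sin(2 * pi * 2.4 * t) + 0.3 * sin(2 * pi * 4.8 * t) + rnorm(15000, sd = 0.5)
  sp <- compute_spectrum(x, 500)
  pk <- find_cardiac_peaks(sp)
  got <- window_snr(sp, pk$fund, pk$harm)
  num <- sum(sp$amp[(pk$fund - 1):(pk$fund + 1)]^2)
  between <- (pk$fund + 3):(pk$harm - 3)
  expect_equal(got, num / sum(sp$amp[between]^2), tolerance = 1e-12)
  expect_gt(window_snr(compute_spectrum(0.8 * sin(2 * pi * 2.4 * t) +
                                          0.3 * sin(2 * pi * 4.8 * t), 500),
                       pk$fund, pk$harm), 1e6)
  expect_error(window_snr(sp, 73, 76), "cv_imp_peaks_too_close")
})

test_that("pure noise windows fall below the SNR threshold with high probability", {
  below <- vapply(1:100, function(s) {
    set.seed(s)
    sp <- compute_spectrum(rnorm(3000), 100)
    pk <- find_cardiac_peaks(sp)
    if (!pk$ok || pk$harm <= pk$fund + 4) return(TRUE)
    window_snr(sp, pk$fund, pk$harm) < 3
  }, logical(1))
  expect_gt(mean(below), 0.9)
})

test_that("the rejection rule accepts at the threshold and rejects strictly below", {
  expect_true(reject_window(10, 10))
  expect_false(reject_window(10, 2.9))
  expect_false(reject_window(2.9, 10))
  expect_true(reject_window(3.0, 3.0))
})

test_that("impedance index sums the spectral magnitude ratios", {
  t <- (0:14999) / 500
  sq <- compute_spectrum(sin(2 * pi * 2.4 * t) + 0.5 * sin(2 * pi * 4.8 * t), 500)
  expect_equal(impedance_index(sq, sq, 73, 145), 2)
  sp3 <- sq; sp3$amp <- sq$amp * 3
  sp3$amp[145] <- sq$amp[145]          # P = 3Q at f0, P = Q at f1
  expect_equal(impedance_index(sp3, sq, 73, 145), 4)
  # random two-tone pair vs closed-form amplitudes
  set.seed(44)
  for (k in 1:5) {
    a <- runif(4, 0.2, 3)
    sq2 <- compute_spectrum(two_tone(a[1], a[2]), 500)
    sp2 <- compute_spectrum(two_tone(a[3], a[4], phi1 = 1.1, phi2 = -0.4), 500)
    expect_equal(impedance_index(sp2, sq2, 73, 145),
                 a[3] / a[1] + a[4] / a[2], tolerance = 1e-9)
  }
  # |Q| at numerical floor rejects the window
  zq <- list(freq = sq$freq, amp = c(1, rep(1e-20, length(sq$amp) - 1L)))
  expect_true(is.na(impedance_index(sq, zq, 73, 145)))
})

test_that("window means equal brute-force averages of the raw channels", {
  n <- 3000
  pre <- cv_ts(cbind(ABP = rep(80, n), ICP = rep(15, n)), 100)
  flow <- cv_ts(rep(1.4, n), 100, channels = "CBF")
  m <- summarize_window(pre, flow, 1, n)
  expect_equal(unname(m), c(65, 80, 15, 1.4))
  ramp <- cv_ts(cbind(ABP = seq(70, 90, length.out = n), ICP = rep(0, n)), 100)
  expect_equal(summarize_window(ramp, flow, 1, n)[["abp"]], 80)
  set.seed(55)
  noisy <- cv_ts(cbind(ABP = 80 + rnorm(n), ICP = 15 + rnorm(n)), 100)
  m2 <- summarize_window(noisy, flow, 101, 700)
  expect_equal(m2[["abp"]], sum(ts_values(noisy)[101:700, "ABP"]) / 600,
               tolerance = 1e-12)
  expect_error(summarize_window(pre, flow, 1, n + 1), "cv_imp_window_gap")
})

test_that("scaling P scales every accepted index by the same constant", {
  rec <- known_ratio_recording(0.25, 0.1, 0.4, 0.12)
  w1 <- analyze_recording(rec$flow, rec$vol, rec$pressure)
  expect_true(all(w1$accepted))
  # dyadic constant: scaling is exact in floating point, so equality is exact
  c2 <- 4
  w2 <- analyze_recording(rec$flow,
                          cv_ts(c2 * ts_values(rec$vol), 500, channels = "HbT"),
                          rec$pressure)
  expect_equal(w2$z_cbv, c2 * w1$z_cbv, tolerance = 1e-12)
  # arbitrary constant: equal up to recursive-filter rounding
  c0 <- 3.7
  w2b <- analyze_recording(rec$flow,
                           cv_ts(c0 * ts_values(rec$vol), 500, channels = "HbT"),
                           rec$pressure)
  expect_equal(w2b$z_cbv, c0 * w1$z_cbv, tolerance = 1e-9)
  # scaling Q divides the index: flow pulsatility scaled around its mean
  flow_scaled <- cv_ts(1 + c2 * (ts_values(rec$flow) - 1), 500, channels = "CBF")
  w3 <- analyze_recording(flow_scaled, rec$vol, rec$pressure)
  expect_equal(w3$z_cbv, w1$z_cbv / c2, tolerance = 1e-12)
})

test_that("integer-sample delays leave window indices unchanged (magnitudes only)", {
  rec <- known_ratio_recording(0.3, 0.12, 0.5, 0.2, dur = 120)
  w1 <- analyze_recording(rec$flow, rec$vol, rec$pressure)
  k <- 250  # half a second
  shift <- function(ts, ch) {
    v <- ts_values(ts)
    cv_ts(v[c((k + 1):nrow(v), 1:k), , drop = FALSE], 500,
          channels = ts_channels(ts))
  }
  w2 <- analyze_recording(shift(rec$flow), shift(rec$vol), rec$pressure)
  # fully covered (interior) windows see pure shifted tones and are invariant;
  # the first/last windows touch the zero-phase filter's edge transients
  interior <- 2:(nrow(w1) - 1L)
  expect_equal(w2$z_cbv[interior], w1$z_cbv[interior], tolerance = 1e-9)
})

test_that("the CPP-based index is the same computation with dP = dCPP", {
  # ABP pulse amplitudes (4, 1.6) are exactly 16 x the flow amplitudes
  # (0.25, 0.10); with unit transfer the CPP index must be 16 x the CBV index
  spec <- protocol_spec(abp_pulse = c(4, 1.6), icp_pulse = c(0, 0),
                        slow_noise_sd = 0, baseline_s = 100,
                        map_steps = 0, icp_steps = 0)
  p <- generate_protocol(spec, 1)
  h <- generate_hemodynamics(p, ground_truth_constant(c(1, 1)), seed = 1,
                             pulse_amp = c(0.25, 0.10), cbf_noise_sd = 0,
                             hbt_noise_sd = 0, hbt_drift_sd = 0)
  flow <- cv_ts(ts_channel(h$optical, "CBF"), 500, channels = "CBF")
  vol <- cv_ts(ts_channel(h$optical, "HbT"), 500, channels = "HbT")
  pal <- align_streams(p, flow, sync_events(c(1, 199), c(1, 199)))
  w <- analyze_recording(flow, vol, pal)
  expect_true(all(w$accepted))
  # tolerance reflects linear interpolation of the 100 Hz pressure stream
  expect_equal(w$z_cpp / w$z_cbv, rep(16, nrow(w)), tolerance = 0.02)
})
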