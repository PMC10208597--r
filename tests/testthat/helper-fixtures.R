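# Shared in-code fixtures for the suite. All synthetic, built at test time.

# two exact-bin cardiac tones (2.4 / 4.8 Hz at 30 s windows) on a uniform grid
two_tone <- function(a1, a2, rate = 500, dur = 30, f0 = 2.4,
                     phi1 = 0, phi2 = 0) {
  t <- (seq_len(round(dur * rate)) - 1L) / rate
  a1 * sin(2 * pi * f0 * t + phi1) + a2 * sin(4 * pi * f0 * t + phi2)
}

# write a small time-series CSV and return its path
write_ts_csv <- function(time, ..., dir = withr::local_tempdir(.local_envir = parent.frame())) {
  df <- data.frame(time = time, ...)
  path <- file.path(dir, "ts.csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# a short noiseless recording whose impedance index is known in closed form:
# Q carries tones (qa1, qa2), P carries (pa1, pa2); index = pa1/qa1 + pa2/qa2
known_ratio_recording <- function(qa1, qa2, pa1, pa2, dur = 90, rate = 500) {
  n <- round(dur * rate)
  t <- (seq_len(n) - 1L) / rate
  flow <- cv_ts(1 + qa1 * sin(2 * pi * 2.4 * t) + qa2 * sin(4 * pi * 2.4 * t),
                rate, channels = "CBF")
  vol <- cv_ts(pa1 * sin(2 * pi * 2.4 * t + 0.4) +
                 pa2 * sin(4 * pi * 2.4 * t + 0.9),
               rate, channels = "HbT")
  pressure <- cv_ts(cbind(ABP = rep(80, n) + 2 * sin(2 * pi * 2.4 * t),
                          ICP = rep(15, n)), rate)
  list(flow = flow, vol = vol, pressure = pressure)
}

# fabricate an accepted-windows data frame for curve-building tests
fake_windows <- function(cpp, z, cbf = NULL, accepted = TRUE) {
  n <- length(cpp)
  data.frame(start = seq_len(n) * 15, accepted = rep_len(accepted, n),
             f0 = 2.4, snr_q = 10, snr_p = 10,
             z_cbv = z, z_cpp = z * 2,
             cpp = cpp, abp = cpp + 10, icp = 10,
             cbf = if (is.null(cbf)) rep(1, n) else cbf)
}

# curve object straight from bin centers and values (bypasses binning)
curve_from_values <- function(centers, values, bin_width = 3) {
  structure(data.frame(center = centers, value = values, se = 0,
                       n = rep(3L, length(centers))),
            class = c("cv_curve", "data.frame"),
            bin_width = bin_width, normalized = FALSE, statistic = "impedance")
}
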