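#' Ground truth for a synthetic recording
#'
#' Bundles the synthetic world's true autoregulation limits, impedance
#' transfer, and mean-flow model. The impedance transfer Z(CPP, harmonic) is a
#' piecewise-linear "tent": strictly increasing on [LLA, ULA] and strictly
#' decreasing outside, with an optional per-harmonic scale. The mean-flow
#' model F(CPP) is a Lassen plateau: constant on [LLA, ULA], decreasing below
#' and increasing above.
#'
#' @param lla,ula autoregulation limits (mmHg), lla < ula.
#' @param z_lla,z_ula impedance transfer value at the limits (z_lla < z_ula).
#' @param slope_out_low,slope_out_high (negative) slopes of Z per mmHg outside
#'   the limits.
#' @param harmonic_scale length-2 multiplier of Z at the fundamental and first
#'   harmonic.
#' @param flow_plateau mean flow on the plateau (flow units).
#' @param flow_slope_low,flow_slope_high positive slopes of mean flow per mmHg
#'   below / above the limits.
#' @param cpp_domain CPP domain (mmHg) on which the transfer is defined.
#' @param hr_hz cardiac fundamental frequency (default 2.4 Hz, an integer
#'   multiple of the 1/30 Hz window resolution).
#' @return object of class `cv_truth` with callable `z_fun(cpp, harmonic)` and
#'   `f_fun(cpp)`.
#' @export
ground_truth <- function(lla = 60, ula = 72, z_lla = 0.8, z_ula = 1.4,
                         slope_out_low = -0.03, slope_out_high = -0.04,
                         harmonic_scale = c(1, 1), flow_plateau = 1,
                         flow_slope_low = 0.02, flow_slope_high = 0.015,
                         cpp_domain = c(20, 120), hr_hz = 2.4) {
  stopifnot(lla < ula, z_lla < z_ula, slope_out_low < 0, slope_out_high < 0,
            flow_slope_low > 0, flow_slope_high > 0)
  slope_in <- (z_ula - z_lla) / (ula - lla)
  z_base <- function(cpp) {
    ifelse(cpp < lla, z_lla + slope_out_low * (cpp - lla),
    ifelse(cpp <= ula, z_lla + slope_in * (cpp - lla),
           z_ula + slope_out_high * (cpp - ula)))
  }
  z_fun <- function(cpp, harmonic = 1L) {
    if (any(cpp < cpp_domain[1L] | cpp > cpp_domain[2L]))
      stop("cv_truth_domain: CPP outside the impedance transfer domain")
    harmonic_scale[harmonic] * z_base(cpp)
  }
  f_fun <- function(cpp) {
    ifelse(cpp < lla, flow_plateau - flow_slope_low * (lla - cpp),
    ifelse(cpp <= ula, flow_plateau,
           flow_plateau + flow_slope_high * (cpp - ula)))
  }
  structure(list(lla = lla, ula = ula, z_fun = z_fun, f_fun = f_fun,
                 harmonic_scale = harmonic_scale, hr_hz = hr_hz,
                 cpp_domain = cpp_domain, flow_plateau = flow_plateau),
            class = "cv_truth")
}

#' Constant (flat) impedance transfer, for analytic identity checks
#'
#' @param z length-2 impedance magnitude at the fundamental and harmonic.
#' @param hr_hz cardiac fundamental (Hz).
#' @return `cv_truth` whose `z_fun(cpp, k)` returns `z[k]` for any CPP and
#'   whose mean flow is constant 1.
#' @export
ground_truth_constant <- function(z = c(1, 1), hr_hz = 2.4) {
  gt <- ground_truth(hr_hz = hr_hz)
  gt$z_fun <- function(cpp, harmonic = 1L) rep(z[harmonic], length(cpp))
  gt$f_fun <- function(cpp) rep(1, length(cpp))
  gt
}

#' Protocol specification for a synthetic experiment
#'
#' Desk-scale rendition of the in-vivo protocol shape: a baseline, a staircase
#' of vasopressor-driven MAP steps, a return to baseline, then a staircase of
#' 5 mmHg ICP steps up to a maximum. All durations are scalable so the same
#' shape runs in minutes on a desk instead of hours.
#'
#' @param baseline_s baseline duration (s).
#' @param abp0,icp0 baseline ABP and ICP (mmHg).
#' @param map_step_mmhg MAP step size (mmHg).
#' @param map_steps number of MAP steps.
#' @param map_step_s duration of each MAP step (s).
#' @param icp_step_mmhg ICP step size (default 5 mmHg).
#' @param icp_steps number of ICP steps.
#' @param icp_step_s duration of each ICP step (s).
#' @param icp_max_mmhg cap on ICP (mmHg).
#' @param rate_hz pressure sampling rate (default 100).
#' @param hr_hz cardiac fundamental (Hz).
#' @param abp_pulse length-2 cardiac pulse amplitudes of ABP at the
#'   fundamental and first harmonic (mmHg).
#' @param icp_pulse length-2 cardiac pulse amplitudes of ICP (mmHg, smaller).
#' @param slow_noise_sd sd of the slow (1/f-like) baseline wander (mmHg).
#' @param window_s analysis window length the durations must support (30).
#' @return list of class `cv_protocol`.
#' @export
protocol_spec <- function(baseline_s = 90, abp0 = 75, icp0 = 10,
                          map_step_mmhg = 3, map_steps = 12, map_step_s = 75,
                          icp_step_mmhg = 5, icp_steps = 3, icp_step_s = 90,
                          icp_max_mmhg = 40, rate_hz = 100, hr_hz = 2.4,
                          abp_pulse = c(4, 1.6), icp_pulse = c(1, 0.4),
                          slow_noise_sd = 2, window_s = 30) {
  stopifnot(map_step_mmhg >= 0, icp_step_mmhg >= 0)
  durs <- c(baseline_s, if (map_steps > 0) map_step_s,
            if (icp_steps > 0) icp_step_s)
  if (any(durs <= 2 * window_s))
    stop("cv_protocol_too_short: every stage must exceed 2 analysis windows")
  structure(as.list(environment()), class = "cv_protocol")
}

# deterministic RNG scope: run `expr` under `seed`, restoring global state
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# slow colored baseline wander: low-passed white noise rescaled to target sd
.slow_noise <- function(n, rate, sd_target, fc = 0.05) {
  if (sd_target <= 0 || n < 16L) return(numeric(n))
  x <- stats::rnorm(n)
  bf <- signal::butter(2, min(fc / (rate / 2), 0.99), type = "low")
  y <- signal::filtfilt(bf, x)
  s <- stats::sd(y)
  if (s == 0) return(numeric(n))
  y / s * sd_target
}

#' Generate the ABP/ICP pressure protocol at 100 Hz
#'
#' Mean ABP follows baseline, a MAP staircase, a return to baseline, then
#' stays constant while mean ICP climbs its own staircase (capped at
#' `icp_max_mmhg`). Both channels carry cardiac pulsatility at the fundamental
#' and first harmonic plus slow colored baseline noise. Deterministic given
#' the seed.
#'
#' @param spec a [protocol_spec].
#' @param seed integer RNG seed.
#' @return [cv_ts] with channels ABP and ICP at `spec$rate_hz`.
#' @export
generate_protocol <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cv_protocol"))
  r <- spec$rate_hz
  seg <- function(mean_abp, mean_icp, dur)
    list(abp = mean_abp, icp = mean_icp, n = round(dur * r))
  segs <- list(seg(spec$abp0, spec$icp0, spec$baseline_s))
  if (spec$map_steps > 0)
    for (k in seq_len(spec$map_steps))
      segs <- c(segs, list(seg(spec$abp0 + k * spec$map_step_mmhg, spec$icp0,
                               spec$map_step_s)))
  segs <- c(segs, list(seg(spec$abp0, spec$icp0, spec$baseline_s)))
  if (spec$icp_steps > 0)
    for (k in seq_len(spec$icp_steps)) {
      icp_k <- min(spec$icp0 + k * spec$icp_step_mmhg, spec$icp_max_mmhg)
      segs <- c(segs, list(seg(spec$abp0, icp_k, spec$icp_step_s)))
    }
  abp_mean <- unlist(lapply(segs, function(s) rep(s$abp, s$n)))
  icp_mean <- unlist(lapply(segs, function(s) rep(s$icp, s$n)))
  n <- length(abp_mean)
  t <- (seq_len(n) - 1L) / r
  f0 <- spec$hr_hz
  pulse <- function(a) a[1L] * sin(2 * pi * f0 * t) +
    a[2L] * sin(4 * pi * f0 * t + pi / 4)
  .with_seed(seed, {
    abp <- abp_mean + pulse(spec$abp_pulse) + .slow_noise(n, r, spec$slow_noise_sd)
    icp <- icp_mean + pulse(spec$icp_pulse) + .slow_noise(n, r, spec$slow_noise_sd / 4)
    cv_ts(cbind(ABP = abp, ICP = icp), rate = r, start = 0)
  })
}

#' Generate pulsatile CBF and hemoglobin traces from a pressure recording
#'
#' Realizes the forward model the pipeline assumes. The slow CPP trend is
#' extracted by low-pass filtering ABP - ICP; then
#' CBF(t) = F(CPP) + A1 sin(2 pi f0 t + phi1) + A2 sin(4 pi f0 t + phi2) +
#' noise, and the cardiac components of dHbT have amplitudes Z(CPP, k) * A_k
#' per harmonic, with parameterized phase offsets, independent white noise and
#' slow drift. dHbT is split into dHbO/dHb by a fixed fraction so that
#' dHbT = dHbO + dHb holds identically. Deterministic given the seed.
#'
#' @param pressures [cv_ts] with ABP and ICP channels (gap-free).
#' @param truth a [ground_truth] (or [ground_truth_constant]).
#' @param seed integer RNG seed.
#' @param rate_hz optical output rate (default 500).
#' @param pulse_amp length-2 cardiac flow amplitudes A1, A2 (flow units).
#' @param phase_flow,phase_vol length-2 phases of the flow and volume cardiac
#'   components (rad).
#' @param cbf_noise_sd,hbt_noise_sd white-noise sd on CBF (flow units) and
#'   dHbT (uM).
#' @param hbt_drift_sd sd of the slow dHbT drift (uM).
#' @param hbo_fraction fraction of dHbT assigned to dHbO (default 0.75).
#' @return list with `optical` (a [cv_ts]: CBF, HbO, Hb, HbT at `rate_hz`) and
#'   `truth` (completed with the true traces).
#' @export
generate_hemodynamics <- function(pressures, truth, seed = 1L, rate_hz = 500,
                                  pulse_amp = c(0.25, 0.10),
                                  phase_flow = c(0, 0),
                                  phase_vol = c(0.6, 0.9),
                                  cbf_noise_sd = 0.10, hbt_noise_sd = 0.05,
                                  hbt_drift_sd = 0.02, hbo_fraction = 0.75) {
  stopifnot(inherits(pressures, "cv_ts"), inherits(truth, "cv_truth"))
  abp <- ts_channel(pressures, "ABP"); icp <- ts_channel(pressures, "ICP")
  cpp_raw <- abp - icp
  bf <- signal::butter(2, 0.5 / (pressures$rate / 2), type = "low")
  cpp_slow_src <- signal::filtfilt(bf, cpp_raw - mean(cpp_raw)) + mean(cpp_raw)
  tsrc <- ts_times(pressures)
  n <- floor(ts_duration(pressures) * rate_hz)
  t <- pressures$start + (seq_len(n) - 1L) / rate_hz
  cpp_slow <- stats::approx(tsrc, cpp_slow_src, xout = t, rule = 2)$y
  f0 <- truth$hr_hz
  z1 <- truth$z_fun(cpp_slow, 1L); z2 <- truth$z_fun(cpp_slow, 2L)
  car1 <- sin(2 * pi * f0 * t + phase_flow[1L])
  car2 <- sin(4 * pi * f0 * t + phase_flow[2L])
  vol1 <- sin(2 * pi * f0 * t + phase_vol[1L])
  vol2 <- sin(4 * pi * f0 * t + phase_vol[2L])
  .with_seed(seed, {
    cbf <- truth$f_fun(cpp_slow) + pulse_amp[1L] * car1 + pulse_amp[2L] * car2 +
      stats::rnorm(n, sd = cbf_noise_sd)
    hbt <- z1 * pulse_amp[1L] * vol1 + z2 * pulse_amp[2L] * vol2 +
      stats::rnorm(n, sd = hbt_noise_sd) + .slow_noise(n, rate_hz, hbt_drift_sd)
    hbo <- hbo_fraction * hbt
    hb <- hbt - hbo
    optical <- cv_ts(cbind(CBF = cbf, HbO = hbo, Hb = hb, HbT = hbo + hb),
                     rate = rate_hz, start = pressures$start)
    truth$true_cbf <- truth$f_fun(cpp_slow)
    truth$true_hbt_amp <- cbind(z1 * pulse_amp[1L], z2 * pulse_amp[2L])
    truth$seed <- seed
    list(optical = optical, truth = truth)
  })
}

#' Forward-model DCS autocorrelation curves from a flow-index trace
#'
#' For each sample of the flow-index trace, evaluates the semi-infinite
#' correlation-diffusion model ([model_g2]) on the lag grid and adds Gaussian
#' noise with per-lag standard deviation `noise_scale * (1 + (g2 - 1))`.
#' Deterministic given the seed.
#'
#' @param alpha_db [cv_ts] (one channel) or numeric vector of flow-index
#'   values (cm^2/s), all > 0.
#' @param props optical properties as in [model_g2].
#' @param beta speckle contrast parameter in (0, 1].
#' @param noise_scale noise amplitude (0 = noiseless).
#' @param seed integer RNG seed.
#' @param tau lag grid (s); defaults to 64 log-spaced lags over 500 ns--20 ms.
#' @return list of [g2_curve] objects.
#' @export
forward_dcs <- function(alpha_db, props, beta = 0.5, noise_scale = 0,
                        seed = 1L, tau = NULL) {
  vals <- if (inherits(alpha_db, "cv_ts")) ts_channel(alpha_db, ts_channels(alpha_db)[1L]) else alpha_db
  tstamps <- if (inherits(alpha_db, "cv_ts")) ts_times(alpha_db) else
    (seq_along(vals) - 1L) * 0.002
  if (any(vals <= 0)) stop("cv_dcs_nonpositive_flow: alpha_db must be positive")
  stopifnot(beta > 0, beta <= 1)
  if (is.null(tau)) tau <- 10^seq(log10(5e-7), log10(0.02), length.out = 64)
  .with_seed(seed, {
    lapply(seq_along(vals), function(i) {
      g2 <- model_g2(tau, vals[i], beta, props)
      if (noise_scale > 0)
        g2 <- g2 + stats::rnorm(length(tau), sd = noise_scale * (1 + (g2 - 1)))
      g2_curve(tau, g2, t = tstamps[i])
    })
  })
}

#' Forward-model two-wavelength NIRS intensities from chromophore traces
#'
#' I_lambda(t) = I0_lambda * exp(-(eps_HbO dHbO + eps_Hb dHb) * rho *
#' DPF(lambda)) * (1 + noise). Deterministic given the seed.
#'
#' @param hbo,hb [cv_ts] (one channel each) of dHbO and dHb (uM), same grid.
#' @param calib a [nirs_calibration] with baseline intensities `i0`.
#' @param noise_scale multiplicative noise sd (0 = noiseless).
#' @param seed integer RNG seed.
#' @return [cv_ts] with one intensity channel per wavelength.
#' @export
forward_nirs <- function(hbo, hb, calib, noise_scale = 0, seed = 1L) {
  stopifnot(inherits(hbo, "cv_ts"), inherits(hb, "cv_ts"),
            inherits(calib, "cv_nirs_calib"))
  if (is.null(calib$i0)) stop("cv_nirs_no_i0: forward model needs baseline intensities")
  co <- hbo$values[, 1L]; cd <- hb$values[, 1L]
  n <- length(co)
  .with_seed(seed, {
    I <- sapply(1:2, function(j) {
      od <- (calib$eps[j, "HbO"] * co + calib$eps[j, "Hb"] * cd) *
        calib$rho_cm * calib$dpf[j]
      calib$i0[j] * exp(-od) *
        (1 + if (noise_scale > 0) stats::rnorm(n, sd = noise_scale) else 0)
    })
    cv_ts(I, rate = hbo$rate, start = hbo$start,
          channels = paste0("wl", calib$wavelengths_nm))
  })
}

#' Simulate one complete synthetic subject
#'
#' Generates the pressure protocol and the matching optical streams, plus the
#' shared sync pulses used by [align_streams()] (placed 1 s after the start
#' and 1 s before the end, identical on both clocks).
#'
#' @param spec a [protocol_spec].
#' @param truth a [ground_truth].
#' @param seed integer RNG seed (protocol and hemodynamics use derived seeds).
#' @param ... forwarded to [generate_hemodynamics()].
#' @return list with `pressure`, `optical`, `sync`, `truth`.
#' @export
simulate_subject <- function(spec, truth, seed = 1L, ...) {
  pressure <- generate_protocol(spec, seed = seed)
  hemo <- generate_hemodynamics(pressure, truth, seed = seed + 10000L, ...)
  dur <- ts_duration(pressure)
  sync <- sync_events(c(1, dur - 1), c(1, dur - 1))
  list(pressure = pressure, optical = hemo$optical, sync = sync,
       truth = hemo$truth)
}

#' Run a full synthetic cohort study end to end
#'
#' Simulates `n_subjects` subjects, aligns each pressure stream onto the
#' optical grid via the sync pulses, runs the windowed impedance analysis,
#' bins and normalizes the per-subject impedance and Lassen curves, cohort
#' averages them, and estimates the autoregulation limits from both.
#'
#' @param n_subjects number of subjects (default 3).
#' @param seed integer base seed; subject s uses `seed + s`.
#' @param truth a [ground_truth].
#' @param spec a [protocol_spec].
#' @param config processing configuration.
#' @param ... forwarded to [generate_hemodynamics()] via [simulate_subject()].
#' @return list: `windows` (per subject), `impedance` and `lassen` cohort
#'   curves, `limits_impedance`, `limits_lassen`, `truth`.
#' @export
run_synthetic_study <- function(n_subjects = 3, seed = 1L,
                                truth = ground_truth(),
                                spec = protocol_spec(),
                                config = default_config(), ...) {
  subjects <- lapply(seq_len(n_subjects), function(s)
    simulate_subject(spec, truth, seed = seed + s * 1000L, ...))
  windows <- lapply(subjects, function(sub) {
    pal <- align_streams(sub$pressure, sub$optical, sub$sync)
    flow <- cv_ts(ts_channel(sub$optical, "CBF"), rate = sub$optical$rate,
                  start = sub$optical$start, channels = "CBF")
    vol <- cv_ts(ts_channel(sub$optical, "HbT"), rate = sub$optical$rate,
                 start = sub$optical$start, channels = "HbT")
    analyze_recording(flow, vol, pal, config)
  })
  cur <- config$curves
  imp <- lapply(windows, function(w)
    normalize_curve(bin_curve(w, "impedance", cur$bin_width_mmhg,
                              cur$cpp_min, cur$cpp_max), cur$ref_cpp_mmhg))
  las <- lapply(windows, function(w)
    normalize_curve(bin_curve(w, "cbf", cur$bin_width_mmhg,
                              cur$cpp_min, cur$cpp_max), cur$ref_cpp_mmhg))
  imp_cohort <- cohort_average(imp)
  las_cohort <- cohort_average(las)
  list(windows = windows,
       impedance = imp_cohort, lassen = las_cohort,
       limits_impedance = estimate_limits(imp_cohort, "tent",
                                          cur$limit_grid_mmhg),
       limits_lassen = estimate_limits(las_cohort, "plateau",
                                       cur$limit_grid_mmhg),
       truth = truth)
}
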