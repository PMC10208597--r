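#' Isolate cardiac pulsatility: mean-subtract and high-pass
#'
#' Each channel is mean-subtracted, then high-pass filtered with a 4th-order
#' Butterworth applied forward-backward (zero phase), cutoff `fc`. Output
#' length equals input length.
#'
#' @param series a [cv_ts] with rate > 2 * fc.
#' @param fc high-pass cutoff in Hz (default 1.2).
#' @return filtered [cv_ts].
#' @export
preprocess_pulsatile <- function(series, fc = 1.2) {
  stopifnot(inherits(series, "cv_ts"))
  if (series$rate <= 2 * fc)
    stop("cv_imp_rate_too_low: sampling rate must exceed 2 * cutoff")
  settle <- ceiling(series$rate / fc)
  if (nrow(series$values) < 3L * settle)
    stop("cv_imp_too_short: series shorter than 3x the filter settling length")
  bf <- signal::butter(4, fc / (series$rate / 2), type = "high")
  out <- apply(series$values, 2L, function(x)
    signal::filtfilt(bf, x - mean(x)))
  cv_ts(out, rate = series$rate, start = series$start,
        channels = ts_channels(series))
}

#' Segment a series into overlapping analysis windows
#'
#' Windows of `len_s` seconds starting every `len_s - overlap_s` seconds from
#' the start of the series; a window is kept only if it fits entirely, giving
#' floor((T - len) / hop) + 1 windows for duration T.
#'
#' @param series a [cv_ts].
#' @param len_s window length in seconds (default 30).
#' @param overlap_s overlap in seconds (default 15).
#' @return data frame with `start` (s, relative to series start), `i0`, `i1`
#'   (sample indices).
#' @export
segment_windows <- function(series, len_s = 30, overlap_s = 15) {
  stopifnot(inherits(series, "cv_ts"))
  hop <- len_s - overlap_s
  stopifnot(hop > 0)
  nwin <- round(len_s * series$rate)
  n <- nrow(series$values)
  if (n < nwin) stop("cv_imp_too_short: series shorter than one analysis window")
  nhop <- round(hop * series$rate)
  starts_i <- seq.int(1L, n - nwin + 1L, by = nhop)
  data.frame(start = (starts_i - 1L) / series$rate,
             i0 = starts_i, i1 = starts_i + nwin - 1L)
}

#' One-sided amplitude spectrum of a window segment
#'
#' Rectangular-windowed FFT scaled so a unit-amplitude sinusoid at an exact bin
#' frequency reads 1.0 at its bin. Bin k (0-based) corresponds to frequency
#' k / T where T is the segment duration; with T = 30 s the resolution is
#' 1/30 Hz.
#'
#' @param x numeric segment.
#' @param rate sampling rate (Hz).
#' @return list with `freq` (Hz) and `amp` (one-sided amplitudes), both of
#'   length floor(n/2) + 1.
#' @export
compute_spectrum <- function(x, rate) {
  n <- length(x)
  a <- Mod(stats::fft(x)) / n
  m <- n %/% 2L + 1L
  amp <- a[seq_len(m)]
  dbl <- 2:(if (n %% 2L == 0L) m - 1L else m)
  amp[dbl] <- 2 * amp[dbl]
  list(freq = (seq_len(m) - 1L) * rate / n, amp = amp)
}

.local_maxima <- function(amp) {
  n <- length(amp)
  if (n < 3L) return(integer(0))
  which(amp[2:(n - 1L)] > amp[1:(n - 2L)] & amp[2:(n - 1L)] >= amp[3:n]) + 1L
}

#' Locate the cardiac fundamental and first harmonic in a spectrum
#'
#' The fundamental is the largest local maximum inside the search band
#' (default 1.2--4.0 Hz); the harmonic is the largest local maximum within
#' `harm_tol_bins` bins of twice the fundamental frequency (the band limit
#' applies to the fundamental only). Failure to find either marks the window
#' rejected rather than raising an error.
#'
#' @param spec list(freq, amp) from [compute_spectrum()].
#' @param band fundamental search band in Hz.
#' @param harm_tol_bins harmonic search half-width in bins (default 3).
#' @return list with `fund`, `harm` (1-based indices into `spec$amp`), `f0`
#'   (Hz) and `ok` (FALSE when no usable peak pair exists).
#' @export
find_cardiac_peaks <- function(spec, band = c(1.2, 4.0), harm_tol_bins = 3L) {
  rejected <- list(fund = NA_integer_, harm = NA_integer_, f0 = NA_real_, ok = FALSE)
  cand <- .local_maxima(spec$amp)
  cand <- cand[spec$freq[cand] >= band[1L] & spec$freq[cand] <= band[2L]]
  if (length(cand) == 0L) return(rejected)
  fund <- cand[which.max(spec$amp[cand])]
  target <- fund + (fund - 1L)          # bin index of 2 * f0
  lo <- max(2L, target - harm_tol_bins)
  hi <- min(length(spec$amp) - 1L, target + harm_tol_bins)
  if (hi < lo) return(rejected)
  hcand <- .local_maxima(spec$amp)
  hcand <- hcand[hcand >= lo & hcand <= hi]
  if (length(hcand) == 0L) return(rejected)
  harm <- hcand[which.max(spec$amp[hcand])]
  list(fund = fund, harm = harm, f0 = spec$freq[fund], ok = TRUE)
}

#' Window SNR: cardiac peak power over the in-between noise power
#'
#' Power at the fundamental (sum of squared amplitudes over the fundamental
#' +/- `peak_halfwidth` bins) divided by the total power over the bins
#' strictly between (fundamental + guard) and (harmonic - guard). Using the
#' band's total power (rather than its per-bin mean) makes the statistic
#' reject noise-only windows: the largest noise peak in the search band is
#' biased high by selection, but never carries a multiple of the whole
#' in-between band's power.
#'
#' @param spec list(freq, amp).
#' @param fund,harm peak indices from [find_cardiac_peaks()].
#' @param peak_halfwidth half-width of the peak neighborhood in bins (default 1).
#' @param guard guard bins excluded next to each peak (default 2).
#' @return unitless SNR.
#' @export
window_snr <- function(spec, fund, harm, peak_halfwidth = 1L, guard = 2L) {
  if (harm <= fund + 4L)
    stop("cv_imp_peaks_too_close: harmonic must exceed fundamental by > 4 bins")
  pk <- max(1L, fund - peak_halfwidth):min(length(spec$amp), fund + peak_halfwidth)
  between <- seq.int(fund + guard + 1L, harm - guard - 1L)
  between <- between[between > fund + guard & between < harm - guard]
  if (length(between) == 0L)
    stop("cv_imp_empty_noise_band: no bins between the guarded peaks")
  sum(spec$amp[pk]^2) / sum(spec$amp[between]^2)
}

#' Window acceptance rule
#'
#' A window is accepted iff both the flow (Q) and the pressure-surrogate (P)
#' window SNRs are at least the threshold; SNR exactly at the threshold is
#' accepted (the rule rejects strictly-less-than).
#'
#' @param snr_q,snr_p window SNRs (finite, >= 0).
#' @param threshold rejection threshold (default 3).
#' @return logical.
#' @export
reject_window <- function(snr_q, snr_p, threshold = 3) {
  stopifnot(is.finite(snr_q), is.finite(snr_p), snr_q >= 0, snr_p >= 0)
  snr_q >= threshold && snr_p >= threshold
}

#' Impedance index of one window
#'
#' Z(jw) = P(jw) / Q(jw); the index sums the impedance magnitude at the
#' cardiac fundamental and first harmonic:
#' |P(f0)|/|Q(f0)| + |P(f1)|/|Q(f1)|.
#'
#' @param spec_p,spec_q one-sided amplitude spectra of the pressure surrogate
#'   and the flow channel.
#' @param fund,harm peak indices.
#' @param q_floor relative floor on |Q| at a peak (fraction of max |Q|); below
#'   it the window is unusable and `NA` is returned.
#' @return the unitless index, or `NA_real_` when |Q| is numerically zero at a
#'   peak.
#' @export
impedance_index <- function(spec_p, spec_q, fund, harm, q_floor = 1e-12) {
  qf <- spec_q$amp[fund]; qh <- spec_q$amp[harm]
  if (min(qf, qh) <= q_floor * max(spec_q$amp)) return(NA_real_)
  spec_p$amp[fund] / qf + spec_p$amp[harm] / qh
}

#' Mean CPP, ABP, ICP and CBF over a window
#'
#' Arithmetic means of the unfiltered (pre-high-pass) channels; CPP is the
#' samplewise ABP - ICP.
#'
#' @param pressure [cv_ts] with channels ABP and ICP, aligned to the flow grid.
#' @param flow [cv_ts] with the flow channel.
#' @param i0,i1 sample indices delimiting the window (inclusive).
#' @return named numeric: cpp, abp, icp, cbf.
#' @export
summarize_window <- function(pressure, flow, i0, i1) {
  if (i1 > nrow(pressure$values) || i1 > nrow(flow$values) || i0 < 1L)
    stop("cv_imp_window_gap: streams do not cover the analysis window")
  abp <- mean(pressure$values[i0:i1, "ABP"])
  icp <- mean(pressure$values[i0:i1, "ICP"])
  cbf <- mean(flow$values[i0:i1, 1L])
  c(cpp = abp - icp, abp = abp, icp = icp, cbf = cbf)
}

#' Run the windowed impedance analysis over a full recording
#'
#' The complete per-window chain: mean-subtract + high-pass the flow, volume
#' and CPP channels; segment into overlapping windows; FFT each segment;
#' locate the cardiac fundamental and first harmonic on the flow (Q) spectrum
#' and verify the volume (P) spectrum peaks within `pq_check_bins` bins;
#' compute window SNRs; apply the rejection rule; and for accepted windows
#' compute both impedance-index variants -- CBV-based (P = dHbT) and CPP-based
#' (P = dCPP) -- together with window means of the unfiltered channels.
#'
#' @param flow [cv_ts], one channel, the CBF flow index at the optical rate.
#' @param volume [cv_ts], one channel, the pressure surrogate (dHbT, uM),
#'   same grid as `flow`.
#' @param pressure [cv_ts] with channels ABP and ICP aligned to the same grid.
#' @param config list from [default_config()] / [load_config()].
#' @return data frame, one row per window: start, accepted, f0, snr_q, snr_p,
#'   z_cbv, z_cpp, cpp, abp, icp, cbf. Rejected windows carry NA impedance.
#' @export
analyze_recording <- function(flow, volume, pressure, config = default_config()) {
  pr <- config$processing
  stopifnot(inherits(flow, "cv_ts"), inherits(volume, "cv_ts"),
            inherits(pressure, "cv_ts"))
  rates <- c(flow$rate, volume$rate, pressure$rate)
  if (max(abs(rates - rates[1L])) > 1e-9 * rates[1L])
    stop("cv_imp_rate_mismatch: all streams must share one sampling rate")
  # restrict every stream to the common time overlap
  t0 <- max(flow$start, volume$start, pressure$start)
  t1 <- min(flow$start + (nrow(flow$values) - 1L) / flow$rate,
            volume$start + (nrow(volume$values) - 1L) / volume$rate,
            pressure$start + (nrow(pressure$values) - 1L) / pressure$rate)
  if (t1 <= t0) stop("cv_imp_no_overlap: streams do not overlap in time")
  clip <- function(ts) {
    a <- round((t0 - ts$start) * ts$rate) + 1L
    b <- round((t1 - ts$start) * ts$rate) + 1L
    ts_slice(ts, a:b)
  }
  flow <- clip(flow); volume <- clip(volume); pressure <- clip(pressure)
  cpp <- cv_ts(ts_channel(pressure, "ABP") - ts_channel(pressure, "ICP"),
               rate = pressure$rate, start = pressure$start, channels = "CPP")

  q_hp <- preprocess_pulsatile(flow, pr$hp_cutoff_hz)
  p_hp <- preprocess_pulsatile(volume, pr$hp_cutoff_hz)
  c_hp <- preprocess_pulsatile(cpp, pr$hp_cutoff_hz)

  wins <- segment_windows(flow, pr$win_len_s, pr$win_overlap_s)
  rows <- lapply(seq_len(nrow(wins)), function(k) {
    i0 <- wins$i0[k]; i1 <- wins$i1[k]
    sq <- compute_spectrum(q_hp$values[i0:i1, 1L], flow$rate)
    sp <- compute_spectrum(p_hp$values[i0:i1, 1L], flow$rate)
    sc <- compute_spectrum(c_hp$values[i0:i1, 1L], flow$rate)
    means <- summarize_window(pressure, flow, i0, i1)
    out <- data.frame(start = wins$start[k], accepted = FALSE,
                      f0 = NA_real_, snr_q = NA_real_, snr_p = NA_real_,
                      z_cbv = NA_real_, z_cpp = NA_real_,
                      cpp = means[["cpp"]], abp = means[["abp"]],
                      icp = means[["icp"]], cbf = means[["cbf"]])
    pk <- find_cardiac_peaks(sq, pr$band_hz, pr$harm_tol_bins)
    if (!pk$ok) return(out)
    # P must show a local maximum near the Q fundamental
    pmax_idx <- .local_maxima(sp$amp)
    if (!any(abs(pmax_idx - pk$fund) <= pr$pq_check_bins)) return(out)
    snr_q <- window_snr(sq, pk$fund, pk$harm, pr$peak_halfwidth_bins, pr$guard_bins)
    snr_p <- window_snr(sp, pk$fund, pk$harm, pr$peak_halfwidth_bins, pr$guard_bins)
    out$f0 <- pk$f0; out$snr_q <- snr_q; out$snr_p <- snr_p
    if (!reject_window(snr_q, snr_p, pr$snr_threshold)) return(out)
    z_cbv <- impedance_index(sp, sq, pk$fund, pk$harm)
    z_cpp <- impedance_index(sc, sq, pk$fund, pk$harm)
    if (is.na(z_cbv)) return(out)
    out$accepted <- TRUE; out$z_cbv <- z_cbv; out$z_cpp <- z_cpp
    out
  })
  do.call(rbind, rows)
}
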