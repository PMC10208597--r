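#' Intensity autocorrelation curve
#'
#' Normalized intensity autocorrelation g2 over a lag grid, optionally carrying
#' per-lag SNR weights for the flow fit.
#'
#' @param tau lag grid in seconds, strictly increasing, non-negative.
#' @param g2 autocorrelation values, finite, same length as `tau`.
#' @param snr optional per-lag SNR weights, >= 0.
#' @param t timestamp of the curve in seconds.
#' @return object of class `cv_g2`.
#' @export
g2_curve <- function(tau, g2, snr = NULL, t = 0) {
  if (length(tau) != length(g2))
    stop("cv_g2_length_mismatch: tau and g2 differ in length")
  if (any(diff(tau) <= 0)) stop("cv_g2_tau_order: tau must be strictly increasing")
  if (any(!is.finite(g2))) stop("cv_g2_nonfinite: g2 values must be finite")
  if (!is.null(snr)) {
    if (length(snr) != length(tau)) stop("cv_g2_length_mismatch: snr length differs")
    if (any(snr < 0)) stop("cv_g2_negative_snr: SNR weights must be >= 0")
  }
  structure(list(tau = as.numeric(tau), g2 = as.numeric(g2),
                 snr = snr, t = as.numeric(t)), class = "cv_g2")
}

#' @export
print.cv_g2 <- function(x, ...) {
  cat(sprintf("<cv_g2> %d lags, tau [%.3g, %.3g] s, intercept %.4f%s\n",
              length(x$tau), x$tau[1L], x$tau[length(x$tau)], x$g2[1L],
              if (is.null(x$snr)) "" else ", with SNR weights"))
  invisible(x)
}

#' Compute g2 curves from binned photon counts
#'
#' Estimates g2(tau) = <I(t) I(t+tau)> / <I>^2 over a sliding window, per
#' detector, then averages the detectors' curves. With the device geometry
#' (500 ns count bins, 20 ms windows slid every 2 ms) this yields curves at a
#' 500 Hz cadence; all of window, step and lag range are expressed in count
#' bins so the estimator can be exercised at any scale.
#'
#' @param counts non-negative integer matrix (bins x detectors) or vector.
#' @param bin_s width of one count bin in seconds (default 500 ns).
#' @param window_bins window length in bins (default 40000 = 20 ms).
#' @param step_bins slide step in bins (default 4000 = 2 ms).
#' @param max_lag_bins largest lag in bins (default `window_bins / 2`).
#' @return list of [g2_curve] objects, one per window position, with lags
#'   0, 1, ..., max_lag_bins (in seconds).
#' @export
compute_g2 <- function(counts, bin_s = 5e-7, window_bins = 40000L,
                       step_bins = 4000L, max_lag_bins = NULL) {
  if (is.vector(counts)) counts <- matrix(counts, ncol = 1)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("cv_g2_bad_counts: photon counts must be non-negative integers")
  n <- nrow(counts)
  if (is.null(max_lag_bins)) max_lag_bins <- window_bins %/% 2L
  if (window_bins < max_lag_bins + 2L)
    stop("cv_g2_window_too_short: window must hold >= 2 samples per lag")
  if (n < window_bins) stop("cv_g2_too_short: fewer count bins than one window")
  starts <- seq.int(1L, n - window_bins + 1L, by = step_bins)
  lags <- 0:max_lag_bins
  lapply(starts, function(s) {
    seg <- counts[s:(s + window_bins - 1L), , drop = FALSE]
    if (all(seg == 0))
      stop("cv_g2_no_light: all-zero counts in window")
    per_det <- apply(seg, 2L, function(I) {
      m <- mean(I)
      vapply(lags, function(l) {
        k <- window_bins - l
        mean(I[1:k] * I[(1L + l):(l + k)]) / m^2
      }, numeric(1))
    })
    g2_curve(tau = lags * bin_s, g2 = rowMeans(as.matrix(per_det)),
             t = (s - 1L) * bin_s)
  })
}

#' Per-lag SNR curve from a history of g2 curves
#'
#' SNR(tau) = (mean over history of g2(tau) - 1) / (sample sd over history at
#' tau), computed per lag over (by default) the previous 10 s of curves.
#'
#' @param history list of [g2_curve] on a common lag grid, or a numeric matrix
#'   (curves x lags).
#' @return numeric vector, one SNR per lag.
#' @export
compute_snr_curve <- function(history) {
  if (is.list(history) && !is.matrix(history)) {
    if (length(history) == 0L) stop("cv_snr_empty_history: no curves")
    history <- do.call(rbind, lapply(history, function(c) c$g2))
  }
  if (nrow(history) < 2L)
    stop("cv_snr_degenerate_history: need >= 2 curves for a standard deviation")
  m <- colMeans(history)
  s <- apply(history, 2L, stats::sd)
  if (any(s == 0))
    stop("cv_snr_degenerate_history: zero standard deviation at some lag")
  (m - 1) / s
}

#' Semi-infinite correlation-diffusion model for g2
#'
#' Siegert relation g2 = 1 + beta |g1|^2 with g1 from the semi-infinite
#' extrapolated-boundary Green's-function solution with Brownian dynamics:
#' decay argument K(tau) = sqrt(3 mua musp + 6 musp^2 k0^2 alpha_db tau) with
#' k0 = 2 pi n / lambda, image-source radii from z0 = 1/musp and
#' zb = 2 (1 + Reff) / (3 musp (1 - Reff)), normalized so g1(0) = 1.
#'
#' @param tau lag grid (s).
#' @param alpha_db flow index (cm^2/s), > 0.
#' @param beta speckle contrast parameter in (0, 1].
#' @param props list with `mua`, `musp` (1/cm), `wavelength_nm`, `rho_cm`,
#'   `n_tissue`, `reff` (see `default_config()$dcs`).
#' @return g2 values on `tau`.
#' @export
model_g2 <- function(tau, alpha_db, beta, props) {
  stopifnot(alpha_db > 0, beta > 0, beta <= 1)
  mua <- props$mua; musp <- props$musp
  lambda_cm <- props$wavelength_nm * 1e-7
  k0 <- 2 * pi * props$n_tissue / lambda_cm
  z0 <- 1 / musp
  zb <- 2 * (1 + props$reff) / (3 * musp * (1 - props$reff))
  r1 <- sqrt(props$rho_cm^2 + z0^2)
  r2 <- sqrt(props$rho_cm^2 + (z0 + 2 * zb)^2)
  G1 <- function(K) exp(-K * r1) / r1 - exp(-K * r2) / r2
  K <- sqrt(3 * mua * musp + 6 * musp^2 * k0^2 * alpha_db * tau)
  g1 <- G1(K) / G1(sqrt(3 * mua * musp))
  1 + beta * g1^2
}

#' Fit the flow index to a measured g2 curve
#'
#' Bounded nonlinear least squares on residuals weighted per lag:
#' minimize sum_tau [w(tau) (g2_meas - model_g2)]^2 over (alpha_db, beta).
#' Weights default to the curve's SNR(tau); pass `weights = "uniform"` for an
#' unweighted fit. alpha_db is fit on a log scale for conditioning. The
#' starting point is beta from the small-lag intercept and alpha_db from a
#' coarse log-spaced scan, unless `init` overrides it.
#'
#' @param curve a [g2_curve]; must carry SNR weights unless `weights` given.
#' @param props optical properties as in [model_g2].
#' @param init optional list(alpha_db, beta) starting point.
#' @param weights `NULL` (use curve$snr), `"uniform"`, or a numeric vector.
#' @param bounds list(alpha_db = c(lo, hi), beta = c(lo, hi)).
#' @return list with `alpha_db`, `beta`, `resid_norm`, `converged`.
#' @export
fit_flow_index <- function(curve, props, init = NULL, weights = NULL,
                           bounds = list(alpha_db = c(1e-12, 1e-4),
                                         beta = c(1e-6, 1))) {
  stopifnot(inherits(curve, "cv_g2"))
  w <- if (is.null(weights)) {
    if (is.null(curve$snr))
      stop("cv_fit_no_weights: curve has no SNR weights; pass weights explicitly")
    curve$snr
  } else if (identical(weights, "uniform")) rep(1, length(curve$tau)) else weights
  tau <- curve$tau; y <- curve$g2
  if (any(!is.finite(w)) || any(!is.finite(y)))
    stop("cv_fit_nonfinite: non-finite residual inputs")

  if (is.null(init)) {
    nhead <- max(1L, min(3L, length(y)))
    beta0 <- min(max(mean(y[seq_len(nhead)]) - 1, 0.05), 1)
    scan <- 10^seq(log10(bounds$alpha_db[1]) + 1, log10(bounds$alpha_db[2]) - 1,
                   length.out = 25)
    sse <- vapply(scan, function(a)
      sum((w * (y - model_g2(tau, a, beta0, props)))^2), numeric(1))
    init <- list(alpha_db = scan[which.min(sse)], beta = beta0)
  }
  resid_fn <- function(p) {
    w * (y - model_g2(tau, exp(p[1L]), p[2L], props))
  }
  fit <- minpack.lm::nls.lm(
    par = c(log(init$alpha_db), init$beta), fn = resid_fn,
    lower = c(log(bounds$alpha_db[1]), bounds$beta[1]),
    upper = c(log(bounds$alpha_db[2]), bounds$beta[2]),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- fit$par
  lo <- c(log(bounds$alpha_db[1]), bounds$beta[1])
  hi <- c(log(bounds$alpha_db[2]), bounds$beta[2])
  at_bound <- any(p <= lo + 1e-10) || any(p >= hi - 1e-10)
  list(alpha_db = exp(p[1L]), beta = p[2L],
       resid_norm = sqrt(sum(resid_fn(p)^2)),
       converged = fit$info %in% 1:4 && !at_bound && fit$niter < 200)
}

#' Fit a sequence of g2 curves into a flow-index time series
#'
#' Attaches an SNR curve computed over the trailing history (default 10 s) to
#' each curve, fits each, and returns the flow index as a [cv_ts].
#'
#' @param curves list of [g2_curve] at a uniform cadence.
#' @param props optical properties as in [model_g2].
#' @param history_s trailing history used for the SNR curve (default 10).
#' @param rate output rate in Hz (default inferred from curve timestamps).
#' @return list with `flow` (a [cv_ts], channel "CBF") and `fits`.
#' @export
fit_flow_series <- function(curves, props, history_s = 10, rate = NULL) {
  stopifnot(length(curves) >= 2L)
  tstamps <- vapply(curves, function(c) c$t, numeric(1))
  if (is.null(rate)) rate <- 1 / stats::median(diff(tstamps))
  g2mat <- do.call(rbind, lapply(curves, function(c) c$g2))
  nhist <- max(2L, min(length(curves), round(history_s * rate)))
  fits <- vector("list", length(curves))
  for (i in seq_along(curves)) {
    lo <- max(1L, i - nhist + 1L)
    hist_rows <- if (i - lo + 1L >= 2L) g2mat[lo:i, , drop = FALSE] else g2mat[1:2, , drop = FALSE]
    # zero-sd lags (fully decorrelated or noiseless history) carry no noise
    # information; give them zero weight instead of failing the whole fit
    m <- colMeans(hist_rows)
    s <- apply(hist_rows, 2L, stats::sd)
    snr <- ifelse(s > 0, (m - 1) / s, 0)
    cur <- curves[[i]]; cur$snr <- pmax(snr, 0)
    if (all(cur$snr == 0)) cur$snr <- rep(1, length(cur$snr))
    fits[[i]] <- fit_flow_index(cur, props)
  }
  flow <- cv_ts(vapply(fits, function(f) f$alpha_db, numeric(1)),
                rate = rate, start = tstamps[1L], channels = "CBF")
  list(flow = flow, fits = fits)
}
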