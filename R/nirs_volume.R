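#' NIRS calibration for modified Beer-Lambert unmixing
#'
#' @param wavelengths_nm the two wavelengths (default 685, 852 nm).
#' @param rho_cm source-detector distance (default 1.5 cm).
#' @param dpf differential pathlength factor per wavelength.
#' @param eps_hbo,eps_hb extinction coefficients per wavelength, natural-log
#'   convention, 1/(cm*uM).
#' @param i0 baseline intensities per wavelength (arbitrary units, > 0), or
#'   `NULL` to estimate from a baseline interval at conversion time.
#' @return object of class `cv_nirs_calib`.
#' @export
nirs_calibration <- function(wavelengths_nm = c(685, 852), rho_cm = 1.5,
                             dpf = c(4, 4), eps_hbo = NULL, eps_hb = NULL,
                             i0 = NULL) {
  cfg <- default_config()$nirs
  if (is.null(eps_hbo)) eps_hbo <- cfg$eps_hbo
  if (is.null(eps_hb)) eps_hb <- cfg$eps_hb
  stopifnot(length(wavelengths_nm) == 2L, length(dpf) == 2L,
            length(eps_hbo) == 2L, length(eps_hb) == 2L)
  if (any(dpf <= 0)) stop("cv_nirs_bad_dpf: DPF must be positive")
  if (!is.null(i0) && any(i0 <= 0)) stop("cv_nirs_bad_i0: baseline intensities must be positive")
  E <- cbind(HbO = eps_hbo, Hb = eps_hb)
  rownames(E) <- paste0("wl", wavelengths_nm)
  if (kappa(E, exact = TRUE) >= 100)
    stop("cv_nirs_ill_conditioned: extinction matrix condition number >= 100")
  structure(list(wavelengths_nm = wavelengths_nm, rho_cm = rho_cm, dpf = dpf,
                 eps = E, i0 = i0), class = "cv_nirs_calib")
}

#' Intensity to absorption change via the modified Beer-Lambert law
#'
#' Delta mua(lambda, t) = ln(I0 / I(t)) / (rho * DPF(lambda)). If the
#' calibration carries no I0, the mean over the first `baseline_s` seconds of
#' each channel is used.
#'
#' @param intensity [cv_ts] with one channel per wavelength (positive values),
#'   in calibration wavelength order.
#' @param calib a [nirs_calibration].
#' @param baseline_s baseline interval for I0 estimation (default 5 s).
#' @return [cv_ts] of Delta mua per wavelength (1/cm).
#' @export
intensity_to_delta_mua <- function(intensity, calib, baseline_s = 5) {
  stopifnot(inherits(intensity, "cv_ts"), inherits(calib, "cv_nirs_calib"))
  V <- intensity$values
  if (ncol(V) != 2L) stop("cv_nirs_bad_channels: expected two wavelength channels")
  bad <- which(V <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("cv_nirs_nonpositive_intensity: non-positive sample(s) at row %s",
                 paste(utils::head(unique(bad[, 1L]), 10L), collapse = ", ")))
  i0 <- calib$i0
  if (is.null(i0)) {
    nb <- max(1L, min(nrow(V), round(baseline_s * intensity$rate)))
    i0 <- colMeans(V[seq_len(nb), , drop = FALSE])
  }
  dmua <- sapply(1:2, function(j)
    log(i0[j] / V[, j]) / (calib$rho_cm * calib$dpf[j]))
  cv_ts(dmua, rate = intensity$rate, start = intensity$start,
        channels = paste0("dmua_", calib$wavelengths_nm))
}

#' Unmix absorption changes into hemoglobin concentration changes
#'
#' Solves, per sample, the 2x2 system eps %*% c(dHbO, dHb) = dmua and appends
#' dHbT = dHbO + dHb.
#'
#' @param delta_mua [cv_ts] with one channel per wavelength (1/cm).
#' @param calib a [nirs_calibration].
#' @return [cv_ts] with channels HbO, Hb, HbT (uM).
#' @export
unmix_hemoglobin <- function(delta_mua, calib) {
  stopifnot(inherits(delta_mua, "cv_ts"), inherits(calib, "cv_nirs_calib"))
  if (ncol(delta_mua$values) != 2L)
    stop("cv_nirs_bad_channels: expected two wavelength channels")
  if (kappa(calib$eps, exact = TRUE) >= 100)
    stop("cv_nirs_ill_conditioned: extinction matrix condition number >= 100")
  conc <- t(solve(calib$eps, t(delta_mua$values)))
  out <- cbind(conc, conc[, 1L] + conc[, 2L])
  cv_ts(out, rate = delta_mua$rate, start = delta_mua$start,
        channels = c("HbO", "Hb", "HbT"))
}

#' Blood-volume to pulsatile-pressure surrogate
#'
#' Under a constant vascular elastic modulus, pulsatile pressure changes are
#' proportional to pulsatile blood volume changes, so the linear mode is the
#' identity (dP = dHbT). The exponential mode models a stiffening bed:
#' dP = (exp(kappa * dHbT) - 1) / kappa, which tends to dHbT as dHbT -> 0.
#'
#' @param hbt [cv_ts] of dHbT (uM); any channel count is mapped elementwise.
#' @param mode "linear" or "exponential".
#' @param kappa stiffness (1/uM), > 0; exponential mode only.
#' @return [cv_ts] of the pressure surrogate.
#' @export
volume_to_pressure_surrogate <- function(hbt, mode = c("linear", "exponential"),
                                         kappa = 0.1) {
  stopifnot(inherits(hbt, "cv_ts"))
  mode <- match.arg(mode)
  if (mode == "linear") return(hbt)
  if (!is.numeric(kappa) || kappa <= 0)
    stop("cv_nirs_bad_kappa: kappa must be > 0 in exponential mode")
  cv_ts((exp(kappa * hbt$values) - 1) / kappa, rate = hbt$rate,
        start = hbt$start, channels = ts_channels(hbt))
}
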