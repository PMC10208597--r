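#' Default processing configuration
#'
#' A flat-ish list of every numeric parameter used by the pipeline, suitable
#' for writing to / overriding from a YAML file. Units are given per key.
#'
#' Groups:
#' \describe{
#'   \item{dcs}{optical properties and fit constants for the
#'     correlation-diffusion model: `mua` (1/cm), `musp` (1/cm), `wavelength_nm`
#'     (852), `rho_cm` source-detector distance (1.5), `n_tissue`, `reff`
#'     effective reflection coefficient, fit bounds for `alpha_db` (cm^2/s) and
#'     `beta`.}
#'   \item{nirs}{wavelengths (nm), `rho_cm`, `dpf` per wavelength, extinction
#'     coefficients (natural-log convention, 1/(cm*uM)) for HbO and Hb at each
#'     wavelength, baseline intensities `i0`.}
#'   \item{processing}{high-pass cutoff `hp_cutoff_hz` (1.2), window length
#'     `win_len_s` (30) and overlap `win_overlap_s` (15), cardiac fundamental
#'     search band `band_hz` (1.2--4.0), harmonic search tolerance
#'     `harm_tol_bins` (3), peak neighborhood half-width `peak_halfwidth_bins`
#'     (1), guard bins `guard_bins` (2) around the in-between noise band, SNR
#'     rejection threshold `snr_threshold` (3), and `pq_check_bins` (2) for the
#'     P-spectrum peak consistency check.}
#'   \item{curves}{CPP bin width `bin_width_mmhg` (3), normalization reference
#'     `ref_cpp_mmhg` (65), optional analysis range `cpp_min`/`cpp_max` (NULL =
#'     no truncation), limit-search grid step `limit_grid_mmhg` (1.5).}
#' }
#'
#' @return nested list of defaults.
#' @export
default_config <- function() {
  ln10 <- log(10)
  list(
    dcs = list(
      mua = 0.1, musp = 10, wavelength_nm = 852, rho_cm = 1.5,
      n_tissue = 1.4, reff = 0.493, beta = 0.5,
      alpha_db_min = 1e-12, alpha_db_max = 1e-4,
      tau_max_s = 0.02, tau_bin_s = 5e-7
    ),
    nirs = list(
      wavelengths_nm = c(685, 852), rho_cm = 1.5, dpf = c(4.0, 4.0),
      # molar extinction (compiled tabulation), converted to ln-based 1/(cm*uM)
      eps_hbo = c(294, 1062) * ln10 * 1e-6,
      eps_hb  = c(2407, 690) * ln10 * 1e-6,
      i0 = c(1, 1),
      baseline_s = 5
    ),
    processing = list(
      hp_cutoff_hz = 1.2, win_len_s = 30, win_overlap_s = 15,
      band_hz = c(1.2, 4.0), harm_tol_bins = 3,
      peak_halfwidth_bins = 1, guard_bins = 2,
      snr_threshold = 3, pq_check_bins = 2
    ),
    curves = list(
      bin_width_mmhg = 3, ref_cpp_mmhg = 65,
      cpp_min = NULL, cpp_max = NULL,
      limit_grid_mmhg = 1.5
    )
  )
}

#' Load a configuration file, merging over the defaults
#'
#' @param path YAML file with any subset of the keys of [default_config()];
#'   `NULL` returns the defaults.
#' @return nested list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  for (grp in names(user)) {
    if (!grp %in% names(cfg))
      stop(sprintf("cv_config_unknown_group: '%s'", grp))
    for (key in names(user[[grp]])) {
      if (!key %in% names(cfg[[grp]]))
        stop(sprintf("cv_config_unknown_key: '%s.%s'", grp, key))
      cfg[[grp]][[key]] <- user[[grp]][[key]]
    }
  }
  cfg
}
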