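#' Read a time-series CSV
#'
#' Expects a header row with a `time` column (seconds, uniformly spaced) and
#' one column per channel. The sampling rate is inferred from the median time
#' step; spacing must be uniform within relative tolerance 1e-6.
#'
#' @param path CSV file path.
#' @param expected_channels optional character vector; all must be present.
#' @param time_col name of the time column (default "time").
#' @return a [cv_ts].
#' @export
read_timeseries <- function(path, expected_channels = NULL, time_col = "time") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!time_col %in% names(df))
    stop(sprintf("cv_io_missing_time: no '%s' column in %s", time_col, path))
  tt <- df[[time_col]]
  vals <- as.matrix(df[setdiff(names(df), time_col)])
  if (!is.null(expected_channels)) {
    missing <- setdiff(expected_channels, colnames(vals))
    if (length(missing))
      stop(sprintf("cv_io_missing_channel: channel(s) %s absent from %s",
                   paste(missing, collapse = ", "), path))
    vals <- vals[, expected_channels, drop = FALSE]
  }
  bad <- which(rowSums(is.na(vals)) > 0L | !is.finite(tt))
  if (length(bad))
    stop(sprintf("cv_io_nan_cells: NaN/NA cells at row(s) %s",
                 paste(utils::head(bad, 20L), collapse = ", ")))
  if (length(tt) < 2L)
    stop("cv_io_too_short: need at least 2 samples to infer a rate")
  dt <- diff(tt)
  dt0 <- stats::median(dt)
  if (dt0 <= 0 || max(abs(dt - dt0)) > 1e-6 * dt0)
    stop("cv_io_nonuniform_time: time column is not uniformly spaced within relative tolerance 1e-6")
  cv_ts(vals, rate = 1 / dt0, start = tt[1L])
}

#' Write a time series to CSV
#'
#' Numeric values are written with 17 significant digits so the paired reader
#' reproduces them bit-identically.
#'
#' @param ts a [cv_ts].
#' @param path output path.
#' @export
write_timeseries <- function(ts, path) {
  df <- data.frame(time = ts_times(ts), ts$values, check.names = FALSE)
  .write_csv17(df, path)
}

.fmt17 <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), "", tolower(as.character(x))))
  if (is.numeric(x)) return(ifelse(is.na(x), "", sprintf("%.17g", x)))
  as.character(x)
}

.write_csv17 <- function(df, path) {
  cols <- lapply(df, .fmt17)
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path, useBytes = TRUE)
}

#' Sync pulse event pairs shared by two streams
#'
#' Alignment voltage pulses recorded on both the pressure and the optical
#' acquisition clock. Counts must match and times be strictly increasing.
#'
#' @param pressure_times pulse times on the pressure clock (s).
#' @param optical_times pulse times on the optical clock (s).
#' @return an object of class `cv_sync`.
#' @export
sync_events <- function(pressure_times, optical_times) {
  if (length(pressure_times) != length(optical_times))
    stop("cv_sync_count_mismatch: pulse counts differ between streams")
  if (length(pressure_times) < 2L)
    stop("cv_sync_too_few: need at least 2 sync pulses per stream")
  if (any(diff(pressure_times) <= 0) || any(diff(optical_times) <= 0))
    stop("cv_sync_not_increasing: pulse times must be strictly increasing")
  structure(list(pressure = as.numeric(pressure_times),
                 optical = as.numeric(optical_times)),
            class = "cv_sync")
}

#' Map the pressure stream onto the optical clock and sample grid
#'
#' Fits a two-parameter clock model (offset + drift) to the sync pulse pairs by
#' least squares, maps the pressure sample times onto the optical clock, and
#' linearly interpolates every pressure channel onto the optical sample grid.
#' The result is restricted to the overlapping interval; no extrapolation.
#'
#' @param pressure a [cv_ts] (e.g. ABP/ICP at 100 Hz).
#' @param optical a [cv_ts] defining the target clock and rate (e.g. 500 Hz).
#' @param sync a [sync_events] object.
#' @param max_drift largest tolerated |drift - 1| (default 0.01); a larger
#'   fitted drift suggests mispaired pulses.
#' @return a [cv_ts] with the pressure channels at the optical rate.
#' @export
align_streams <- function(pressure, optical, sync, max_drift = 0.01) {
  stopifnot(inherits(pressure, "cv_ts"), inherits(optical, "cv_ts"),
            inherits(sync, "cv_sync"))
  tp <- sync$pressure; to <- sync$optical
  # least squares: optical_time = offset + drift * pressure_time
  drift <- if (length(tp) == 2L) diff(to) / diff(tp) else
    stats::cov(tp, to) / stats::var(tp)
  offset <- mean(to) - drift * mean(tp)
  if (abs(drift - 1) > max_drift)
    stop(sprintf("cv_sync_drift: fitted clock drift %.4g exceeds %.3g (mispaired pulses?)",
                 drift - 1, max_drift))
  src_t <- offset + drift * ts_times(pressure)  # pressure samples on optical clock
  grid <- ts_times(optical)
  keep <- which(grid >= src_t[1L] & grid <= src_t[length(src_t)])
  if (length(keep) < 2L)
    stop("cv_sync_no_overlap: aligned streams do not overlap")
  out <- apply(pressure$values, 2L, function(v)
    stats::approx(src_t, v, xout = grid[keep])$y)
  cv_ts(out, rate = optical$rate, start = grid[keep[1L]],
        channels = ts_channels(pressure))
}

.window_cols <- c("start", "accepted", "f0", "snr_q", "snr_p",
                  "z_cbv", "z_cpp", "cpp", "abp", "icp", "cbf")

#' Write per-window analysis results to CSV
#'
#' One row per 30 s analysis window: start time, accepted flag, cardiac
#' fundamental frequency, window SNRs of the flow (Q) and volume (P) spectra,
#' both impedance-index variants, and the window means of CPP/ABP/ICP/CBF.
#' Rejected windows are retained with empty impedance fields so provenance is
#' preserved. Numeric fields round-trip bit-identically through
#' [read_windows()].
#'
#' @param windows a data frame as produced by [analyze_recording()].
#' @param path output CSV path.
#' @export
write_windows <- function(windows, path) {
  if (!is.data.frame(windows) || nrow(windows) == 0L)
    stop("cv_io_empty_windows: no windows to write")
  missing <- setdiff(.window_cols, names(windows))
  if (length(missing))
    stop(sprintf("cv_io_bad_windows: missing column(s) %s",
                 paste(missing, collapse = ", ")))
  .write_csv17(windows[.window_cols], path)
}

#' Read per-window analysis results written by [write_windows()]
#' @param path CSV path.
#' @return data frame with one row per window.
#' @export
read_windows <- function(path) {
  df <- utils::read.csv(path)
  df$accepted <- as.logical(df$accepted)
  for (col in setdiff(.window_cols, c("accepted"))) df[[col]] <- as.numeric(df[[col]])
  df
}
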