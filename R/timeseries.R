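#' Uniformly sampled multichannel time series
#'
#' The universal currency between processing stages: a samples-by-channels
#' matrix with a start time and a sampling rate. Sampling is uniform by
#' construction -- there are no per-sample timestamps. Pressure channels are in
#' mmHg, the DCS flow index in flow units (cm^2/s-equivalent, relative), and
#' hemoglobin channels in micromolar.
#'
#' @param values numeric matrix (samples x channels) or vector; finite.
#' @param rate sampling rate in Hz, > 0.
#' @param start time of the first sample in seconds.
#' @param channels optional channel names; defaults to column names.
#' @return an object of class `cv_ts`.
#' @export
cv_ts <- function(values, rate, start = 0, channels = NULL) {
  if (is.vector(values)) values <- matrix(values, ncol = 1)
  if (!is.matrix(values) || !is.numeric(values))
    stop("cv_ts_invalid_values: `values` must be a numeric matrix or vector")
  if (!is.null(channels)) colnames(values) <- channels
  if (is.null(colnames(values)))
    colnames(values) <- paste0("ch", seq_len(ncol(values)))
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("cv_ts_invalid_rate: `rate` must be a single positive number")
  if (anyNA(values) || any(!is.finite(values)))
    stop("cv_ts_nonfinite: time series values must be finite (gaps must be handled explicitly before construction)")
  structure(list(values = values, rate = as.numeric(rate),
                 start = as.numeric(start)),
            class = "cv_ts")
}

#' @export
print.cv_ts <- function(x, ...) {
  cat(sprintf("<cv_ts> %d samples x %d channel(s) @ %g Hz, t = [%g, %g] s\n",
              nrow(x$values), ncol(x$values), x$rate,
              x$start, x$start + (nrow(x$values) - 1L) / x$rate))
  cat("  channels:", paste(colnames(x$values), collapse = ", "), "\n")
  invisible(x)
}

#' Channel names of a time series
#' @param ts a `cv_ts`.
#' @return character vector.
#' @export
ts_channels <- function(ts) colnames(ts$values)

#' Sampling rate (Hz)
#' @param ts a `cv_ts`.
#' @export
ts_rate <- function(ts) ts$rate

#' Start time (s)
#' @param ts a `cv_ts`.
#' @export
ts_start <- function(ts) ts$start

#' Number of samples
#' @param ts a `cv_ts`.
#' @export
ts_length <- function(ts) nrow(ts$values)

#' Duration in seconds (n / rate)
#' @param ts a `cv_ts`.
#' @export
ts_duration <- function(ts) nrow(ts$values) / ts$rate

#' Sample times (s)
#' @param ts a `cv_ts`.
#' @export
ts_times <- function(ts) ts$start + (seq_len(nrow(ts$values)) - 1L) / ts$rate

#' Extract one channel as a numeric vector
#' @param ts a `cv_ts`.
#' @param channel channel name.
#' @export
ts_channel <- function(ts, channel) {
  if (!channel %in% colnames(ts$values))
    stop(sprintf("cv_ts_missing_channel: channel '%s' not present (have: %s)",
                 channel, paste(colnames(ts$values), collapse = ", ")))
  ts$values[, channel]
}

#' Values matrix (samples x channels)
#' @param ts a `cv_ts`.
#' @export
ts_values <- function(ts) ts$values

#' Subset a time series by sample index, keeping rate and adjusting start
#' @param ts a `cv_ts`.
#' @param i integer sample indices (must be contiguous).
#' @export
ts_slice <- function(ts, i) {
  i <- as.integer(i)
  if (length(i) == 0L) stop("cv_ts_empty_slice: empty index")
  if (any(diff(i) != 1L)) stop("cv_ts_noncontiguous_slice: indices must be contiguous")
  cv_ts(ts$values[i, , drop = FALSE], ts$rate,
        start = ts$start + (i[1L] - 1L) / ts$rate)
}
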