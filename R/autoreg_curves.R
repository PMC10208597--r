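#' Samplewise cerebral perfusion pressure
#'
#' CPP = ABP - ICP, per sample, on a shared grid.
#'
#' @param abp,icp [cv_ts] with one channel each, equal length, rate and start.
#' @return [cv_ts] with channel CPP (mmHg).
#' @export
cpp_series <- function(abp, icp) {
  stopifnot(inherits(abp, "cv_ts"), inherits(icp, "cv_ts"))
  if (nrow(abp$values) != nrow(icp$values) || abp$rate != icp$rate)
    stop("cv_curve_misaligned: ABP and ICP must share length and rate")
  cv_ts(abp$values[, 1L] - icp$values[, 1L], rate = abp$rate,
        start = abp$start, channels = "CPP")
}

#' Bin a per-window statistic by CPP
#'
#' Accepted analysis windows are binned by their mean CPP into half-open
#' 3 mmHg bins anchored at multiples of the width ([3k, 3k+3)); per bin the
#' mean, count and standard error of the mean are kept, and bins with one or
#' fewer samples are discarded.
#'
#' @param windows data frame from [analyze_recording()] (or [read_windows()]).
#' @param statistic "impedance" (default, CBV-based), "impedance_cpp", or
#'   "cbf" for a Lassen curve.
#' @param bin_width bin width in mmHg (default 3).
#' @param cpp_min,cpp_max optional truncation of the analysis range (windows
#'   outside are dropped before binning).
#' @return object of class `cv_curve`: data frame with `center`, `value`,
#'   `se`, `n`; attributes `bin_width` and `normalized`.
#' @export
bin_curve <- function(windows, statistic = c("impedance", "impedance_cpp", "cbf"),
                      bin_width = 3, cpp_min = NULL, cpp_max = NULL) {
  statistic <- match.arg(statistic)
  col <- switch(statistic, impedance = "z_cbv", impedance_cpp = "z_cpp",
                cbf = "cbf")
  w <- windows[windows$accepted & !is.na(windows[[col]]), , drop = FALSE]
  if (!is.null(cpp_min)) w <- w[w$cpp >= cpp_min, , drop = FALSE]
  if (!is.null(cpp_max)) w <- w[w$cpp <= cpp_max, , drop = FALSE]
  if (nrow(w) == 0L) stop("cv_curve_no_windows: no accepted windows to bin")
  edge <- floor(w$cpp / bin_width) * bin_width
  sp <- split(w[[col]], edge)
  centers <- as.numeric(names(sp)) + bin_width / 2
  n <- vapply(sp, length, integer(1))
  value <- vapply(sp, mean, numeric(1))
  se <- vapply(sp, function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_,
               numeric(1))
  keep <- n >= 2L
  out <- data.frame(center = centers[keep], value = unname(value[keep]),
                    se = unname(se[keep]), n = unname(n[keep]))
  out <- out[order(out$center), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("cv_curve", "data.frame"),
            bin_width = bin_width, normalized = FALSE, statistic = statistic,
            n_discarded = sum(!keep), n_accepted = nrow(w))
}

#' Normalize a binned curve to the reference CPP bin
#'
#' Divides the statistic and its standard error by the value of the bin
#' containing the reference CPP (default 65 mmHg, i.e. the [63, 66) bin), so
#' curves from different subjects can be cohort-averaged. Idempotent once the
#' reference bin reads 1.
#'
#' @param curve a `cv_curve`.
#' @param ref reference CPP in mmHg (default 65).
#' @return normalized `cv_curve`.
#' @export
normalize_curve <- function(curve, ref = 65) {
  bw <- attr(curve, "bin_width")
  ref_center <- floor(ref / bw) * bw + bw / 2
  i <- which(abs(curve$center - ref_center) < 1e-9)
  if (length(i) != 1L)
    stop(sprintf("cv_curve_no_reference: bin containing %g mmHg absent or discarded", ref))
  v0 <- curve$value[i]
  if (v0 == 0) stop("cv_curve_degenerate_reference: reference-bin statistic is zero")
  out <- curve
  out$value <- curve$value / v0
  out$se <- curve$se / v0
  attr(out, "normalized") <- TRUE
  attr(out, "ref") <- ref
  out
}

#' Cohort-average normalized curves across subjects
#'
#' Per-bin unweighted mean across the subjects that have that bin, with the
#' cross-subject standard error; bins present in fewer than two subjects are
#' dropped. All curves must share the bin grid (same width and anchoring).
#'
#' @param curves list of (normalized) `cv_curve` objects, length >= 2.
#' @return cohort `cv_curve`.
#' @export
cohort_average <- function(curves) {
  stopifnot(length(curves) >= 2L)
  bw <- unique(vapply(curves, attr, numeric(1), "bin_width"))
  if (length(bw) != 1L)
    stop("cv_curve_incompatible_grids: curves have different bin widths")
  phase <- vapply(curves, function(c) (c$center[1L] - bw / 2) %% bw, numeric(1))
  if (any(abs(phase - phase[1L]) > 1e-9))
    stop("cv_curve_incompatible_grids: curves have different bin anchoring")
  centers <- sort(unique(unlist(lapply(curves, function(c) c$center))))
  rows <- lapply(centers, function(ct) {
    vals <- unlist(lapply(curves, function(c) c$value[abs(c$center - ct) < 1e-9]))
    if (length(vals) < 2L) return(NULL)
    data.frame(center = ct, value = mean(vals),
               se = stats::sd(vals) / sqrt(length(vals)), n = length(vals))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop("cv_curve_no_common_bins: no bin shared by >= 2 subjects")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("cv_curve", "data.frame"), bin_width = bw,
            normalized = TRUE, statistic = attr(curves[[1L]], "statistic"))
}

#' @export
print.cv_curve <- function(x, ...) {
  cat(sprintf("<cv_curve> %s, %d bins (width %g mmHg)%s\n",
              attr(x, "statistic"), nrow(x), attr(x, "bin_width"),
              if (isTRUE(attr(x, "normalized"))) ", normalized" else ""))
  print.data.frame(x, ...)
  invisible(x)
}

.piecewise_design <- function(x, b1, b2, shape) {
  if (shape == "tent") cbind(1, x, pmax(x - b1, 0), pmax(x - b2, 0))
  else cbind(1, pmin(x - b1, 0), pmax(x - b2, 0))   # plateau: flat middle
}

.piecewise_fit <- function(x, y, b1, b2, shape) {
  X <- .piecewise_design(x, b1, b2, shape)
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  if (anyNA(beta)) return(NULL)
  slopes <- if (shape == "tent")
    c(beta[2L], beta[2L] + beta[3L], beta[2L] + beta[3L] + beta[4L])
  else c(beta[2L], 0, beta[3L])
  ok <- if (shape == "tent") slopes[1L] < 0 && slopes[2L] > 0 && slopes[3L] < 0
        else slopes[1L] > 0 && slopes[3L] > 0
  if (!ok) return(NULL)
  list(sse = sum(fit$residuals^2), slopes = slopes)
}

#' Estimate the lower and upper limits of autoregulation from a binned curve
#'
#' Exhaustive grid search over ordered breakpoint pairs (b1 < b2) fitting a
#' continuous three-segment piecewise-linear model by least squares.
#' `shape = "tent"` constrains segment slopes to (-, +, -), matching the
#' impedance-index curve (impedance rises with CPP inside the autoregulatory
#' range and falls outside); `shape = "plateau"` constrains them to (+, 0, +)
#' for Lassen curves (flat CBF inside the range). Candidate breakpoints lie on
#' a half-bin grid spanning the curve so that limits at bin edges as well as
#' bin centers are representable. Returns the SSE-minimizing pair.
#'
#' @param curve a `cv_curve` with at least 6 bins.
#' @param shape "tent" or "plateau".
#' @param grid_step candidate breakpoint spacing in mmHg (default half the bin
#'   width).
#' @param min_pts minimum data points required in each segment (default 2).
#' @return list with `lla`, `ula` (mmHg), `sse`, `slopes`, `shape`.
#' @export
estimate_limits <- function(curve, shape = c("tent", "plateau"),
                            grid_step = NULL, min_pts = 2L) {
  shape <- match.arg(shape)
  if (nrow(curve) < 6L)
    stop("cv_curve_too_few_bins: need >= 6 bins to place two breakpoints")
  if (is.null(grid_step)) grid_step <- attr(curve, "bin_width") / 2
  x <- curve$center; y <- curve$value
  cand <- seq(min(x), max(x), by = grid_step)
  best <- NULL
  for (b1 in cand) for (b2 in cand[cand > b1]) {
    if (sum(x < b1) < min_pts || sum(x > b2) < min_pts ||
        sum(x >= b1 & x <= b2) < min_pts) next
    fit <- .piecewise_fit(x, y, b1, b2, shape)
    if (is.null(fit)) next
    if (is.null(best) || fit$sse < best$sse)
      best <- list(lla = b1, ula = b2, sse = fit$sse, slopes = fit$slopes,
                   shape = shape)
  }
  if (is.null(best))
    stop("cv_curve_no_limits: no breakpoint pair satisfies the slope constraints")
  best
}
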