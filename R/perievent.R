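#' Extract an event-aligned epoch from a normalized trace
#'
#' Takes every sample whose time lies in the closed window
#' `[event_time - pre, event_time + post]` and re-expresses time
#' relative to the event. The baseline is the pre-event slice
#' (relative time `< 0`). If the window is not fully contained in the
#' trace's recording, the epoch is rejected: the function returns an
#' `epoch_rejection` object carrying the reason, so callers can keep a
#' machine-readable exclusion report instead of silently dropping
#' events.
#'
#' @param trace A `normalized_signal`.
#' @param event_time Event time in seconds (fiber clock).
#' @param window Numeric length-2 `c(pre_s, post_s)`, both positive.
#' @return An object of class `fp_epoch`, or `epoch_rejection`.
#' @export
extract_epoch <- function(trace, event_time, window) {
  stopifnot(length(window) == 2, all(window > 0))
  tm <- trace$recording$time
  lo <- event_time - window[1]
  hi <- event_time + window[2]
  if (lo < tm[1] || hi > tm[length(tm)]) {
    return(epoch_rejection(event_time, "window outside recording"))
  }
  idx <- which(tm >= lo & tm <= hi)
  rel <- tm[idx] - event_time
  if (!any(rel < 0) || !any(rel > 0)) {
    return(epoch_rejection(event_time, "empty baseline or post-event slice"))
  }
  structure(list(event_time = event_time,
                 rel_time = rel,
                 values = trace$values[idx],
                 method = trace$method,
                 window = window,
                 sample_idx = idx),
            class = "fp_epoch")
}

epoch_rejection <- function(event_time, reason) {
  structure(list(event_time = event_time, reason = reason),
            class = "epoch_rejection")
}

#' @export
print.fp_epoch <- function(x, ...) {
  cat(sprintf("<fp_epoch> event %.3f s, window (-%g, +%g) s, %d samples ('%s')\n",
              x$event_time, x$window[1], x$window[2], length(x$values),
              x$method))
  invisible(x)
}

epoch_baseline <- function(e) e$values[e$rel_time < 0]

#' Baseline Z-score of an epoch
#'
#' Renormalizes the epoch against its own pre-event baseline:
#' `z = (values - mean(baseline)) / sd(baseline)`. A baseline with zero
#' standard deviation rejects the epoch.
#'
#' @param e An `fp_epoch`.
#' @return Numeric vector of Z-scored values (same length as
#'   `e$values`), or an `epoch_rejection`.
#' @export
zscore_epoch <- function(e) {
  bs <- epoch_baseline(e)
  s <- stats::sd(bs)
  if (!is.finite(s) || s == 0) {
    return(epoch_rejection(e$event_time, "zero baseline standard deviation"))
  }
  (e$values - mean(bs)) / s
}

#' Baseline robust Z-score of an epoch
#'
#' As [zscore_epoch()] but median/MAD based:
#' `rz = (values - median(baseline)) / MAD(baseline)` with the raw MAD
#' of [mad_raw()]. Outliers in the baseline barely move the median and
#' MAD, so heavy-tailed baselines do not distort the renormalization.
#'
#' @param e An `fp_epoch`.
#' @return Numeric vector of robust Z-scores, or an `epoch_rejection`.
#' @export
robust_zscore_epoch <- function(e) {
  bs <- epoch_baseline(e)
  m <- mad_raw(bs)
  if (!is.finite(m) || m == 0) {
    return(epoch_rejection(e$event_time, "zero baseline MAD"))
  }
  (e$values - stats::median(bs)) / m
}

#' Interpolate epochs onto a common relative-time grid
#'
#' Epochs from different recordings have slightly different sampling
#' rates and grid phases. All epochs (which must share one window) are
#' linearly interpolated onto a uniform grid over `[-pre, +post]` whose
#' sample count is the maximum count among the epochs; values requested
#' just outside an epoch's own grid take the nearest endpoint value.
#'
#' @param epochs List of `fp_epoch` objects sharing one window.
#' @return List with `grid` (relative times), `signals` (matrix, one
#'   column per epoch), and `mean` (pointwise mean trace).
#' @export
interpolate_epochs <- function(epochs) {
  stopifnot(length(epochs) >= 1)
  wins <- vapply(epochs, function(e) e$window, numeric(2))
  if (any(abs(wins - wins[, 1]) > 1e-9)) {
    stop("epochs have mixed perievent windows; cannot interpolate",
         call. = FALSE)
  }
  pre <- wins[1, 1]; post <- wins[2, 1]
  n <- max(vapply(epochs, function(e) length(e$values), integer(1)))
  grid <- seq(-pre, post, length.out = n)
  signals <- vapply(epochs, function(e) {
    stats::approx(e$rel_time, e$values, xout = grid, rule = 2)$y
  }, numeric(n))
  signals <- matrix(signals, nrow = n)
  list(grid = grid, signals = signals, mean = rowMeans(signals))
}

# trapezoidal integral of y over x restricted to [a, b], with linear
# interpolation at the cut points
trapz_between <- function(x, y, a, b) {
  keep <- x >= a & x <= b
  xs <- x[keep]; ys <- y[keep]
  if (a > min(x) && !any(x == a)) {
    xs <- c(a, xs); ys <- c(stats::approx(x, y, xout = a)$y, ys)
  }
  if (b < max(x) && !any(x == b)) {
    xs <- c(xs, b); ys <- c(ys, stats::approx(x, y, xout = b)$y)
  }
  if (length(xs) < 2) return(0)
  pracma::trapz(xs, ys)
}

#' Summarize one epoch
#'
#' Computes the per-epoch summary reported in the batch results table:
#' pre/post area under the curve (trapezoid over seconds, split at the
#' event, not time-normalized), pre/post averages of the trace in its
#' native normalization and of its baseline Z and robust-Z variants,
#' and pre/post transient statistics from [detect_peaks()] run on the
#' epoch itself.
#'
#' @param e An `fp_epoch`.
#' @param peaks_cfg A [peak_params()] object for the within-epoch peak
#'   detection.
#' @return One-row `data.frame` with columns `preAUC`, `postAUC`,
#'   `preAVG_dF`, `postAVG_dF`, `preAVG_Z`, `PostAVG_Z`, `preAVG_RZ`,
#'   `PostAVG_RZ`, `pre_peak_freq`, `post_peak_freq`, `pre_peak_amp`,
#'   `post_peak_amp`. Z/RZ columns are `NA` when the corresponding
#'   renormalization is degenerate.
#' @export
summarize_epoch <- function(e, peaks_cfg = peak_params()) {
  rel <- e$rel_time; v <- e$values
  pre_idx <- rel < 0; post_idx <- rel > 0
  z <- zscore_epoch(e)
  rz <- robust_zscore_epoch(e)
  avg <- function(x, idx) if (inherits(x, "epoch_rejection")) NA_real_ else mean(x[idx])
  pk <- detect_peaks(list(time = rel, values = v), peaks_cfg)
  pre_pk <- peak_stats(pk, c(-e$window[1], 0))
  post_pk <- peak_stats(pk, c(0, e$window[2] + 1e-12))
  data.frame(
    preAUC = trapz_between(rel, v, -e$window[1], 0),
    postAUC = trapz_between(rel, v, 0, e$window[2]),
    preAVG_dF = mean(v[pre_idx]),
    postAVG_dF = mean(v[post_idx]),
    preAVG_Z = avg(z, pre_idx),
    PostAVG_Z = avg(z, post_idx),
    preAVG_RZ = avg(rz, pre_idx),
    PostAVG_RZ = avg(rz, post_idx),
    pre_peak_freq = pre_pk$frequency,
    post_peak_freq = post_pk$frequency,
    pre_peak_amp = pre_pk$mean_amplitude,
    post_peak_amp = post_pk$mean_amplitude
  )
}
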