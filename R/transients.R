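#' Median absolute deviation (raw, no consistency constant)
#'
#' `MAD(x) = median(|x_i - median(x)|)`. This is the robust spread
#' estimator used throughout the transient detector and the robust
#' perievent Z-score; note the absence of the 1.4826 Gaussian
#' consistency constant.
#'
#' @param x Non-empty numeric vector.
#' @return Scalar MAD.
#' @export
#' @examples
#' mad_raw(c(1, 2, 3, 4, 5))   # 1
mad_raw <- function(x) {
  if (!length(x)) stop("mad_raw: empty input", call. = FALSE)
  stats::mad(x, constant = 1)
}

#' Transient detection parameters
#'
#' @param window_s Analysis window length in seconds (non-overlapping;
#'   the last window may be short). Windowing limits the impact of
#'   photobleaching-driven decay, which would otherwise suppress
#'   detection late in a recording.
#' @param bmad_k Baseline MAD multiplier for the first threshold.
#' @param pmad_k Peak MAD multiplier for the second threshold.
#' @param spacing_ms Refractory spacing: within any run of candidates
#'   closer than this, only the highest sample is kept. Matched to the
#'   sensor rise time (GCaMP6f ~50 ms).
#' @param scope Standardization scope: scores computed `"per-window"`
#'   or over the `"whole-recording"`.
#' @param config Optional `fp_config` whose `transients` section
#'   supplies any argument not given explicitly.
#' @return A list of class `peak_params`.
#' @export
peak_params <- function(window_s = NULL, bmad_k = NULL, pmad_k = NULL,
                        spacing_ms = NULL, scope = NULL,
                        config = default_config()) {
  tr <- config$transients
  p <- list(window_s = window_s %||% tr$window_s,
            bmad_k = bmad_k %||% tr$bmad_k,
            pmad_k = pmad_k %||% tr$pmad_k,
            spacing_ms = spacing_ms %||% tr$spacing_ms,
            scope = scope %||% tr$scope)
  stopifnot(p$window_s > 0, p$bmad_k > 0, p$pmad_k > 0, p$spacing_ms > 0,
            p$scope %in% c("per-window", "whole-recording"))
  structure(p, class = "peak_params")
}

#' Detect transients by windowed MAD double-thresholding
#'
#' The trace is cut into non-overlapping windows of `window_s` seconds
#' (a trace shorter than one window is analyzed as a single window).
#' Within each window, deviations are measured from the window median:
#' \enumerate{
#'   \item optionally standardize (per the `scope` parameter);
#'   \item first threshold: `bmad_k * MAD(window)` above the window
#'     median (bMAD). Samples at or below it are set aside as baseline;
#'   \item second threshold: `pmad_k` times the median deviation of the
#'     *remaining* (supra-threshold) samples, still measured from the
#'     window median (pMAD). Samples strictly above it are transient
#'     candidates;
#'   \item a refractory maxima filter keeps only the highest sample
#'     within any run of candidates spaced closer than `spacing_ms`.
#' }
#' Because stage 2 rescales by the spread of the extreme tail rather
#' than of the bulk, the effective threshold sits far above what noise
#' alone reaches, while genuine transients (an order of magnitude above
#' the noise MAD) survive. A window with zero MAD (e.g. a constant
#' trace) yields no peaks, with a warning; so does a window with fewer
#' than 2 samples above the first threshold.
#'
#' @param trace A `normalized_signal`, or a list with `time` and
#'   `values` vectors.
#' @param params A [peak_params()] object.
#' @return `data.frame` with columns `time` (s) and `amplitude` (value
#'   of the input trace at the peak, in its own units).
#' @export
detect_peaks <- function(trace, params = peak_params()) {
  tm <- if (inherits(trace, "normalized_signal")) trace$recording$time else trace$time
  vals <- trace$values
  stopifnot(length(tm) == length(vals))
  score <- vals
  if (params$scope == "whole-recording") {
    s <- stats::sd(vals)
    if (s == 0) {
      warning("constant trace: no peaks", call. = FALSE)
      return(data.frame(time = numeric(0), amplitude = numeric(0)))
    }
    score <- (vals - mean(vals)) / s
  }
  win_id <- floor((tm - tm[1]) / params$window_s)
  cand <- integer(0)
  for (w in unique(win_id)) {
    idx <- which(win_id == w)
    if (length(idx) < 2) next
    v <- score[idx]
    if (params$scope == "per-window") {
      s <- stats::sd(v)
      if (s == 0) {
        warning("degenerate window (zero variance): skipped", call. = FALSE)
        next
      }
      v <- (v - mean(v)) / s
    }
    m <- mad_raw(v)
    if (m == 0) {
      warning("degenerate window (zero MAD): skipped", call. = FALSE)
      next
    }
    d <- v - stats::median(v)
    th1 <- params$bmad_k * m
    rem <- d[d > th1]
    if (length(rem) < 2) next
    th2 <- params$pmad_k * stats::median(rem)
    cand <- c(cand, idx[d > th2 & d > th1])
  }
  if (!length(cand)) return(data.frame(time = numeric(0), amplitude = numeric(0)))
  cand <- sort(cand)
  spacing_s <- params$spacing_ms / 1000
  grp <- cumsum(c(1, diff(tm[cand]) > spacing_s))
  keep <- vapply(split(cand, grp),
                 function(ix) ix[which.max(vals[ix])], integer(1))
  keep <- sort(unname(keep))
  data.frame(time = tm[keep], amplitude = vals[keep])
}

#' Peak frequency and mean amplitude over a span
#'
#' @param peaks `data.frame` from [detect_peaks()].
#' @param span Numeric length-2 `(start_s, end_s)`, `end > start`.
#'   Membership is closed-open `[start, end)`.
#' @return List with `frequency` (peaks/s), `mean_amplitude` (`NA` when
#'   the span holds no peaks), and `n`.
#' @export
peak_stats <- function(peaks, span) {
  stopifnot(length(span) == 2, span[2] > span[1])
  inside <- peaks$time >= span[1] & peaks$time < span[2]
  n <- sum(inside)
  list(frequency = n / (span[2] - span[1]),
       mean_amplitude = if (n) mean(peaks$amplitude[inside]) else NA_real_,
       n = n)
}
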