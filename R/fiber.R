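#' Read a dual-channel photometry CSV file
#'
#' Reads a Doric-style CSV (header row, one column each for time,
#' calcium-dependent signal, and isosbestic control) into a raw fiber
#' object. Column names are taken from `config$fiber$columns`. Rows
#' containing non-finite values in any mapped column are dropped with a
#' message.
#'
#' @param path CSV file path.
#' @param config An `fp_config` supplying the column mapping.
#' @return An object of class `raw_fiber`: list with `path`, `time`,
#'   `signal`, `isosbestic` (equal-length numeric vectors, file order).
#' @export
read_fiber_csv <- function(path, config = default_config()) {
  if (!file.exists(path)) stop("fiber file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  cols <- config$fiber$columns
  missing <- setdiff(unlist(cols), names(df))
  if (length(missing)) {
    stop("fiber CSV ", path, " lacks mapped column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  new_raw_fiber(path,
                time = as.numeric(df[[cols$time]]),
                signal = as.numeric(df[[cols$signal]]),
                isosbestic = as.numeric(df[[cols$isosbestic]]))
}

#' Read a dual-channel photometry HDF5 container
#'
#' Reads the three channel datasets from an HDF5 file (the container
#' format used by recent Doric acquisition software). Dataset names are
#' taken from `config$fiber$hdf5`. Requires the `rhdf5` package.
#'
#' @param path HDF5 file path.
#' @inheritParams read_fiber_csv
#' @return A `raw_fiber` object, identical in structure to
#'   [read_fiber_csv()] output.
#' @export
read_fiber_hdf5 <- function(path, config = default_config()) {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    stop("reading HDF5 fiber files requires the 'rhdf5' package",
         call. = FALSE)
  }
  if (!file.exists(path)) stop("fiber file not found: ", path, call. = FALSE)
  ds <- config$fiber$hdf5
  grab <- function(name) {
    v <- tryCatch(as.numeric(rhdf5::h5read(path, name)),
                  error = function(e) stop("dataset '", name,
                                           "' not found in ", path,
                                           call. = FALSE))
    if (!length(v)) stop("dataset '", name, "' in ", path, " is empty",
                         call. = FALSE)
    v
  }
  out <- new_raw_fiber(path, time = grab(ds$time), signal = grab(ds$signal),
                       isosbestic = grab(ds$isosbestic))
  rhdf5::h5closeAll()
  out
}

new_raw_fiber <- function(path, time, signal, isosbestic) {
  n <- length(time)
  if (length(signal) != n || length(isosbestic) != n) {
    stop("time, signal and isosbestic channels differ in length",
         call. = FALSE)
  }
  ok <- is.finite(time) & is.finite(signal) & is.finite(isosbestic)
  if (any(!ok)) {
    message(sum(!ok), " row(s) with non-finite values dropped from ",
            basename(path))
    time <- time[ok]; signal <- signal[ok]; isosbestic <- isosbestic[ok]
  }
  if (length(time) < 2) {
    stop("fewer than 2 valid rows in ", path, call. = FALSE)
  }
  structure(list(path = path, time = time, signal = signal,
                 isosbestic = isosbestic),
            class = "raw_fiber")
}

#' Write a photometry CSV / HDF5 twin
#'
#' Writers for the two supported containers. The CSV writer prints at
#' full double precision (17 significant digits) so that a written file
#' re-reads to bit-identical vectors, and so that CSV and HDF5 twins of
#' the same data compare equal.
#'
#' @param raw A `raw_fiber` object (or any list with `time`, `signal`,
#'   `isosbestic`).
#' @param path Output path.
#' @param config An `fp_config` supplying column / dataset names.
#' @return `path`, invisibly.
#' @export
write_fiber_csv <- function(raw, path, config = default_config()) {
  cols <- config$fiber$columns
  df <- data.frame(sprintf("%.17g", raw$time),
                   sprintf("%.17g", raw$signal),
                   sprintf("%.17g", raw$isosbestic))
  names(df) <- c(cols$time, cols$signal, cols$isosbestic)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fiber_csv
#' @export
write_fiber_hdf5 <- function(raw, path, config = default_config()) {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    stop("writing HDF5 fiber files requires the 'rhdf5' package",
         call. = FALSE)
  }
  ds <- config$fiber$hdf5
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(raw$time, path, ds$time)
  rhdf5::h5write(raw$signal, path, ds$signal)
  rhdf5::h5write(raw$isosbestic, path, ds$isosbestic)
  rhdf5::h5closeAll()
  invisible(path)
}

#' Split a raw fiber file into contiguous recordings
#'
#' Acquisition is often paused between behavioral phases, so one file
#' can hold several discontinuous recordings. The time axis is split
#' wherever the inter-sample gap strictly exceeds `gap_threshold_s`;
#' segments shorter than `min_length_s` (or with fewer than 2 samples)
#' are discarded with a warning. Recordings are numbered 1..K in
#' temporal order and each carries its own sampling rate, estimated as
#' `(n - 1) / (t_last - t_first)`.
#'
#' @param raw A `raw_fiber` object.
#' @param gap_threshold_s Gap (s) above which the file is split
#'   (default from `config`).
#' @param min_length_s Minimum retained segment span in seconds.
#' @param config An `fp_config` supplying defaults.
#' @return List of `fp_recording` objects.
#' @export
split_recordings <- function(raw, gap_threshold_s = NULL, min_length_s = NULL,
                             config = default_config()) {
  gap_threshold_s <- gap_threshold_s %||% config$fiber$gap_threshold_s
  min_length_s <- min_length_s %||% config$fiber$min_recording_s
  breaks <- which(diff(raw$time) > gap_threshold_s)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(raw$time))
  recs <- list()
  for (i in seq_along(starts)) {
    idx <- starts[i]:ends[i]
    span <- raw$time[ends[i]] - raw$time[starts[i]]
    if (length(idx) < 2 || span < min_length_s) {
      warning("discarding recording segment of ", signif(span, 3),
              " s (< ", min_length_s, " s minimum)", call. = FALSE)
      next
    }
    recs[[length(recs) + 1L]] <- structure(
      list(index = length(recs) + 1L,
           time = raw$time[idx],
           signal = raw$signal[idx],
           isosbestic = raw$isosbestic[idx],
           sampling_rate = (length(idx) - 1) / span,
           source = raw$path),
      class = "fp_recording")
  }
  recs
}

#' @export
print.fp_recording <- function(x, ...) {
  cat(sprintf("<fp_recording #%d> [%.3f, %.3f] s, %d samples @ %.1f Hz\n",
              x$index, x$time[1], x$time[length(x$time)], length(x$time),
              x$sampling_rate))
  invisible(x)
}

#' Isosbestic-corrected dF/F
#'
#' Fits the isosbestic (control) channel to the calcium-dependent
#' channel by ordinary least squares on this recording only
#' (`signal ~ a * isosbestic + b`), then expresses the signal as a
#' fractional change relative to the fitted control:
#' `dF/F = (signal - fitted) / fitted`. Because the control channel
#' shares motion and bleaching artifacts but not calcium transients,
#' the fitted control acts as a time-varying baseline.
#'
#' @param rec An `fp_recording`.
#' @return A `normalized_signal` object with method tag `"F"`, the
#'   dimensionless values, and the regression coefficients
#'   `c(slope, intercept)`.
#' @export
compute_dff <- function(rec) {
  iso <- rec$isosbestic; sig <- rec$signal
  if (stats::var(iso) == 0) {
    stop("degenerate control channel: isosbestic has zero variance",
         call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(intercept = 1, slope = iso), sig)
  b <- fit$coefficients[["intercept"]]
  a <- fit$coefficients[["slope"]]
  fitted <- a * iso + b
  if (any(fitted <= 0)) {
    stop("fitted isosbestic non-positive at sample ",
         which(fitted <= 0)[1], "; dF/F undefined", call. = FALSE)
  }
  new_normalized_signal(rec, method = "F", values = (sig - fitted) / fitted,
                        coef = c(slope = a, intercept = b))
}

#' Z-difference normalization
#'
#' Standardizes each channel by its own recording-wide mean and sample
#' standard deviation and subtracts: `Z = z(signal) - z(isosbestic)`.
#' Shared artifacts standardize similarly in both channels and largely
#' cancel.
#'
#' @param rec An `fp_recording`.
#' @return A `normalized_signal` with method tag `"Z"`.
#' @export
compute_zdiff <- function(rec) {
  s_sig <- stats::sd(rec$signal)
  s_iso <- stats::sd(rec$isosbestic)
  if (s_sig == 0 || s_iso == 0) {
    stop("zero standard deviation in signal or isosbestic channel",
         call. = FALSE)
  }
  z <- (rec$signal - mean(rec$signal)) / s_sig -
    (rec$isosbestic - mean(rec$isosbestic)) / s_iso
  new_normalized_signal(rec, method = "Z", values = z)
}

#' Normalize a recording by method tag
#'
#' @param rec An `fp_recording`.
#' @param method `"F"` (dF/F, [compute_dff()]) or `"Z"` (Z-difference,
#'   [compute_zdiff()]).
#' @return A `normalized_signal`.
#' @export
normalize_recording <- function(rec, method = c("F", "Z")) {
  method <- match.arg(method)
  if (method == "F") compute_dff(rec) else compute_zdiff(rec)
}

new_normalized_signal <- function(rec, method, values, coef = NULL) {
  stopifnot(length(values) == length(rec$time))
  structure(list(recording = rec, method = method, values = values,
                 coef = coef),
            class = "normalized_signal")
}

#' @export
print.normalized_signal <- function(x, ...) {
  cat(sprintf("<normalized_signal '%s'> %d samples from recording #%d\n",
              x$method, length(x$values), x$recording$index))
  if (!is.null(x$coef)) {
    cat(sprintf("  control fit: slope %.6g, intercept %.6g\n",
                x$coef[["slope"]], x$coef[["intercept"]]))
  }
  invisible(x)
}

#' Write a normalized trace to CSV
#'
#' @param ns A `normalized_signal`.
#' @param path Output CSV path (columns `time_s`, `value`, `method`).
#' @return `path`, invisibly.
#' @export
write_normalized_csv <- function(ns, path) {
  df <- data.frame(time_s = sprintf("%.17g", ns$recording$time),
                   value = sprintf("%.17g", ns$values),
                   method = ns$method)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
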