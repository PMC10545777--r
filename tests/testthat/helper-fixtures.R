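# Shared fixtures, built in code. The synthetic study is expensive enough
# to build once and reuse across test files (helpers are sourced once per
# test run, so this environment persists).

.fixture_env <- new.env(parent = emptyenv())

# default 3-session synthetic study (behavior + photometry), seed 11
shared_study <- function() {
  if (is.null(.fixture_env$study)) {
    root <- file.path(tempdir(), "opfiber-study-fixture")
    unlink(root, recursive = TRUE)
    .fixture_env$study_root <- root
    .fixture_env$study <- simulate_study(root, n_sessions = 3, seed = 11)
  }
  list(root = .fixture_env$study_root, sessions = .fixture_env$study)
}

# a single parsed + interval-derived session from the shared study
shared_session <- function(i = 1) {
  st <- shared_study()
  derive_intervals(parse_imetronic(st$sessions[[i]]$behavior$files[["imetronic"]]))
}

# small uniform recording carrying given signal/isosbestic vectors
make_recording <- function(signal, isosbestic, rate = 100, t0 = 0) {
  n <- length(signal)
  structure(list(index = 1L,
                 time = t0 + seq_len(n) / rate,
                 signal = signal,
                 isosbestic = isosbestic,
                 sampling_rate = rate,
                 source = NA_character_),
            class = "fp_recording")
}

# normalized trace wrapper around arbitrary values on a uniform grid
make_trace <- function(values, rate = 1000, t0 = 0, method = "F") {
  rec <- make_recording(values, values, rate = rate, t0 = t0)
  structure(list(recording = rec, method = method, values = values,
                 coef = NULL),
            class = "normalized_signal")
}

# epoch built directly from relative times and values
make_epoch <- function(rel_time, values, window, method = "F") {
  structure(list(event_time = 0, rel_time = rel_time, values = values,
                 method = method, window = window,
                 sample_idx = seq_along(values)),
            class = "fp_epoch")
}

# 60 s @ 1000 Hz Gaussian noise with unit-amplitude impulses scaled to
# `amp`; returns the trace and the injected sample indices
impulse_trace <- function(seed = 1, amp = 15, n = 60000, rate = 1000,
                          idx = c(5000, 17000, 29000, 41000, 53000)) {
  set.seed(seed)
  x <- rnorm(n)
  x[idx] <- amp
  list(trace = make_trace(x, rate = rate), idx = idx,
       times = idx / rate)
}

expect_no_peaks_closer_than <- function(peaks, spacing_s) {
  if (nrow(peaks) >= 2) {
    expect_true(all(diff(peaks$time) >= spacing_s))
  } else {
    succeed()
  }
}
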