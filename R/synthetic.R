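#' Template for a synthetic operant session
#'
#' Describes the cocaine intravenous self-administration protocol the
#' generator emulates: three 40-min drug-availability periods (LED2
#' lit) alternating with two 15-min drug-free periods (house light
#' lit); a fixed-ratio 5 schedule in which the fifth active nose-poke
#' lights the cue (LED1) 1 s later for 4 s and triggers the pump 1 s
#' after cue onset; and a 40 s post-injection time-out during which
#' nose-pokes are recorded but have no consequences. Nose-poking is
#' modelled as a homogeneous Poisson process with a separate rate per
#' period type.
#'
#' @param drug_min,nodrug_min Period durations in minutes.
#' @param n_drug,n_nodrug Number of periods of each type (alternating,
#'   starting and ending with a drug period).
#' @param ratio Fixed-ratio requirement (active pokes per injection).
#' @param timeout_s Post-injection time-out duration (s).
#' @param cue_latency_s Delay from the completing poke to cue onset.
#' @param cue_duration_s Cue (LED1) illumination time.
#' @param pump_latency_s Delay from cue onset to pump activation.
#' @param rate_drug,rate_nodrug Active nose-poke Poisson rates
#'   (events/s) during drug and drug-free periods.
#' @param rate_inactive Inactive (np2) poke rate over the whole
#'   session.
#' @return List of class `session_template`.
#' @export
session_template <- function(drug_min = 40, nodrug_min = 15, n_drug = 3,
                             n_nodrug = 2, ratio = 5, timeout_s = 40,
                             cue_latency_s = 1, cue_duration_s = 4,
                             pump_latency_s = 1, rate_drug = 0.05,
                             rate_nodrug = 0.02, rate_inactive = 0.01) {
  stopifnot(drug_min > 0, nodrug_min > 0, n_drug >= 1, n_nodrug >= 0,
            ratio >= 1, timeout_s > 0, rate_drug >= 0, rate_nodrug >= 0,
            rate_inactive >= 0)
  structure(as.list(environment()), class = "session_template")
}

# poisson event times on [a, b), rounded to ms so files round-trip exactly
poisson_times <- function(rate, a, b) {
  if (rate <= 0 || b <= a) return(numeric(0))
  n <- stats::rpois(1, rate * (b - a))
  round(sort(stats::runif(n, a, b)) * 1000) / 1000
}

#' Generate a synthetic operant session with ground truth
#'
#' Draws a full session from a [session_template()]: period lights,
#' Poisson nose-pokes, fixed-ratio cue/injection chains (only during
#' drug periods; pokes during time-outs or drug-free periods are
#' recorded without consequence), and the implied intervals. The
#' session is written in both supported dialects -- an integer-coded
#' tab-separated file and a generic column-per-event file -- together
#' with ground-truth tables, so parser round-trips can be checked
#' exactly. Deterministic given `seed`.
#'
#' @param tmpl A [session_template()].
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param config An `fp_config` supplying the integer event codes used
#'   by the tab-coded writer.
#' @return List with `files` (named: `imetronic`, `generic`, `truth`)
#'   and `truth` (list: `events`, `intervals`, `session_end`, `seed`).
#' @export
simulate_behavior <- function(tmpl = session_template(), dir, seed = 1,
                              config = default_config()) {
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # period structure: D N D N D ...
  types <- rep(c("drug", "nodrug"), length.out = tmpl$n_drug + tmpl$n_nodrug)
  durs <- ifelse(types == "drug", tmpl$drug_min, tmpl$nodrug_min) * 60
  ends <- cumsum(durs)
  starts <- c(0, ends[-length(ends)])
  session_end <- ends[length(ends)]

  ev <- list()
  add <- function(name, time) {
    ev[[length(ev) + 1L]] <<- data.frame(name = name, time = time)
  }
  for (i in seq_along(types)) {
    if (types[i] == "drug") {
      add("led2_on", starts[i]); add("led2_off", ends[i])
    } else {
      add("hled_on", starts[i]); add("hled_off", ends[i])
    }
  }
  np1 <- sort(unlist(lapply(seq_along(types), function(i) {
    rate <- if (types[i] == "drug") tmpl$rate_drug else tmpl$rate_nodrug
    poisson_times(rate, starts[i], ends[i])
  })))
  np2 <- poisson_times(tmpl$rate_inactive, 0, session_end)
  if (length(np1)) add("np1", np1)
  if (length(np2)) add("np2", np2)

  drug_iv <- data.frame(start = starts[types == "drug"],
                        end = ends[types == "drug"])
  timeout_until <- -Inf
  counter <- 0L
  inj <- numeric(0); cue_on <- numeric(0); cue_off <- numeric(0)
  timeouts <- data.frame(start = numeric(0), end = numeric(0))
  for (t in np1) {
    if (t < timeout_until) next                     # no consequences
    if (!any(t >= drug_iv$start & t < drug_iv$end)) next  # drug unavailable
    counter <- counter + 1L
    if (counter == tmpl$ratio) {
      c_on <- t + tmpl$cue_latency_s
      i_t <- c_on + tmpl$pump_latency_s
      cue_on <- c(cue_on, c_on)
      cue_off <- c(cue_off, c_on + tmpl$cue_duration_s)
      inj <- c(inj, i_t)
      timeout_until <- i_t + tmpl$timeout_s
      timeouts <- rbind(timeouts,
                        data.frame(start = i_t,
                                   end = min(i_t + tmpl$timeout_s,
                                             session_end)))
      counter <- 0L
    }
  }
  if (length(cue_on)) { add("led1_on", cue_on); add("led1_off", cue_off) }
  if (length(inj)) add("inj1", inj)

  events <- do.call(rbind, ev)
  events <- events[order(events$time, events$name), ]
  rownames(events) <- NULL

  intervals <- rbind(
    data.frame(name = "DRUG", drug_iv),
    data.frame(name = "NODRUG", start = starts[types == "nodrug"],
               end = ends[types == "nodrug"]),
    if (nrow(timeouts)) data.frame(name = "TIMEOUT", timeouts),
    if (length(cue_on)) data.frame(name = "LED1_ON", start = cue_on,
                                   end = cue_off))
  truth <- list(events = events, intervals = intervals,
                session_end = session_end, seed = seed)

  files <- c(
    imetronic = write_imetronic_dat(events, file.path(dir, "events_imetronic.dat"),
                                    config),
    generic = write_generic_dat(events, file.path(dir, "events_generic.dat")),
    truth = write_truth_json(truth, file.path(dir, "truth_behavior.json")))
  list(files = files, truth = truth)
}

# tab-separated integer-coded writer (inverse of parse_imetronic)
write_imetronic_dat <- function(events, path, config) {
  defs <- config$behavior$events
  unit <- time_unit_factor(config$behavior$time_unit %||% "ms")
  rows <- character(0)
  for (i in seq_len(nrow(events))) {
    def <- defs[[events$name[i]]]
    if (is.null(def)) {
      stop("no integer code configured for event '", events$name[i], "'",
           call. = FALSE)
    }
    ncol_needed <- max(as.integer(names(def$match)), def$time_col %||% 1L)
    row <- rep(0L, ncol_needed)
    row[as.integer(def$time_col %||% 1L)] <- round(events$time[i] / unit)
    for (col in names(def$match)) row[as.integer(col)] <- def$match[[col]]
    rows <- c(rows, paste(row, collapse = "\t"))
  }
  writeLines(rows, path)
  path
}

# generic column-per-event writer (Table-style dialect), ragged columns
write_generic_dat <- function(events, path) {
  nms <- unique(events$name)
  cols <- lapply(nms, function(nm) sprintf("%.3f", events$time[events$name == nm]))
  depth <- max(vapply(cols, length, integer(1)))
  lines <- c(paste(nms, collapse = ","),
             vapply(seq_len(depth), function(r) {
               paste(vapply(cols, function(cl) {
                 if (r <= length(cl)) cl[r] else ""
               }, character(1)), collapse = ",")
             }, character(1)))
  writeLines(lines, path)
  path
}

write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  path
}

#' Template for a synthetic photometry recording
#'
#' Describes the dual-channel signal model: a shared bleaching baseline
#' `B(t) = baseline * exp(-t / bleach_tau_s)`; calcium transients
#' (difference-of-exponentials kernel, unit peak) entering only the
#' signal channel multiplicatively as fractional fluorescence changes,
#' so a transient of amplitude `a` produces a dF/F excursion of about
#' `a`; a shared slow additive artifact (AR(1)) entering both channels
#' equally (motion); and independent white measurement noise per
#' channel. The isosbestic channel is `iso_scale * B(t) + iso_offset`
#' plus artifact and noise -- affinely related to the signal baseline,
#' exactly the assumption the least-squares dF/F correction relies on.
#'
#' @param sampling_hz Sampling rate (default 1000 Hz).
#' @param blocks `data.frame(start, duration)` in seconds: the
#'   discontinuous recording blocks. The default covers the two
#'   drug-to-no-drug shifts of the default session template (house
#'   light onsets at 2400 s and 5700 s).
#' @param baseline Raw fluorescence baseline (a.u.).
#' @param bleach_tau_s Photobleaching time constant (s).
#' @param iso_scale,iso_offset Affine map from signal baseline to
#'   isosbestic baseline.
#' @param noise_sd White noise SD per channel (raw units).
#' @param artifact_sd,artifact_tau_s SD and time constant of the shared
#'   AR(1) motion artifact (set `artifact_sd = 0` to disable).
#' @param rise_s,decay_s Transient kernel time constants (GCaMP6f-like
#'   50 ms rise).
#' @param spont_rate_hz Spontaneous transient rate.
#' @param amp_meanlog,amp_sdlog Log-normal parameters of spontaneous
#'   transient fractional amplitudes.
#' @param event_locked `NULL`, or `list(event=, latency_s=, amplitude=)`
#'   adding one transient of fixed fractional amplitude at a fixed
#'   latency after every ground-truth occurrence of `event`.
#' @return List of class `photometry_template`.
#' @export
photometry_template <- function(sampling_hz = 1000,
                                blocks = data.frame(start = c(2370, 5670),
                                                    duration = c(60, 60)),
                                baseline = 0.15, bleach_tau_s = 7200,
                                iso_scale = 0.85, iso_offset = 0.02,
                                noise_sd = 2e-4, artifact_sd = 1e-4,
                                artifact_tau_s = 2, rise_s = 0.05,
                                decay_s = 0.4, spont_rate_hz = 0.02,
                                amp_meanlog = log(0.02), amp_sdlog = 0.4,
                                event_locked = list(event = "hled_on",
                                                    latency_s = 0.2,
                                                    amplitude = 0.05)) {
  stopifnot(sampling_hz > 0, all(blocks$duration > 0), baseline > 0,
            bleach_tau_s > 0, rise_s > 0, decay_s > rise_s)
  structure(as.list(environment()), class = "photometry_template")
}

# difference-of-exponentials kernel, normalized to unit peak and shifted
# so the peak sits at t = 0 (transient times denote peak times)
transient_kernel <- function(t, rise_s, decay_s) {
  tpk <- log(decay_s / rise_s) * rise_s * decay_s / (decay_s - rise_s)
  tt <- t + tpk
  k <- ifelse(tt < 0, 0, exp(-tt / decay_s) - exp(-tt / rise_s))
  k / (exp(-tpk / decay_s) - exp(-tpk / rise_s))
}

#' Generate a synthetic photometry recording with ground truth
#'
#' Simulates the dual-channel recording implied by a behavioral ground
#' truth and a [photometry_template()], writes it as a Doric-style CSV
#' (and optionally an HDF5 twin), and extends the truth with transient
#' times/amplitudes, block bounds, and the true affine coefficients
#' linking isosbestic to signal baseline. Deterministic given `seed`.
#'
#' @param truth Behavioral truth from [simulate_behavior()] (used for
#'   event-locked transients); may be `NULL` when
#'   `tmpl$event_locked` is `NULL`.
#' @param tmpl A [photometry_template()].
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param write_h5 Also write an HDF5 twin (requires `rhdf5`).
#' @param config An `fp_config` supplying column/dataset names.
#' @return List with `files` (`csv`, optionally `h5`, `truth`) and
#'   `truth` (list: `transients`, `blocks`, `coef`, `seed`).
#' @export
simulate_photometry <- function(truth = NULL, tmpl = photometry_template(),
                                dir, seed = 1, write_h5 = FALSE,
                                config = default_config()) {
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  all_t <- list(); all_sig <- list(); all_iso <- list()
  transients <- list()
  for (b in seq_len(nrow(tmpl$blocks))) {
    t0 <- tmpl$blocks$start[b]
    t1 <- t0 + tmpl$blocks$duration[b]
    tt <- seq(t0, t1, by = 1 / tmpl$sampling_hz)
    base <- tmpl$baseline * exp(-tt / tmpl$bleach_tau_s)
    # transient times: spontaneous + event-locked
    sp <- poisson_times(tmpl$spont_rate_hz, t0, t1)
    sp_amp <- stats::rlnorm(length(sp), tmpl$amp_meanlog, tmpl$amp_sdlog)
    el <- numeric(0); el_amp <- numeric(0)
    if (!is.null(tmpl$event_locked)) {
      stopifnot(!is.null(truth))
      ev_t <- truth$events$time[truth$events$name == tmpl$event_locked$event]
      el <- ev_t + tmpl$event_locked$latency_s
      el <- el[el >= t0 & el <= t1]
      el_amp <- rep(tmpl$event_locked$amplitude, length(el))
    }
    tr_t <- c(sp, el); tr_a <- c(sp_amp, el_amp)
    frac <- numeric(length(tt))
    for (j in seq_along(tr_t)) {
      frac <- frac + tr_a[j] * transient_kernel(tt - tr_t[j],
                                                tmpl$rise_s, tmpl$decay_s)
    }
    art <- if (tmpl$artifact_sd > 0) {
      rho <- exp(-1 / (tmpl$artifact_tau_s * tmpl$sampling_hz))
      as.numeric(stats::filter(stats::rnorm(length(tt),
                                            sd = tmpl$artifact_sd * sqrt(1 - rho^2)),
                               rho, method = "recursive"))
    } else {
      numeric(length(tt))
    }
    noise1 <- if (tmpl$noise_sd > 0) stats::rnorm(length(tt), sd = tmpl$noise_sd) else 0
    noise2 <- if (tmpl$noise_sd > 0) stats::rnorm(length(tt), sd = tmpl$noise_sd) else 0
    all_t[[b]] <- tt
    all_sig[[b]] <- base * (1 + frac) + art + noise1
    all_iso[[b]] <- tmpl$iso_scale * base + tmpl$iso_offset + art + noise2
    if (length(tr_t)) {
      transients[[b]] <- data.frame(block = b, time = tr_t, amplitude = tr_a,
                                    kind = rep(c("spontaneous", "event_locked"),
                                               c(length(sp), length(el))))
    }
  }
  raw <- list(time = unlist(all_t), signal = unlist(all_sig),
              isosbestic = unlist(all_iso))
  csv <- file.path(dir, "fiber.csv")
  write_fiber_csv(raw, csv, config)
  files <- c(csv = csv)
  if (write_h5) {
    h5 <- file.path(dir, "fiber.h5")
    write_fiber_hdf5(raw, h5, config)
    files <- c(files, h5 = h5)
  }
  ph_truth <- list(
    transients = if (length(transients)) do.call(rbind, transients) else NULL,
    blocks = data.frame(start = tmpl$blocks$start,
                        end = tmpl$blocks$start + tmpl$blocks$duration),
    # signal = (1/iso_scale) * iso - iso_offset/iso_scale (noise-free)
    coef = c(slope = 1 / tmpl$iso_scale,
             intercept = -tmpl$iso_offset / tmpl$iso_scale),
    seed = seed)
  tj <- write_truth_json(ph_truth, file.path(dir, "truth_photometry.json"))
  files <- c(files, truth = tj)
  list(files = files, truth = ph_truth)
}

#' Generate a complete synthetic study
#'
#' Writes `n_sessions` session subfolders under `root`, each holding
#' one behavioral log in each dialect, one photometry CSV, and the
#' ground-truth JSON files -- the layout [discover_sessions()] expects.
#' Session `i` uses seed `seed + i - 1`.
#'
#' @param root Output root directory.
#' @param n_sessions Number of sessions.
#' @param seed Base integer seed.
#' @param behavior_tmpl A [session_template()].
#' @param photo_tmpl A [photometry_template()].
#' @param config An `fp_config`.
#' @return List of per-session results (`behavior`, `photometry`).
#' @export
simulate_study <- function(root, n_sessions = 3, seed = 1,
                           behavior_tmpl = session_template(),
                           photo_tmpl = photometry_template(),
                           config = default_config()) {
  out <- lapply(seq_len(n_sessions), function(i) {
    d <- file.path(root, sprintf("session%02d", i))
    beh <- simulate_behavior(behavior_tmpl, d, seed = seed + i - 1L,
                             config = config)
    pho <- simulate_photometry(beh$truth, photo_tmpl, d,
                               seed = seed + 1000L + i - 1L, config = config)
    list(behavior = beh, photometry = pho)
  })
  invisible(out)
}
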