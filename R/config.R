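#' Built-in analysis configuration
#'
#' Returns the default configuration that drives every other module:
#' event definitions and interval rules for the behavior parsers, column
#' and dataset mappings for the photometry readers, transient-detection
#' parameters and perievent defaults. All defaults ship in code so the
#' package works with no configuration file at all; [load_config()]
#' merges a user YAML file and ad-hoc overrides on top of these values.
#'
#' The default event table encodes a cocaine self-administration
#' protocol: nose-pokes in the active (`np1`) and inactive (`np2`)
#' holes, licks (`lk1`), cue light (`led1_on`/`led1_off`), the
#' drug-period light (`led2_on`/`led2_off`), the house light
#' (`hled_on`/`hled_off`) signalling drug-free periods, and pump
#' activations (`inj1`). Integer-coded log files are matched through
#' per-event `match` patterns (column index -> required integer value)
#' plus a time column; generic column-per-event files take their event
#' names directly from the file header, so only intervals need
#' configuring for them.
#'
#' @return A nested list of class `fp_config` with sections
#'   `behavior`, `fiber`, `transients` and `perievent`.
#' @seealso [load_config()], [save_config()]
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$transients$bmad_k
default_config <- function() {
  cfg <- list(
    behavior = list(
      # raw time unit of integer-coded logs; generic files are already in s
      time_unit = "ms",
      generic_time_unit = "s",
      events = list(
        np1      = list(match = list(`2` = 1L, `3` = 1L), time_col = 1L),
        np2      = list(match = list(`2` = 1L, `3` = 2L), time_col = 1L),
        lk1      = list(match = list(`2` = 2L, `3` = 1L), time_col = 1L),
        led1_on  = list(match = list(`2` = 3L, `3` = 1L), time_col = 1L),
        led1_off = list(match = list(`2` = 3L, `3` = 2L), time_col = 1L),
        led2_on  = list(match = list(`2` = 4L, `3` = 1L), time_col = 1L),
        led2_off = list(match = list(`2` = 4L, `3` = 2L), time_col = 1L),
        hled_on  = list(match = list(`2` = 5L, `3` = 1L), time_col = 1L),
        hled_off = list(match = list(`2` = 5L, `3` = 2L), time_col = 1L),
        inj1     = list(match = list(`2` = 6L, `3` = 1L), time_col = 1L)
      ),
      intervals = list(
        DRUG    = list(kind = "paired_on_off", on = "led2_on", off = "led2_off"),
        NODRUG  = list(kind = "paired_on_off", on = "hled_on", off = "hled_off"),
        HLED_ON = list(kind = "paired_on_off", on = "hled_on", off = "hled_off"),
        LED1_ON = list(kind = "paired_on_off", on = "led1_on", off = "led1_off"),
        TIMEOUT = list(kind = "event_offset", trigger = "inj1", duration_s = 40),
        hled_switch = list(kind = "guarded_switch", onset = "hled_on",
                           prior = "DRUG", lookback_s = 1,
                           label_if = "hled_on_from_led2",
                           label_else = "hled_on_from_dark")
      )
    ),
    fiber = list(
      columns = list(time = "Time", signal = "Signal", isosbestic = "Isosbestic"),
      hdf5 = list(time = "Time", signal = "Signal", isosbestic = "Isosbestic"),
      gap_threshold_s = 1,
      min_recording_s = 5
    ),
    transients = list(
      window_s = 10,
      bmad_k = 2.5,
      pmad_k = 3.5,
      spacing_ms = 50,
      scope = "per-window"
    ),
    perievent = list(
      norm = "F",
      pre_s = 5,
      post_s = 5,
      baseline = NULL   # NULL = whole pre-event span
    )
  )
  structure(cfg, class = "fp_config")
}

#' Load and merge an analysis configuration
#'
#' Builds the effective configuration by layering, in increasing
#' precedence: the built-in defaults ([default_config()]), an optional
#' YAML file, and an optional list of overrides. Keys absent from the
#' file keep their defaults; keys unknown to the schema produce a
#' warning and are ignored.
#'
#' @param path Optional path to a YAML configuration file with any of
#'   the top-level sections `behavior`, `fiber`, `transients`,
#'   `perievent`.
#' @param overrides Optional named list of overrides taking highest
#'   precedence. Names may be dotted paths, e.g.
#'   `list("transients.bmad_k" = 3)`, or nested lists mirroring the
#'   configuration structure.
#' @return A validated `fp_config` list.
#' @export
#' @examples
#' cfg <- load_config()                     # pure defaults
#' cfg <- load_config(overrides = list("transients.window_s" = 5))
#' cfg$transients$window_s
load_config <- function(path = NULL, overrides = NULL) {
  cfg <- unclass(default_config())
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop("configuration file not found: ", path, call. = FALSE)
    }
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    if (!is.list(user)) stop("configuration file must be a YAML mapping", call. = FALSE)
    cfg <- merge_config(cfg, user, context = "")
  }
  if (!is.null(overrides) && length(overrides)) {
    cfg <- merge_config(cfg, expand_dotted(overrides), context = "",
                        allow_unknown = FALSE)
  }
  cfg <- structure(cfg, class = "fp_config")
  validate_config(cfg)
  cfg
}

#' Serialize a configuration to YAML
#'
#' The written file reloads to an identical configuration via
#' [load_config()] (round-trip idempotence).
#'
#' @param config An `fp_config` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(drop_null(unclass(config)), path)
  invisible(path)
}

#' Validate a configuration
#'
#' Checks the invariants every downstream module relies on: strictly
#' positive numeric parameters, unique ASCII event names, and interval
#' rules that reference only defined events (or previously defined
#' intervals).
#'
#' @param config An `fp_config` object.
#' @return `config`, invisibly; stops on violation.
#' @export
validate_config <- function(config) {
  ev_names <- names(config$behavior$events)
  if (anyDuplicated(ev_names)) {
    stop("event names must be unique", call. = FALSE)
  }
  bad <- ev_names[grepl("[^\x20-\x7E]", ev_names)]
  if (length(bad)) {
    stop("event names must be ASCII: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  num <- c(
    fiber.gap_threshold_s = config$fiber$gap_threshold_s,
    fiber.min_recording_s = config$fiber$min_recording_s,
    transients.window_s   = config$transients$window_s,
    transients.bmad_k     = config$transients$bmad_k,
    transients.pmad_k     = config$transients$pmad_k,
    transients.spacing_ms = config$transients$spacing_ms,
    perievent.pre_s       = config$perievent$pre_s,
    perievent.post_s      = config$perievent$post_s
  )
  nonpos <- !is.finite(num) | num <= 0
  if (any(nonpos)) {
    stop("configuration parameters must be strictly positive: ",
         paste(names(num)[nonpos], collapse = ", "), call. = FALSE)
  }
  if (!config$transients$scope %in% c("per-window", "whole-recording")) {
    stop("transients.scope must be 'per-window' or 'whole-recording'",
         call. = FALSE)
  }
  known_intervals <- character(0)
  for (nm in names(config$behavior$intervals)) {
    rule <- config$behavior$intervals[[nm]]
    refs_ev <- switch(rule$kind,
      paired_on_off  = c(rule$on, rule$off),
      event_offset   = rule$trigger,
      guarded_switch = rule$onset,
      set_op         = character(0),
      stop("unknown interval rule kind: ", rule$kind, call. = FALSE))
    missing_ev <- setdiff(refs_ev, ev_names)
    if (length(missing_ev)) {
      stop("interval rule '", nm, "' references undefined event(s): ",
           paste(missing_ev, collapse = ", "), call. = FALSE)
    }
    refs_iv <- switch(rule$kind,
      set_op         = rule$inputs,
      guarded_switch = rule$prior,
      character(0))
    missing_iv <- setdiff(refs_iv, known_intervals)
    if (length(missing_iv)) {
      stop("interval rule '", nm, "' references undefined interval(s): ",
           paste(missing_iv, collapse = ", "), call. = FALSE)
    }
    if (identical(rule$kind, "event_offset") &&
        (!is.finite(rule$duration_s) || rule$duration_s <= 0)) {
      stop("interval rule '", nm, "' has non-positive duration", call. = FALSE)
    }
    if (!identical(rule$kind, "guarded_switch")) {
      known_intervals <- c(known_intervals, nm)
    }
  }
  invisible(config)
}

#' @export
print.fp_config <- function(x, ...) {
  cat("<fp_config>\n")
  cat("  events:    ", paste(names(x$behavior$events), collapse = ", "), "\n")
  cat("  intervals: ", paste(names(x$behavior$intervals), collapse = ", "), "\n")
  cat(sprintf("  transients: window %gs, bMAD k=%g, pMAD k=%g, spacing %g ms (%s)\n",
              x$transients$window_s, x$transients$bmad_k, x$transients$pmad_k,
              x$transients$spacing_ms, x$transients$scope))
  cat(sprintf("  perievent:  norm '%s', window (-%g, +%g) s\n",
              x$perievent$norm, x$perievent$pre_s, x$perievent$post_s))
  invisible(x)
}

# --- internal helpers -------------------------------------------------------

# recursive merge of `user` onto `base`; unknown keys warn and are dropped
merge_config <- function(base, user, context, allow_unknown = TRUE) {
  # event/interval definition tables accept arbitrary entry names
  open_tables <- c(".behavior.events", ".behavior.intervals")
  for (key in names(user)) {
    path <- paste0(context, ".", key)
    if (!key %in% names(base)) {
      if (context %in% open_tables || dirname_cfg(context) %in% open_tables) {
        base[[key]] <- user[[key]]
      } else if (allow_unknown) {
        warning("unknown configuration key ignored: ", sub("^\\.", "", path),
                call. = FALSE)
      } else {
        stop("unknown configuration key: ", sub("^\\.", "", path),
             call. = FALSE)
      }
      next
    }
    if (is.list(base[[key]]) && is.list(user[[key]]) &&
        !is.null(names(user[[key]]))) {
      base[[key]] <- merge_config(base[[key]], user[[key]], path, allow_unknown)
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

dirname_cfg <- function(path) sub("\\.[^.]*$", "", path)

# turn list("a.b" = 1) into list(a = list(b = 1))
expand_dotted <- function(x) {
  out <- list()
  for (nm in names(x)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    leaf <- x[[nm]]
    for (p in rev(parts)) leaf <- stats::setNames(list(leaf), p)
    out <- utils::modifyList(out, leaf)
  }
  out
}

drop_null <- function(x) {
  if (!is.list(x)) return(x)
  x <- x[!vapply(x, is.null, logical(1))]
  lapply(x, drop_null)
}
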