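#' @title Behavioral session objects
#' @description Constructor for a parsed operant session: a sorted event
#'   table, a (possibly empty) interval table, and the session end time.
#'   Usually produced by [parse_imetronic()] or [parse_generic_csv()]
#'   and enriched by [derive_intervals()].
#' @param path Source file path (or `NA` for in-memory sessions).
#' @param events `data.frame` with columns `name` (character) and `time`
#'   (seconds from session start, `>= 0`).
#' @param intervals `data.frame` with columns `name`, `start`, `end`.
#' @param end Session end time in seconds; defaults to the last event or
#'   interval end.
#' @param unmatched Number of log rows that matched no configured event.
#' @return An object of class `behavior_session`.
#' @export
behavior_session <- function(path = NA_character_, events = NULL,
                             intervals = NULL, end = NULL, unmatched = 0L) {
  if (is.null(events)) {
    events <- data.frame(name = character(0), time = numeric(0))
  }
  if (is.null(intervals)) {
    intervals <- data.frame(name = character(0), start = numeric(0),
                            end = numeric(0))
  }
  stopifnot(all(c("name", "time") %in% names(events)),
            all(c("name", "start", "end") %in% names(intervals)))
  if (any(events$time < 0)) stop("event times must be >= 0", call. = FALSE)
  events <- events[order(events$time, events$name), c("name", "time")]
  rownames(events) <- NULL
  if (is.null(end)) {
    end <- max(0, events$time, intervals$end)
  }
  structure(
    list(path = path, events = events, intervals = intervals,
         end = end, unmatched = as.integer(unmatched)),
    class = "behavior_session")
}

#' @export
print.behavior_session <- function(x, ...) {
  cat("<behavior_session> ", if (is.na(x$path)) "(in memory)" else x$path, "\n")
  cat(sprintf("  %d events (%d names), %d intervals (%d names), end %.3f s\n",
              nrow(x$events), length(unique(x$events$name)),
              nrow(x$intervals), length(unique(x$intervals$name)), x$end))
  if (x$unmatched > 0) cat("  ", x$unmatched, "unmatched log rows\n")
  invisible(x)
}

time_unit_factor <- function(unit) {
  switch(unit,
         ms = 1e-3, s = 1, min = 60,
         stop("unknown time unit: ", unit, call. = FALSE))
}

#' Parse an integer-coded (Imetronic-style) behavioral log
#'
#' The log is a tab-separated text file in which each row is one message
#' encoded by integers. Which rows constitute which events is entirely
#' configuration-driven: an event definition gives a `match` pattern
#' (column index -> required integer value) and a `time_col`; matching
#' rows yield one event each, with the timestamp converted from the
#' configured raw unit (`behavior$time_unit`, default milliseconds) to
#' seconds. Rows matching no configured pattern are counted and
#' reported, never fatal.
#'
#' @param path Path to the tab-separated log file.
#' @param config An `fp_config`; see [default_config()] for the event
#'   definition format.
#' @return A [behavior_session()] (without derived intervals; see
#'   [derive_intervals()]).
#' @export
parse_imetronic <- function(path, config = default_config()) {
  if (!file.exists(path)) stop("behavior file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, sep = "\t", header = FALSE, fill = TRUE,
                           colClasses = "numeric")
  unit <- time_unit_factor(config$behavior$time_unit %||% "ms")
  matched <- rep(FALSE, nrow(raw))
  recs <- list()
  for (nm in names(config$behavior$events)) {
    def <- config$behavior$events[[nm]]
    hit <- rep(TRUE, nrow(raw))
    for (col in names(def$match)) {
      ci <- as.integer(col)
      vals <- if (ci <= ncol(raw)) raw[[ci]] else rep(NA_real_, nrow(raw))
      hit <- hit & !is.na(vals) & vals == def$match[[col]]
    }
    if (!any(hit)) next
    matched <- matched | hit
    tc <- as.integer(def$time_col %||% 1L)
    recs[[nm]] <- data.frame(name = nm, time = raw[[tc]][hit] * unit)
  }
  events <- if (length(recs)) do.call(rbind, recs) else NULL
  n_un <- sum(!matched)
  if (is.null(events) || nrow(events) == 0) {
    warning("no configured event matched any row in ", path, call. = FALSE)
  } else if (n_un > 0) {
    message(n_un, " unmatched rows in ", basename(path))
  }
  behavior_session(path = path, events = events, unmatched = n_un)
}

#' Parse a generic column-per-event behavioral file
#'
#' Expects a comma-separated file whose first row holds unique ASCII
#' event names and whose subsequent rows hold timestamps; columns may
#' have unequal lengths (blank cells are simply absent events). Event
#' names are taken directly from the header, so they need not appear in
#' the configuration. By convention these files keep the `.dat`
#' extension.
#'
#' @inheritParams parse_imetronic
#' @return A [behavior_session()].
#' @export
parse_generic_csv <- function(path, config = default_config()) {
  if (!file.exists(path)) stop("behavior file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty behavior file: ", path, call. = FALSE)
  headers <- trimws(strsplit(lines[[1]], ",", fixed = TRUE)[[1]])
  if (anyDuplicated(headers)) {
    stop("duplicate column header(s) in ", path, ": ",
         paste(unique(headers[duplicated(headers)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(grepl("[^\x20-\x7E]", headers))) {
    stop("non-ASCII column header(s) in ", path, call. = FALSE)
  }
  unit <- time_unit_factor(config$behavior$generic_time_unit %||% "s")
  recs <- list()
  for (r in seq_along(lines)[-1]) {
    cells <- strsplit(lines[[r]], ",", fixed = TRUE)[[1]]
    for (ci in seq_along(cells)) {
      cell <- trimws(cells[[ci]])
      if (!nzchar(cell)) next
      val <- suppressWarnings(as.numeric(cell))
      if (is.na(val)) {
        stop("non-numeric cell at row ", r, ", column ", ci, " ('", cell,
             "') in ", path, call. = FALSE)
      }
      if (ci > length(headers)) {
        stop("row ", r, " has more cells than headers in ", path,
             call. = FALSE)
      }
      recs[[length(recs) + 1L]] <- data.frame(name = headers[[ci]],
                                              time = val * unit)
    }
  }
  events <- if (length(recs)) do.call(rbind, recs) else NULL
  if (is.null(events)) warning("no timestamps found in ", path, call. = FALSE)
  behavior_session(path = path, events = events)
}

#' Derive intervals and switch-labelled events from rules
#'
#' Applies interval rules, in order, to a parsed session:
#' \describe{
#'   \item{`paired_on_off`}{pairs each onset event with the next offset
#'     event; an unclosed onset closes at session end; an offset before
#'     any onset is ignored with a warning.}
#'   \item{`event_offset`}{creates `[t, t + duration_s]` for each
#'     trigger event, clipped at session end; overlapping instances are
#'     merged so intervals of one name never overlap.}
#'   \item{`set_op`}{interval set algebra (`AND` intersection, `OR`
#'     union, `DIFF` difference) over previously derived interval
#'     names.}
#'   \item{`guarded_switch`}{labels each onset event according to the
#'     state active during the lookback window before it: if any
#'     `prior` interval overlaps `[t - lookback_s, t)` the onset is
#'     re-emitted under `label_if`, otherwise under `label_else`. This
#'     distinguishes e.g. house-light onsets arriving from the drug
#'     light from those arriving from darkness (post-injection
#'     time-out).}
#' }
#' Membership follows the closed-open convention `[start, end)`: an
#' event exactly at `end` belongs to the next interval.
#'
#' @param session A [behavior_session()].
#' @param rules Named list of rules (default: the rules in `config`).
#' @param config An `fp_config` supplying rules when `rules` is `NULL`.
#' @return The session with its `intervals` table (and any switch
#'   events) filled in.
#' @export
derive_intervals <- function(session, rules = NULL,
                             config = default_config()) {
  if (is.null(rules)) rules <- config$behavior$intervals
  ev <- session$events
  iv <- session$intervals
  extra_events <- list()
  for (nm in names(rules)) {
    rule <- rules[[nm]]
    if (identical(rule$kind, "paired_on_off")) {
      ons <- sort(ev$time[ev$name == rule$on])
      offs <- sort(ev$time[ev$name == rule$off])
      starts <- numeric(0); ends <- numeric(0)
      open <- NA_real_
      for (t in sort(c(ons, offs))) {
        if (t %in% ons && is.na(open)) {
          open <- t
        } else if (t %in% offs) {
          if (is.na(open)) {
            warning("offset '", rule$off, "' at ", t,
                    " s before any onset; ignored", call. = FALSE)
          } else {
            starts <- c(starts, open); ends <- c(ends, t); open <- NA_real_
          }
        }
      }
      if (!is.na(open)) { starts <- c(starts, open); ends <- c(ends, session$end) }
      keep <- ends > starts
      if (any(keep)) {
        iv <- rbind(iv, data.frame(name = nm, start = starts[keep],
                                   end = ends[keep]))
      }
    } else if (identical(rule$kind, "event_offset")) {
      trig <- sort(ev$time[ev$name == rule$trigger])
      if (length(trig)) {
        segs <- merge_intervals(trig, pmin(trig + rule$duration_s, session$end))
        iv <- rbind(iv, data.frame(name = nm, start = segs$start,
                                   end = segs$end))
      }
    } else if (identical(rule$kind, "set_op")) {
      a <- iv[iv$name == rule$inputs[[1]], c("start", "end")]
      b <- iv[iv$name == rule$inputs[[2]], c("start", "end")]
      segs <- interval_set_op(toupper(rule$op), a, b)
      if (nrow(segs)) iv <- rbind(iv, cbind(name = nm, segs))
    } else if (identical(rule$kind, "guarded_switch")) {
      onsets <- ev$time[ev$name == rule$onset]
      prior <- iv[iv$name == rule$prior, , drop = FALSE]
      lb <- rule$lookback_s %||% 1
      for (t in onsets) {
        active <- nrow(prior) > 0 &&
          any(prior$start < t & prior$end > t - lb)
        lbl <- if (active) rule$label_if else rule$label_else
        extra_events[[length(extra_events) + 1L]] <-
          data.frame(name = lbl, time = t)
      }
    } else {
      stop("unknown interval rule kind: ", rule$kind, call. = FALSE)
    }
  }
  if (length(extra_events)) ev <- rbind(ev, do.call(rbind, extra_events))
  rownames(iv) <- NULL
  behavior_session(path = session$path, events = ev, intervals = iv,
                   end = max(session$end, iv$end, ev$time, 0),
                   unmatched = session$unmatched)
}

# union of possibly-overlapping [start, end] pairs (inputs sorted by start)
merge_intervals <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

interval_set_op <- function(op, a, b) {
  empty <- data.frame(start = numeric(0), end = numeric(0))
  norm <- function(x) if (nrow(x)) merge_intervals(x$start, x$end) else empty
  a <- norm(a); b <- norm(b)
  if (op == "OR") {
    both <- rbind(a, b)
    return(if (nrow(both)) merge_intervals(both$start, both$end) else empty)
  }
  if (op == "AND") {
    out <- empty
    for (i in seq_len(nrow(a))) {
      s <- pmax(a$start[i], b$start); e <- pmin(a$end[i], b$end)
      keep <- e > s
      if (any(keep)) out <- rbind(out, data.frame(start = s[keep], end = e[keep]))
    }
    return(norm(out))
  }
  if (op == "DIFF") {
    out <- empty
    for (i in seq_len(nrow(a))) {
      segs <- data.frame(start = a$start[i], end = a$end[i])
      for (j in seq_len(nrow(b))) {
        nxt <- empty
        for (k in seq_len(nrow(segs))) {
          s <- segs$start[k]; e <- segs$end[k]
          bs <- b$start[j]; be <- b$end[j]
          if (be <= s || bs >= e) {
            nxt <- rbind(nxt, data.frame(start = s, end = e))
          } else {
            if (bs > s) nxt <- rbind(nxt, data.frame(start = s, end = bs))
            if (be < e) nxt <- rbind(nxt, data.frame(start = be, end = e))
          }
        }
        segs <- nxt
      }
      out <- rbind(out, segs)
    }
    return(norm(out))
  }
  stop("unknown set operation: ", op, call. = FALSE)
}

# closed-open membership test
in_intervals <- function(times, intervals) {
  if (!nrow(intervals)) return(rep(FALSE, length(times)))
  vapply(times, function(t) any(t >= intervals$start & t < intervals$end),
         logical(1))
}

#' Select event times for perievent analysis
#'
#' Filters an event's occurrence times, optionally to the union of named
#' intervals (closed-open membership), and applies a selector:
#' \describe{
#'   \item{`all`}{every filtered occurrence.}
#'   \item{`first_in_interval`}{at most one time per interval instance
#'     of `within` -- the earliest occurrence inside it.}
#'   \item{`ordinal_in_series`}{partitions consecutive occurrences
#'     between reinforcements into fixed-ratio series of `series_size`
#'     and returns the `k`-th response of each complete series.
#'     Occurrences during `exclude` intervals (default `TIMEOUT`, when
#'     derived) are recorded but carry no consequence, so they do not
#'     count towards the series.}
#' }
#'
#' @param session A [behavior_session()] (with intervals derived, if
#'   `within`/`exclude` are used).
#' @param event Event name.
#' @param within Optional interval name restricting the selection.
#' @param selector One of `"all"`, `"first_in_interval"`,
#'   `"ordinal_in_series"`.
#' @param k,series_size Position within, and size of, the fixed-ratio
#'   series (selector `ordinal_in_series`); `k` must not exceed
#'   `series_size`.
#' @param reinforcer Event name marking reinforcement (series boundary).
#' @param exclude Interval name whose occupants do not count towards
#'   series (set `NULL` to disable).
#' @return Numeric vector of selected times (seconds), sorted.
#' @export
select_events <- function(session, event, within = NULL,
                          selector = c("all", "first_in_interval",
                                       "ordinal_in_series"),
                          k = 1L, series_size = 5L,
                          reinforcer = "inj1", exclude = "TIMEOUT") {
  selector <- match.arg(selector)
  times <- sort(session$events$time[session$events$name == event])
  win_iv <- NULL
  if (!is.null(within)) {
    win_iv <- session$intervals[session$intervals$name == within, , drop = FALSE]
    if (!nrow(win_iv)) {
      stop("no intervals named '", within, "' in session", call. = FALSE)
    }
    times <- times[in_intervals(times, win_iv)]
  }
  if (selector == "all") return(times)
  if (selector == "first_in_interval") {
    if (is.null(win_iv)) {
      stop("selector 'first_in_interval' requires `within`", call. = FALSE)
    }
    out <- vapply(seq_len(nrow(win_iv)), function(i) {
      inside <- times[times >= win_iv$start[i] & times < win_iv$end[i]]
      if (length(inside)) min(inside) else NA_real_
    }, numeric(1))
    return(sort(out[!is.na(out)]))
  }
  # ordinal_in_series
  if (k > series_size) {
    stop("k (", k, ") exceeds series_size (", series_size, ")", call. = FALSE)
  }
  if (!is.null(exclude)) {
    ex_iv <- session$intervals[session$intervals$name == exclude, , drop = FALSE]
    if (nrow(ex_iv)) times <- times[!in_intervals(times, ex_iv)]
  }
  reinf <- sort(session$events$time[session$events$name == reinforcer])
  bounds <- c(-Inf, reinf, Inf)
  out <- numeric(0)
  for (i in seq_len(length(bounds) - 1L)) {
    seg <- times[times > bounds[i] & times <= bounds[i + 1L]]
    n_full <- length(seg) %/% series_size
    if (n_full > 0) {
      out <- c(out, seg[(seq_len(n_full) - 1L) * series_size + k])
    }
  }
  sort(out)
}

#' Write the canonical event table of a session
#'
#' @param session A [behavior_session()].
#' @param path Output CSV path (columns `name`, `time_s`; times at
#'   full precision so re-reading is lossless).
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(session, path) {
  df <- data.frame(name = session$events$name,
                   time_s = sprintf("%.17g", session$events$time))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
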