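#' Discover behavior/fiber session pairs under a root folder
#'
#' Each immediate subfolder of `root` is expected to hold exactly one
#' behavioral log and one photometry file ("one session per folder").
#' Behavioral candidates are `.dat` files whose content matches the
#' requested dialect (tab-separated integer codes for `"imetronic"`,
#' comma-separated named headers for `"generic"`); photometry
#' candidates are `.csv` files with the configured channel columns, or
#' `.h5`/`.hdf5`/`.doric` containers. Subfolders with zero or several
#' candidates of either kind are skipped with a warning.
#'
#' @param root Directory containing one subfolder per session.
#' @param filetype Behavioral dialect: `"imetronic"` or `"generic"`.
#' @param config An `fp_config` (used to sniff fiber CSV columns).
#' @return `data.frame` of class `session_pairs` with columns `folder`,
#'   `behavior`, `fiber`, `offset` (fiber clock minus behavior clock,
#'   seconds; default 0) and a `filetype` attribute.
#' @export
discover_sessions <- function(root, filetype = c("imetronic", "generic"),
                              config = default_config()) {
  filetype <- match.arg(filetype)
  if (!dir.exists(root)) stop("root folder not found: ", root, call. = FALSE)
  subs <- list.dirs(root, recursive = FALSE)
  rows <- list()
  for (d in subs) {
    files <- list.files(d, full.names = TRUE)
    beh <- files[grepl("\\.dat$", files, ignore.case = TRUE)]
    beh <- beh[vapply(beh, function(f) sniff_dialect(f) == filetype, logical(1))]
    fib <- files[grepl("\\.(csv|h5|hdf5|doric)$", files, ignore.case = TRUE)]
    fib <- fib[vapply(fib, function(f) is_fiber_file(f, config), logical(1))]
    if (length(beh) != 1 || length(fib) != 1) {
      warning("skipping ", d, ": found ", length(beh), " behavior and ",
              length(fib), " fiber file(s)", call. = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(folder = d, behavior = beh,
                                            fiber = fib, offset = 0)
  }
  if (!length(rows)) {
    stop("no valid session subfolders under ", root, call. = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, filetype = filetype, class = c("session_pairs", "data.frame"))
}

# classify a .dat behavioral file by content
sniff_dialect <- function(path) {
  first <- tryCatch(readLines(path, n = 1L, warn = FALSE),
                    error = function(e) "")
  if (!length(first)) return("unknown")
  if (grepl("\t", first)) {
    toks <- strsplit(first, "\t", fixed = TRUE)[[1]]
    if (all(grepl("^-?[0-9.]+$", toks[nzchar(toks)]))) return("imetronic")
  }
  if (grepl(",", first)) {
    toks <- trimws(strsplit(first, ",", fixed = TRUE)[[1]])
    if (any(grepl("[A-Za-z]", toks))) return("generic")
  }
  "unknown"
}

is_fiber_file <- function(path, config) {
  if (grepl("\\.(h5|hdf5|doric)$", path, ignore.case = TRUE)) return(TRUE)
  first <- tryCatch(readLines(path, n = 1L, warn = FALSE),
                    error = function(e) "")
  if (!length(first)) return(FALSE)
  cols <- unlist(config$fiber$columns)
  toks <- trimws(strsplit(first, ",", fixed = TRUE)[[1]])
  all(cols %in% toks)
}

read_fiber_any <- function(path, config) {
  if (grepl("\\.(h5|hdf5|doric)$", path, ignore.case = TRUE)) {
    read_fiber_hdf5(path, config)
  } else {
    read_fiber_csv(path, config)
  }
}

#' Describe a batch perievent request
#'
#' @param event Event name (e.g. `"hled_on"`, `"np1"`).
#' @param within Optional interval name restricting events (e.g.
#'   `"DRUG"`).
#' @param window `c(pre_s, post_s)` perievent window, both positive.
#' @param norm Normalization tag: `"F"` (dF/F) or `"Z"` (Z-difference).
#' @param selector,k,series_size Passed to [select_events()].
#' @return A list of class `batch_request`.
#' @export
batch_request <- function(event, within = NULL, window = c(5, 5),
                          norm = c("F", "Z"), selector = "all",
                          k = 1L, series_size = 5L) {
  norm <- match.arg(norm)
  stopifnot(length(window) == 2, all(window > 0))
  structure(list(event = event, within = within, window = window,
                 norm = norm, selector = selector, k = k,
                 series_size = series_size),
            class = "batch_request")
}

#' Batched perievent analysis across sessions
#'
#' For every behavior/fiber pair: parses the behavioral log, derives
#' intervals, selects the requested event times, shifts them by the
#' pair's clock offset onto the fiber clock, locates the contiguous
#' recording containing each event's full perievent window, normalizes
#' that recording (`"F"` or `"Z"`), extracts and renormalizes the
#' epoch, and summarizes it. Events whose window lies in no recording,
#' or whose baseline is degenerate, go to the exclusion report -- every
#' selected event is accounted for exactly once:
#' `nrow(summary) + nrow(exclusions) == number of selected events`.
#'
#' @param pairs A [discover_sessions()] result, or a `data.frame` with
#'   columns `behavior`, `fiber`, `offset` (and a `filetype`
#'   attribute, defaulting to `"imetronic"`).
#' @param request A [batch_request()].
#' @param config An `fp_config`.
#' @return An object of class `perievent_result`: list with `epochs`
#'   (each epoch annotated with its session), `summary` (one row per
#'   epoch, Table-style schema), `exclusions`, `interp` (common grid,
#'   per-epoch interpolated signals, mean trace), and `request`.
#' @export
analyze <- function(pairs, request, config = default_config()) {
  filetype <- attr(pairs, "filetype") %||% "imetronic"
  parse_fun <- if (filetype == "generic") parse_generic_csv else parse_imetronic
  ppars <- peak_params(config = config)
  epochs <- list()
  summaries <- list()
  exclusions <- list()
  n_selected <- 0L
  per_pair_counts <- integer(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    beh <- derive_intervals(parse_fun(pairs$behavior[i], config),
                            config = config)
    times <- select_events(beh, request$event, within = request$within,
                           selector = request$selector, k = request$k,
                           series_size = request$series_size)
    per_pair_counts[i] <- length(times)
    if (!length(times)) next
    n_selected <- n_selected + length(times)
    raw <- read_fiber_any(pairs$fiber[i], config)
    recs <- split_recordings(raw, config = config)
    norm_cache <- list()
    for (bt in times) {
      ft <- bt + pairs$offset[i]
      ri <- which(vapply(recs, function(r) {
        ft - request$window[1] >= r$time[1] &&
          ft + request$window[2] <= r$time[length(r$time)]
      }, logical(1)))
      if (!length(ri)) {
        exclusions[[length(exclusions) + 1L]] <- data.frame(
          behavior_file = pairs$behavior[i], event_time = bt,
          fiber_file = pairs$fiber[i],
          reason = "no recording contains the perievent window")
        next
      }
      ri <- ri[1]
      key <- as.character(ri)
      if (is.null(norm_cache[[key]])) {
        norm_cache[[key]] <- normalize_recording(recs[[ri]], request$norm)
      }
      ns <- norm_cache[[key]]
      ep <- extract_epoch(ns, ft, request$window)
      if (inherits(ep, "epoch_rejection")) {
        exclusions[[length(exclusions) + 1L]] <- data.frame(
          behavior_file = pairs$behavior[i], event_time = bt,
          fiber_file = pairs$fiber[i], reason = ep$reason)
        next
      }
      z <- zscore_epoch(ep)
      rz <- robust_zscore_epoch(ep)
      if (inherits(z, "epoch_rejection") || inherits(rz, "epoch_rejection")) {
        bad <- if (inherits(z, "epoch_rejection")) z else rz
        exclusions[[length(exclusions) + 1L]] <- data.frame(
          behavior_file = pairs$behavior[i], event_time = bt,
          fiber_file = pairs$fiber[i], reason = bad$reason)
        next
      }
      ep$zscores <- z
      ep$rob_zscores <- rz
      ep$behavior_file <- pairs$behavior[i]
      ep$fiber_file <- pairs$fiber[i]
      ep$behavior_event_time <- bt
      ep$rec_number <- recs[[ri]]$index
      ep$sampling_rate <- recs[[ri]]$sampling_rate
      # raw channel slices for the full-data container
      ep$raw_control <- recs[[ri]]$isosbestic[ep$sample_idx]
      ep$raw_signal <- recs[[ri]]$signal[ep$sample_idx]
      epochs[[length(epochs) + 1L]] <- ep
      summaries[[length(summaries) + 1L]] <- cbind(
        data.frame(behavior_file = pairs$behavior[i], event_time = bt,
                   fiber_file = pairs$fiber[i],
                   normalization = request$norm),
        summarize_epoch(ep, ppars))
    }
  }
  if (n_selected == 0L) {
    stop("no '", request$event, "' events selected in any session (per-pair: ",
         paste(per_pair_counts, collapse = ", "), ")", call. = FALSE)
  }
  exclusions <- if (length(exclusions)) {
    do.call(rbind, exclusions)
  } else {
    data.frame(behavior_file = character(0), event_time = numeric(0),
               fiber_file = character(0), reason = character(0))
  }
  interp <- if (length(epochs)) interpolate_epochs(epochs) else NULL
  structure(list(
    epochs = epochs,
    summary = if (length(summaries)) do.call(rbind, summaries) else NULL,
    exclusions = exclusions,
    interp = interp,
    request = request,
    n_selected = n_selected),
    class = "perievent_result")
}

#' @export
print.perievent_result <- function(x, ...) {
  cat(sprintf("<perievent_result> '%s'%s: %d epochs, %d excluded\n",
              x$request$event,
              if (is.null(x$request$within)) "" else
                paste0(" within ", x$request$within),
              length(x$epochs), nrow(x$exclusions)))
  invisible(x)
}

#' Per-epoch summary table of a batch result
#'
#' One row per accepted epoch: source files, event time (behavior
#' clock), normalization tag, pre/post AUC, pre/post averages of the
#' trace, its baseline Z and robust-Z variants, and pre/post peak
#' frequency and amplitude.
#'
#' @param res A `perievent_result`.
#' @return `data.frame`.
#' @export
result_table <- function(res) {
  if (is.null(res$summary)) stop("empty perievent result", call. = FALSE)
  res$summary
}

#' Per-epoch full-data container
#'
#' For each accepted epoch, the raw channel slices, recording index and
#' sampling rate, the processed trace, and its Z / robust-Z
#' renormalizations -- everything needed to re-derive the summary row.
#'
#' @param res A `perievent_result`.
#' @return List with one entry per epoch.
#' @export
full_table <- function(res) {
  lapply(res$epochs, function(e) {
    list(behavior_file = e$behavior_file,
         fiber_file = e$fiber_file,
         event_time = e$behavior_event_time,
         rec_number = e$rec_number,
         sampling_rate = e$sampling_rate,
         raw_control = e$raw_control,
         raw_signal = e$raw_signal,
         rel_time = e$rel_time,
         processed = e$values,
         zscores = e$zscores,
         rob_zscores = e$rob_zscores)
  })
}

#' Plot individual and mean perievent traces
#'
#' Light-colored individual interpolated epochs, the mean trace in
#' heavy black, and a vertical marker at the event.
#'
#' @param res A `perievent_result` with at least one epoch.
#' @param out Optional PNG path; when given, the figure is written
#'   there, otherwise it is drawn on the current device.
#' @param ... Passed to [graphics::matplot()].
#' @return The mean trace, invisibly.
#' @export
plot_perievent <- function(res, out = NULL, ...) {
  if (is.null(res$interp) || !length(res$epochs)) {
    stop("empty perievent result; nothing to plot", call. = FALSE)
  }
  if (!is.null(out)) {
    grDevices::png(out, width = 900, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  g <- res$interp$grid
  graphics::matplot(g, res$interp$signals, type = "l", lty = 1,
                    col = grDevices::adjustcolor(seq_len(ncol(res$interp$signals)) + 1,
                                                 alpha.f = 0.5),
                    xlab = "time from event (s)",
                    ylab = sprintf("signal (%s)", res$request$norm), ...)
  graphics::lines(g, res$interp$mean, col = "black", lwd = 3)
  graphics::abline(v = 0, lty = 2)
  invisible(res$interp$mean)
}

#' Per-session behavioral summary across files
#'
#' Parses each file, derives intervals, and tabulates -- one row per
#' file -- the count of every configured event and the total duration
#' of every derived interval name. Useful for comparing behavior
#' between subjects, groups, or sessions before any photometry is
#' touched.
#'
#' @param files Character vector of behavioral file paths.
#' @param filetype `"imetronic"` or `"generic"`.
#' @param config An `fp_config`.
#' @return `data.frame`, one row per file; event columns are counts,
#'   interval columns (`dur_<NAME>_s`) are total durations in seconds.
#' @export
multibehavior_summary <- function(files, filetype = c("imetronic", "generic"),
                                  config = default_config()) {
  filetype <- match.arg(filetype)
  parse_fun <- if (filetype == "generic") parse_generic_csv else parse_imetronic
  ev_names <- names(config$behavior$events)
  iv_names <- setdiff(names(config$behavior$intervals),
                      names(which(vapply(config$behavior$intervals,
                                         function(r) r$kind == "guarded_switch",
                                         logical(1)))))
  rows <- lapply(files, function(f) {
    s <- derive_intervals(parse_fun(f, config), config = config)
    counts <- vapply(ev_names, function(nm) sum(s$events$name == nm), integer(1))
    durs <- vapply(iv_names, function(nm) {
      sel <- s$intervals$name == nm
      sum(s$intervals$end[sel] - s$intervals$start[sel])
    }, numeric(1))
    cbind(data.frame(file = f),
          as.data.frame(as.list(counts)),
          stats::setNames(as.data.frame(as.list(durs)),
                          paste0("dur_", iv_names, "_s")))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a perievent result to CSV files
#'
#' Writes `summary.csv` (the [result_table()]), `interpolated.csv`
#' (common grid plus one column per epoch and the mean trace) and
#' `exclusions.csv` into `dir`. Numeric values are printed at 17
#' significant digits, so [import_perievent()] recovers them
#' bit-identically.
#'
#' @param res A `perievent_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_perievent <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(df) {
    df[] <- lapply(df, function(col) {
      if (is.numeric(col)) sprintf("%.17g", col) else col
    })
    df
  }
  utils::write.csv(fmt(result_table(res)), file.path(dir, "summary.csv"),
                   row.names = FALSE)
  sig <- as.data.frame(res$interp$signals)
  names(sig) <- paste0("epoch_", seq_along(sig))
  interp <- cbind(data.frame(grid = res$interp$grid), sig,
                  data.frame(mean = res$interp$mean))
  utils::write.csv(fmt(interp), file.path(dir, "interpolated.csv"),
                   row.names = FALSE)
  utils::write.csv(res$exclusions, file.path(dir, "exclusions.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Re-import an exported perievent result
#'
#' @param dir Directory written by [export_perievent()].
#' @return List with `summary`, `interp` (grid, signals, mean) and
#'   `exclusions`.
#' @export
import_perievent <- function(dir) {
  summary <- utils::read.csv(file.path(dir, "summary.csv"))
  # whole-valued or all-missing columns come back integer/logical; restore
  # the double storage the exporter wrote
  meta <- c("behavior_file", "fiber_file", "normalization", "reason")
  for (cl in setdiff(names(summary), meta)) {
    summary[[cl]] <- as.numeric(summary[[cl]])
  }
  interp_df <- utils::read.csv(file.path(dir, "interpolated.csv"))
  ep_cols <- grep("^epoch_", names(interp_df))
  signals <- as.matrix(interp_df[, ep_cols, drop = FALSE])
  storage.mode(signals) <- "double"
  exclusions <- utils::read.csv(file.path(dir, "exclusions.csv"))
  list(summary = summary,
       interp = list(grid = as.numeric(interp_df$grid),
                     signals = signals,
                     mean = as.numeric(interp_df$mean)),
       exclusions = exclusions)
}
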