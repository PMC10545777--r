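test_that("session discovery pairs one behavior and one fiber file per folder", {
  st <- shared_study()
  pairs <- discover_sessions(st$root, "imetronic")
  expect_equal(nrow(pairs), 3)
  expect_true(all(file.exists(pairs$behavior)))
  expect_true(all(file.exists(pairs$fiber)))
  expect_true(all(grepl("imetronic", pairs$behavior)))
  # the generic dialect resolves to the other writer's file
  pairs_g <- discover_sessions(st$root, "generic")
  expect_true(all(grepl("generic", pairs_g$behavior)))
})

test_that("ambiguous or empty folders are skipped / fatal", {
  root <- tempfile("amb")
  d <- file.path(root, "s1"); dir.create(d, recursive = TRUE)
  sim <- simulate_behavior(session_template(), d, seed = 6)
  ph <- simulate_photometry(sim$truth, photometry_template(), d, seed = 6)
  file.copy(ph$files[["csv"]], file.path(d, "fiber_copy.csv"))  # 2 fiber files
  expect_warning(expect_error(discover_sessions(root, "imetronic"),
                              "no valid session"),
                 "skipping")

  empty <- tempfile("empty"); dir.create(empty)
  expect_error(discover_sessions(empty, "imetronic"), "no valid session")
})

test_that("batch perievent analysis recovers the scheduled events", {
  st <- shared_study()
  pairs <- discover_sessions(st$root, "imetronic")
  res <- analyze(pairs, batch_request("hled_on", window = c(5, 5), norm = "F"))
  # 3 sessions x 2 house-light onsets, all inside recording blocks
  expect_length(res$epochs, 6)
  expect_equal(nrow(res$exclusions), 0)
  tab <- result_table(res)
  expect_equal(nrow(tab), 6)
  expect_equal(sort(unique(tab$event_time)), c(2400, 5700))
  expect_equal(unique(tab$normalization), "F")
  expect_named(tab, c("behavior_file", "event_time", "fiber_file",
                      "normalization", "preAUC", "postAUC", "preAVG_dF",
                      "postAVG_dF", "preAVG_Z", "PostAVG_Z", "preAVG_RZ",
                      "PostAVG_RZ", "pre_peak_freq", "post_peak_freq",
                      "pre_peak_amp", "post_peak_amp"))
})

test_that("every selected event is accounted for exactly once", {
  st <- shared_study()
  pairs <- discover_sessions(st$root, "imetronic")
  res <- analyze(pairs, batch_request("np1", within = "DRUG",
                                      window = c(1, 1), norm = "F"))
  expect_equal(length(res$epochs) + nrow(res$exclusions), res$n_selected)
  # only in-interval nose-pokes were considered
  for (i in seq_len(nrow(pairs))) {
    s <- derive_intervals(parse_imetronic(pairs$behavior[i]))
    drug <- s$intervals[s$intervals$name == "DRUG", ]
    sel <- c(res$exclusions$event_time[res$exclusions$behavior_file ==
                                         pairs$behavior[i]],
             vapply(res$epochs[vapply(res$epochs, function(e)
               e$behavior_file == pairs$behavior[i], logical(1))],
               function(e) e$behavior_event_time, numeric(1)))
    expect_true(all(vapply(sel, function(t)
      any(t >= drug$start & t < drug$end), logical(1))))
  }
  # out-of-recording events are excluded with the documented reason
  expect_true(all(res$exclusions$reason ==
                    "no recording contains the perievent window"))
})

test_that("a window crossing the recording edge lands in the exclusion report", {
  st <- shared_study()
  pairs <- discover_sessions(st$root, "imetronic")[1, ]
  # default blocks start 30 s before the house-light onsets, so a 35 s
  # pre-window cannot fit
  res <- analyze(pairs, batch_request("hled_on", window = c(35, 5)))
  expect_length(res$epochs, 0)
  expect_equal(nrow(res$exclusions), 2)
  expect_equal(length(res$epochs) + nrow(res$exclusions), res$n_selected)
})

test_that("an event absent from all sessions is fatal with per-pair counts", {
  st <- shared_study()
  pairs <- discover_sessions(st$root, "imetronic")
  cfg <- load_config()
  cfg$behavior$events$ghost <- list(match = list(`2` = 99L, `3` = 99L),
                                    time_col = 1L)
  expect_error(suppressWarnings(analyze(pairs, batch_request("ghost"), cfg)),
               "per-pair: 0, 0, 0")
})

test_that("batch analysis equals the concatenation of per-pair analyses", {
  st <- shared_study()
  pairs <- discover_sessions(st$root, "imetronic")
  req <- batch_request("hled_on", window = c(5, 5))
  whole <- result_table(analyze(pairs, req))
  parts <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i)
    result_table(analyze(pairs[i, , drop = FALSE], req))))
  rownames(whole) <- rownames(parts) <- NULL
  expect_equal(whole, parts)
})

test_that("the full-data container carries raw slices and recording metadata", {
  st <- shared_study()
  pairs <- discover_sessions(st$root, "imetronic")[1, ]
  res <- analyze(pairs, batch_request("hled_on", window = c(5, 5)))
  fd <- full_table(res)
  expect_length(fd, 2)
  raw <- read_fiber_csv(pairs$fiber[1])
  recs <- split_recordings(raw)
  for (e in fd) {
    expect_true(e$rec_number %in% c(1L, 2L))
    expect_equal(e$sampling_rate, recs[[e$rec_number]]$sampling_rate)
    expect_equal(length(e$raw_control), length(e$processed))
    expect_equal(length(e$rob_zscores), length(e$processed))
    # raw slices really are slices of the parent recording
    expect_true(all(e$raw_signal %in% recs[[e$rec_number]]$signal))
  }
  # the 2400 s epoch sits in recording 1, the 5700 s epoch in recording 2
  expect_equal(vapply(fd, `[[`, integer(1), "rec_number"), c(1L, 2L))
})

test_that("perievent plotting writes a figure matching the mean trace", {
  st <- shared_study()
  pairs <- discover_sessions(st$root, "imetronic")
  res <- analyze(pairs, batch_request("hled_on", window = c(5, 5)))
  f <- tempfile(fileext = ".png")
  m <- plot_perievent(res, out = f)
  expect_true(file.exists(f))
  expect_gt(file.size(f), 1000)
  expect_equal(m, res$interp$mean)
  expect_error(plot_perievent(structure(list(interp = NULL, epochs = list()),
                                        class = "perievent_result")),
               "empty")
})

test_that("exported results re-import bit-identically", {
  st <- shared_study()
  pairs <- discover_sessions(st$root, "imetronic")
  res <- analyze(pairs, batch_request("hled_on", window = c(5, 5)))
  d <- tempfile("export")
  export_perievent(res, d)
  back <- import_perievent(d)
  expect_identical(back$interp$grid, res$interp$grid)
  expect_identical(unname(back$interp$signals), unname(res$interp$signals))
  expect_identical(back$interp$mean, res$interp$mean)
  num <- vapply(result_table(res), is.numeric, logical(1))
  for (cl in names(which(num))) {
    expect_identical(back$summary[[cl]], result_table(res)[[cl]])
  }
  expect_equal(nrow(back$exclusions), nrow(res$exclusions))
})

test_that("multi-file behavioral summaries match generator truth", {
  st <- shared_study()
  files <- vapply(st$sessions, function(s)
    s$behavior$files[["imetronic"]], character(1))
  tab <- multibehavior_summary(files)
  expect_equal(nrow(tab), 3)
  for (i in 1:3) {
    truth <- st$sessions[[i]]$behavior$truth$events
    for (nm in c("np1", "np2", "inj1", "hled_on")) {
      expect_equal(tab[[nm]][i], sum(truth$name == nm))
    }
    expect_equal(tab$lk1[i], 0)   # no licks in the cocaine protocol
    expect_gte(tab$np1[i], 5 * tab$inj1[i])
    expect_equal(tab$dur_DRUG_s[i], 3 * 40 * 60)
  }
})
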