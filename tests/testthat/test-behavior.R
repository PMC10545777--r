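# writers for hand-built fixtures -------------------------------------------

write_imetronic_fixture <- function(rows) {
  f <- tempfile(fileext = ".dat")
  writeLines(vapply(rows, paste, character(1), collapse = "\t"), f)
  f
}

write_generic_fixture <- function(lines) {
  f <- tempfile(fileext = ".dat")
  writeLines(lines, f)
  f
}

# integer-coded parser -------------------------------------------------------

test_that("integer-coded rows map to named events with ms-to-s conversion", {
  f <- write_imetronic_fixture(list(c(1200000, 1, 1)))  # np1 at 1 200 000 ms
  s <- parse_imetronic(f)
  expect_equal(s$events$name, "np1")
  expect_equal(s$events$time, 1200)
})

test_that("a file with only unmatched codes yields an empty session", {
  f <- write_imetronic_fixture(list(c(100, 99, 99), c(200, 98, 98)))
  expect_warning(s <- parse_imetronic(f), "no configured event")
  expect_equal(nrow(s$events), 0)
  expect_equal(s$unmatched, 2L)
})

test_that("a mixed log parses the matching rows and counts the rest", {
  rows <- c(lapply(c(1000, 2000, 3500, 7000, 9000),
                   function(t) c(t, 1, 1)),      # 5 np1
            list(c(10000, 6, 1)),                # 1 injection
            list(c(500, 77, 77)))                # junk
  f <- write_imetronic_fixture(rows)
  s <- suppressMessages(parse_imetronic(f))
  expect_equal(nrow(s$events), 6)
  expect_equal(sum(s$events$name == "np1"), 5)
  expect_equal(s$events$time[s$events$name == "inj1"], 10)
  expect_equal(s$unmatched, 1L)
})

test_that("synthetic writer to parser round trip is exact", {
  st <- shared_study()
  for (sess in st$sessions) {
    truth <- sess$behavior$truth$events
    im <- parse_imetronic(sess$behavior$files[["imetronic"]])
    ge <- parse_generic_csv(sess$behavior$files[["generic"]])
    for (s in list(im, ge)) {
      expect_equal(nrow(s$events), nrow(truth))
      got <- s$events[order(s$events$name, s$events$time), ]
      want <- truth[order(truth$name, truth$time), ]
      expect_equal(got$name, want$name)
      expect_equal(got$time, want$time, tolerance = 1e-9)
    }
  }
})

# generic column-per-event parser --------------------------------------------

test_that("a toy 3-column x 2-row file yields 6 named events", {
  f <- write_generic_fixture(c("Dim1_on,Dim1_off,Dim2",
                               "1.5,2.5,3.5",
                               "10,20,30"))
  s <- parse_generic_csv(f)
  expect_equal(nrow(s$events), 6)
  expect_setequal(unique(s$events$name), c("Dim1_on", "Dim1_off", "Dim2"))
  expect_equal(sort(s$events$time[s$events$name == "Dim2"]), c(3.5, 30))
})

test_that("single column single timestamp works; ragged columns do not pad", {
  s1 <- parse_generic_csv(write_generic_fixture(c("lick", "4.25")))
  expect_equal(s1$events$time, 4.25)

  f <- write_generic_fixture(c("a,b,c", "1,4,6", "2,,7", "3,,"))
  s <- parse_generic_csv(f)
  expect_equal(nrow(s$events), 6)
  expect_equal(sum(s$events$name == "a"), 3)
  expect_equal(sum(s$events$name == "b"), 1)
  expect_equal(sum(s$events$name == "c"), 2)
})

test_that("duplicate headers and non-numeric cells are fatal", {
  expect_error(parse_generic_csv(write_generic_fixture(c("a,a", "1,2"))),
               "duplicate")
  err <- expect_error(
    parse_generic_csv(write_generic_fixture(c("a,b", "1,oops"))),
    "non-numeric cell")
  expect_match(conditionMessage(err), "row 2")
  expect_match(conditionMessage(err), "column 2")
})

# interval derivation ---------------------------------------------------------

test_that("paired on/off events become intervals; unclosed pairs close at end", {
  s <- behavior_session(events = data.frame(
    name = c("hled_on", "hled_off", "hled_on", "np1"),
    time = c(2400, 3300, 5700, 6000)))
  s <- derive_intervals(s, rules = list(
    HLED_ON = list(kind = "paired_on_off", on = "hled_on", off = "hled_off")))
  iv <- s$intervals[s$intervals$name == "HLED_ON", ]
  expect_equal(iv$start, c(2400, 5700))
  expect_equal(iv$end, c(3300, 6000))  # second closes at session end
})

test_that("an offset before any onset is ignored with a warning", {
  s <- behavior_session(events = data.frame(
    name = c("hled_off", "hled_on", "hled_off"), time = c(10, 100, 200)))
  expect_warning(
    s <- derive_intervals(s, rules = list(
      HLED_ON = list(kind = "paired_on_off", on = "hled_on", off = "hled_off"))),
    "before any onset")
  iv <- s$intervals
  expect_equal(nrow(iv), 1)
  expect_equal(c(iv$start, iv$end), c(100, 200))
})

test_that("event_offset builds the 40 s post-injection time-out", {
  s <- behavior_session(events = data.frame(name = "inj1", time = 100),
                        end = 1000)
  s <- derive_intervals(s, rules = list(
    TIMEOUT = list(kind = "event_offset", trigger = "inj1", duration_s = 40)))
  iv <- s$intervals
  expect_equal(c(iv$start, iv$end), c(100, 140))
})

test_that("set operations combine derived intervals", {
  s <- behavior_session(events = data.frame(
    name = c("led2_on", "led2_off", "inj1"),
    time = c(0, 100, 50)), end = 100)
  s <- derive_intervals(s, rules = list(
    DRUG = list(kind = "paired_on_off", on = "led2_on", off = "led2_off"),
    TIMEOUT = list(kind = "event_offset", trigger = "inj1", duration_s = 40),
    DRUG_FREEPOKE = list(kind = "set_op", op = "DIFF",
                         inputs = c("DRUG", "TIMEOUT")),
    DRUG_TO = list(kind = "set_op", op = "AND",
                   inputs = c("DRUG", "TIMEOUT")),
    EITHER = list(kind = "set_op", op = "OR",
                  inputs = c("DRUG_FREEPOKE", "DRUG_TO"))))
  iv <- s$intervals
  expect_equal(iv[iv$name == "DRUG_FREEPOKE", ]$start, c(0, 90))
  expect_equal(iv[iv$name == "DRUG_FREEPOKE", ]$end, c(50, 100))
  expect_equal(iv[iv$name == "DRUG_TO", ]$start, 50)
  expect_equal(iv[iv$name == "DRUG_TO", ]$end, 90)
  # union of the partition reassembles the drug period
  expect_equal(iv[iv$name == "EITHER", c("start", "end")],
               iv[iv$name == "DRUG", c("start", "end")],
               ignore_attr = TRUE)
})

test_that("guarded switch labels onsets by the preceding light state", {
  rules <- list(
    DRUG = list(kind = "paired_on_off", on = "led2_on", off = "led2_off"),
    hsw = list(kind = "guarded_switch", onset = "hled_on", prior = "DRUG",
               lookback_s = 1, label_if = "hled_on_from_led2",
               label_else = "hled_on_from_dark"))
  # LED2 lit through the switch
  s1 <- behavior_session(events = data.frame(
    name = c("led2_on", "led2_off", "hled_on"), time = c(0, 2400, 2400)))
  s1 <- derive_intervals(s1, rules = rules)
  expect_true("hled_on_from_led2" %in% s1$events$name)
  expect_false("hled_on_from_dark" %in% s1$events$name)
  # darkness (time-out) before the switch
  s2 <- behavior_session(events = data.frame(
    name = c("led2_on", "led2_off", "hled_on"), time = c(0, 2350, 2400)))
  s2 <- derive_intervals(s2, rules = rules)
  expect_true("hled_on_from_dark" %in% s2$events$name)
  expect_false("hled_on_from_led2" %in% s2$events$name)
})

test_that("derived same-name intervals never overlap (synthetic sessions)", {
  for (i in 1:3) {
    s <- shared_session(i)
    for (nm in unique(s$intervals$name)) {
      iv <- s$intervals[s$intervals$name == nm, ]
      iv <- iv[order(iv$start), ]
      expect_true(all(iv$start < iv$end))
      if (nrow(iv) > 1) expect_true(all(iv$start[-1] >= iv$end[-nrow(iv)]))
    }
  }
})

test_that("total time-out duration is 40 s per injection", {
  s <- shared_session(1)
  iv <- s$intervals[s$intervals$name == "TIMEOUT", ]
  n_inj <- sum(s$events$name == "inj1")
  last_inj <- max(s$events$time[s$events$name == "inj1"])
  if (last_inj + 40 <= s$end) {
    expect_equal(sum(iv$end - iv$start), 40 * n_inj)
  } else {
    expect_equal(sum(iv$end - iv$start), 40 * (n_inj - 1) + (s$end - last_inj))
  }
})

test_that("the canonical event-table writer re-reads losslessly", {
  s <- shared_session(1)
  f <- tempfile(fileext = ".csv")
  write_events_csv(s, f)
  back <- utils::read.csv(f)
  expect_equal(back$name, s$events$name)
  expect_identical(back$time_s, s$events$time)
})

# event selection -------------------------------------------------------------

test_that("selection filters to interval membership", {
  s <- behavior_session(
    events = data.frame(name = c(rep("np1", 10), "led2_on", "led2_off"),
                        time = c(seq(5, 95, by = 10), 0, 40)),
    end = 200)
  s <- derive_intervals(s, rules = list(
    DRUG = list(kind = "paired_on_off", on = "led2_on", off = "led2_off")))
  inside <- select_events(s, "np1", within = "DRUG")
  expect_equal(inside, c(5, 15, 25, 35))
  expect_equal(select_events(s, "np1"), seq(5, 95, by = 10))
})

test_that("first_in_interval returns the minimum per interval instance", {
  s <- behavior_session(
    events = data.frame(
      name = c(rep("np1", 6), "led2_on", "led2_off", "led2_on", "led2_off"),
      time = c(12, 15, 3, 55, 60, 80, 10, 30, 50, 70)),
    end = 100)
  s <- derive_intervals(s, rules = list(
    DRUG = list(kind = "paired_on_off", on = "led2_on", off = "led2_off")))
  got <- select_events(s, "np1", within = "DRUG",
                       selector = "first_in_interval")
  # brute force over the event list
  iv <- s$intervals[s$intervals$name == "DRUG", ]
  want <- sort(vapply(seq_len(nrow(iv)), function(i) {
    t <- s$events$time[s$events$name == "np1"]
    min(t[t >= iv$start[i] & t < iv$end[i]])
  }, numeric(1)))
  expect_equal(got, want)
  expect_length(got, 2)
})

test_that("ordinal_in_series picks the k-th response of complete FR series", {
  s <- behavior_session(
    events = data.frame(name = c(rep("np1", 5), "inj1"),
                        time = c(5, 6, 7, 8, 9, 11)))
  expect_equal(select_events(s, "np1", selector = "ordinal_in_series",
                             k = 1, series_size = 5), 5)
  expect_equal(select_events(s, "np1", selector = "ordinal_in_series",
                             k = 5, series_size = 5), 9)
  expect_error(select_events(s, "np1", selector = "ordinal_in_series",
                             k = 6, series_size = 5), "exceeds")
})

test_that("time-out responses do not count towards the series", {
  # two completed series; pokes at 21 and 22 fall inside the time-out
  s <- behavior_session(
    events = data.frame(
      name = c(rep("np1", 5), "inj1", rep("np1", 2), rep("np1", 5), "inj1"),
      time = c(1:5, 7, 21, 22, 61:65, 67)),
    end = 200)
  s <- derive_intervals(s, rules = list(
    TIMEOUT = list(kind = "event_offset", trigger = "inj1", duration_s = 40)))
  firsts <- select_events(s, "np1", selector = "ordinal_in_series",
                          k = 1, series_size = 5)
  expect_equal(firsts, c(1, 61))
})

test_that("selection is consistent with the fixed-ratio schedule on synthetic truth", {
  st <- shared_study()
  s <- shared_session(2)
  truth <- st$sessions[[2]]$behavior$truth
  np1 <- sort(truth$events$time[truth$events$name == "np1"])
  inj <- sort(truth$events$time[truth$events$name == "inj1"])
  # unfiltered selection returns exactly the parser's events of that name
  expect_equal(select_events(s, "np1"), np1, tolerance = 1e-9)
  # each injection was earned by an active poke 2 s earlier (cue 1 s +
  # pump 1 s), and at least ratio x injections pokes happened overall
  expect_true(all(vapply(inj, function(ij)
    any(abs(np1 - (ij - 2)) < 1e-6), logical(1))))
  expect_gte(length(np1), 5 * length(inj))
  # every 5th-of-series selection (drug periods, time-outs excluded) is a
  # poke that immediately precedes an injection or an incomplete tail poke
  fifth <- select_events(s, "np1", within = "DRUG",
                         selector = "ordinal_in_series", k = 5,
                         series_size = 5)
  expect_true(all(vapply(fifth, function(t)
    any(abs(np1 - t) < 1e-9), logical(1))))
  expect_gte(length(fifth), length(inj) - 1)
})
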