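test_that("activity_trace enforces its invariants", {
  expect_error(activity_trace("f", counts = c(1, 2), position = 5), "identical length")
  expect_error(activity_trace("f", counts = -1, position = 5), "non-negative")
  expect_error(activity_trace("f", counts = 1, position = 18), "n_beams")
  expect_error(activity_trace("a,b", counts = 1, position = 5), "comma")
  # nearest beam jumped 3 cells on a single crossing: physically suspect
  expect_warning(activity_trace("f", counts = c(0, 1), position = c(2, 5)),
                 "displacement invariant")
  tr <- activity_trace("f", counts = c(0, 3), position = c(2, 5))
  expect_s3_class(tr, "activity_trace")
  expect_identical(tr$duration, 2L)
})

test_that("ZT conversion wraps elapsed time onto the 24-h circle", {
  expect_identical(zt_at(0, zt0 = 2), 2)        # converting t0 gives zt0
  expect_equal(zt_at(23 * 3600, zt0 = 2), 1)
  expect_equal(zt_at(48 * 3600, zt0 = 11.5), 11.5)
  expect_true(all(zt_at(seq(0, 1e6, by = 977), zt0 = 7) >= 0 &
                  zt_at(seq(0, 1e6, by = 977), zt0 = 7) < 24))
})

test_that("a hand-written dialect file parses to the expected trace", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("#photobeam-activity v1",
               "#t0=2026-01-01T08:00:00Z",
               "#zt0=0",
               "#geometry=16x17",
               "0,0,5", "1,2,7", "2,1,6"), f)
  traces <- read_activity_csv(f)
  expect_length(traces, 1L)
  tr <- traces[[1L]]
  expect_identical(tr$counts, c(0L, 2L, 1L))
  expect_identical(tr$position, c(5L, 7L, 6L))
  expect_identical(tr$duration, 3L)
  expect_identical(tr$fly_id, "tube01")  # no #flies header: tube labels
  expect_identical(format(tr$t0, "%H", tz = "UTC"), "08")
})

test_that("activity CSV write -> read is bit-identical", {
  set.seed(101)
  for (rep in 1:10) {
    n <- sample(1:4, 1)
    zt0 <- runif(1, 0, 24)  # shared session metadata as the writer requires
    traces <- lapply(seq_len(n), function(i)
      rand_trace(duration = 60L, fly_id = sprintf("fly%02d", i), zt0 = zt0))
    f <- withr::local_tempfile(fileext = ".csv")
    write_activity_csv(traces, f)
    back <- read_activity_csv(f)
    expect_equal(back, traces)
    # and byte-stable on rewrite
    f2 <- withr::local_tempfile(fileext = ".csv")
    write_activity_csv(back, f2)
    expect_identical(readLines(f), readLines(f2))
  }
})

test_that("activity CSV reader reports malformed input precisely", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("#photobeam-wrong v9", "#t0=2026-01-01T08:00:00Z",
               "#zt0=0", "#geometry=16x17", "0,1,5"), f)
  expect_error(read_activity_csv(f), "header line 1")
  writeLines(c("#photobeam-activity v1", "#t0=not-a-time",
               "#zt0=0", "#geometry=16x17", "0,1,5"), f)
  expect_error(read_activity_csv(f), "header line 2")
  writeLines(c("#photobeam-activity v1", "#t0=2026-01-01T08:00:00Z",
               "#zt0=0", "#geometry=16x17", "0,1,5", "2,1,5"), f)
  expect_error(read_activity_csv(f), "integrity")
  # displacement glitches are tolerated with a row-indexed warning
  writeLines(c("#photobeam-activity v1", "#t0=2026-01-01T08:00:00Z",
               "#zt0=0", "#geometry=16x17", "0,0,2", "1,0,9"), f)
  expect_warning(tr <- read_activity_csv(f), "displacement")
  expect_identical(tr[[1L]]$position, c(2L, 9L))
})

test_that("write_activity_csv rejects mixed sessions", {
  a <- rand_trace(40L, fly_id = "a")
  b <- rand_trace(50L, fly_id = "b")
  f <- withr::local_tempfile(fileext = ".csv")
  expect_error(write_activity_csv(list(a, b), f), "mixed durations")
})

test_that("stimulus log constructor enforces order and deduplication", {
  expect_error(stimulus_log(time_ms = c(5, 1), tubes = list(1, 1),
                            color = c("off", "white"), intensity = c(0, 1)),
               "sorted")
  expect_error(stimulus_log(time_ms = c(0, 10), tubes = list(1, 1),
                            color = c("white", "white"), intensity = c(1, 1)),
               "no-op")
  # same state on different tubes is not a no-op
  log <- stimulus_log(time_ms = c(0, 10), tubes = list(1, 2),
                      color = c("white", "white"), intensity = c(1, 1))
  expect_identical(nrow(log), 2L)
  expect_error(stimulus_log(1, list(1), "purple", 1), "unknown color")
})

test_that("stimulus log files round-trip losslessly", {
  # empty log: header-only file
  f <- withr::local_tempfile(fileext = ".csv")
  write_stimulus_log(stimulus_log(), f)
  expect_identical(readLines(f),
                   c("#photobeam-stim v1", "time_ms,tubes,color,intensity"))
  expect_identical(nrow(read_stimulus_log(f)), 0L)

  # the 1-s darkness pulse serialises to exactly two rows
  log <- stimulus_log(time_ms = c(1800000, 1801000),
                      tubes = list(1:16, 1:16),
                      color = c("off", "white"), intensity = c(0, 1))
  write_stimulus_log(log, f)
  lines <- readLines(f)
  expect_identical(lines[3:4], c("1800000,1-16,off,0", "1801000,1-16,white,1"))
  expect_equal(read_stimulus_log(f), log)

  # randomized logs (fragmented tube sets, real-valued intensities)
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(1:40, 1)
    cols <- sample(c("white", "blue", "green"), n, replace = TRUE)
    log <- stimulus_log(
      time_ms = cumsum(sample(1:5000, n, replace = TRUE)),
      tubes = lapply(seq_len(n), function(i) sample(1:16, sample(1:16, 1))),
      # distinct intensities: no event can be a per-tube no-op
      color = cols, intensity = runif(n))
    write_stimulus_log(log, f)
    expect_equal(read_stimulus_log(f), log)
  }
})

test_that("unsorted stimulus files raise an integrity error", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("#photobeam-stim v1", "time_ms,tubes,color,intensity",
               "5000,1-16,off,0", "1000,1-16,white,1"), f)
  expect_error(read_stimulus_log(f), "integrity")
})

test_that("tube-set strings compress and parse consistently", {
  expect_identical(format_tube_set(1:16), "1-16")
  expect_identical(format_tube_set(c(5, 1, 3)), "1,3,5")
  expect_identical(format_tube_set(c(1, 2, 3, 7)), "1-3,7")
  expect_identical(parse_tube_set("1-3,7"), c(1L, 2L, 3L, 7L))
  expect_identical(parse_tube_set("16"), 16L)
  expect_error(parse_tube_set("3-1"), "malformed")
  set.seed(11)
  for (rep in 1:25) {
    s <- sort(sample(1:64, sample(1:20, 1)))
    expect_identical(parse_tube_set(format_tube_set(s)), s)
  }
})
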