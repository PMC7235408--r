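# lfp_recording ---------------------------------------------------------------

test_that("lfp_recording validates its inputs", {
  expect_error(lfp_recording(numeric(), 1000), "at least one sample")
  expect_error(lfp_recording(c(1, NA), 1000), "finite")
  expect_error(lfp_recording(c(1, Inf), 1000), "finite")
  expect_error(lfp_recording(1:10, 0), "fs")
  expect_error(lfp_recording(1:10, -5), "fs")
  expect_error(lfp_recording(1:10, 1000, t0 = NA), "t0")
})

test_that("duration, times and tibble conversion are consistent", {
  rec <- lfp_recording(sin(1:2000), fs = 1000, t0 = 2)
  expect_equal(lfp_duration(rec), 2)
  tt <- lfp_times(rec)
  expect_equal(tt[1], 2)
  expect_equal(tt[2] - tt[1], 1e-3)
  tb <- tibble::as_tibble(rec)
  expect_named(tb, c("time", "amplitude"))
  expect_identical(tb$amplitude, rec$samples)
})

test_that("lfp_slice takes [from, to) and re-anchors t0", {
  rec <- lfp_recording(1:1000, fs = 100, t0 = 0)
  sl <- lfp_slice(rec, 1, 2)
  expect_equal(length(sl$samples), 100)
  expect_equal(sl$t0, 1)
  expect_identical(sl$samples, as.numeric(101:200))
  expect_error(lfp_slice(rec, 20, 30), "no samples")
})

# CSV -------------------------------------------------------------------------

test_that("csv reader infers fs from uniform spacing", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,amplitude", "0.000,0.0", "0.001,1.0", "0.002,0.0"), p)
  rec <- read_lfp(p)
  expect_equal(rec$fs, 1000)
  expect_equal(length(rec$samples), 3)
  expect_equal(rec$samples, c(0, 1, 0))
})

test_that("csv round-trip is bitwise for the samples", {
  set.seed(11)
  rec <- lfp_recording(rnorm(500) * 100, fs = 250, t0 = 1.25)
  p <- withr::local_tempfile(fileext = ".csv")
  write_lfp(rec, p)
  back <- read_lfp(p)
  expect_identical(back$samples, rec$samples)
  expect_equal(back$fs, rec$fs, tolerance = 1e-9)
  expect_equal(back$t0, rec$t0)
})

test_that("non-uniform csv timestamps are a sampling error", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,amplitude", "0,0", "0.001,1", "0.003,0"), p)
  expect_error(read_lfp(p), "non-uniform")
})

test_that("malformed csv header is a format error", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,amp", "0,0", "0.001,1"), p)
  expect_error(read_lfp(p), "time,amplitude")
})

# EDF -------------------------------------------------------------------------

test_that("edf round-trip is within the 16-bit quantization bound", {
  set.seed(12)
  x <- runif(2500, -1000, 1000)
  rec <- lfp_recording(x, fs = 1000, t0 = 3.5)
  p <- withr::local_tempfile(fileext = ".edf")
  write_lfp(rec, p)
  back <- read_lfp(p)
  expect_equal(length(back$samples), length(rec$samples))
  expect_equal(back$fs, rec$fs)
  expect_equal(back$t0, rec$t0, tolerance = 1e-8)
  rng <- diff(range(x))
  expect_lt(max(abs(back$samples - rec$samples)), rng / 2^15)
})

test_that("edf handles non-integer record counts and constant signals", {
  rec <- lfp_recording(sin(seq_len(1500)), fs = 1000) # 1.5 s -> padded record
  p <- withr::local_tempfile(fileext = ".edf")
  write_lfp(rec, p)
  expect_equal(length(read_lfp(p)$samples), 1500)
  const <- lfp_recording(rep(5, 100), fs = 100)
  p2 <- withr::local_tempfile(fileext = ".edf")
  write_lfp(const, p2)
  expect_equal(read_lfp(p2)$samples, rep(5, 100), tolerance = 1e-3)
})

test_that("edf requires an integer sampling rate", {
  rec <- lfp_recording(1:100, fs = 250.5)
  expect_error(write_lfp(rec, withr::local_tempfile(fileext = ".edf")), "integer")
})

test_that("round-trip preserves count, fs and values for random recordings", {
  set.seed(13)
  for (i in 1:20) {
    n <- sample(50:400, 1)
    fs <- sample(c(100, 250, 500, 1000), 1)
    rec <- lfp_recording(rnorm(n, sd = 50), fs = fs, t0 = runif(1, 0, 10))
    pc <- withr::local_tempfile(fileext = ".csv")
    write_lfp(rec, pc)
    rc <- read_lfp(pc)
    expect_identical(rc$samples, rec$samples)
    expect_equal(length(rc$samples), n)
    pe <- withr::local_tempfile(fileext = ".edf")
    write_lfp(rec, pe)
    re <- read_lfp(pe)
    expect_equal(length(re$samples), n) # never silently resamples
    expect_equal(re$fs, fs)
    rng <- max(diff(range(rec$samples)), 2)
    expect_lt(max(abs(re$samples - rec$samples)), rng / 2^15)
  }
})

# events ----------------------------------------------------------------------

test_that("event tables validate kinds and ordering", {
  expect_error(event_table(1, "nonsense"), "unknown event kind")
  expect_error(
    event_table(c(2, 1), c("trigger", "trigger")),
    "non-decreasing"
  )
  expect_error(
    event_table(5, "seizure_offset"),
    "without a preceding seizure_onset"
  )
  expect_error(
    event_table(c(1, 2), c("seizure_onset", "seizure_onset")),
    "consecutive seizure_onset"
  )
})

test_that("seizure intervals come from alternating onset/offset pairs", {
  ev <- event_table(c(10, 25), c("seizure_onset", "seizure_offset"))
  iv <- seizure_intervals(ev)
  expect_equal(iv$onset, 10)
  expect_equal(iv$offset, 25)
  expect_equal(iv$duration, 15)
  open <- event_table(c(10, 25, 40),
    c("seizure_onset", "seizure_offset", "seizure_onset")
  )
  expect_error(seizure_intervals(open), "unmatched")
  expect_equal(nrow(seizure_intervals(open, require_matched = FALSE)), 1)
})

test_that("event csv round-trips, including the empty table", {
  ev <- event_table(
    c(1.5, 1.5, 1.9, 10, 25),
    c("trigger", "stim_on", "stim_off", "seizure_onset", "seizure_offset"),
    payload = c("a", "", "", "", "")
  )
  p <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, p)
  back <- read_events(p)
  expect_equal(back$time_s, ev$time_s)
  expect_identical(back$kind, ev$kind)
  expect_identical(back$payload, ev$payload)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_events(event_table(), p2)
  expect_equal(nrow(read_events(p2)), 0)
})
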