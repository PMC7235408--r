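sine_rec <- function(freq, duration_s = 10, fs = 1000, amp = 100) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  lfp_recording(amp * sin(2 * pi * freq * t), fs = fs)
}

# STFT -------------------------------------------------------------------------

test_that("a pure 8 Hz tone peaks at the 8 Hz bin in every frame", {
  map <- stft_power(sine_rec(8))
  peak_bin <- apply(map$power, 2, which.max)
  expect_true(all(map$freq[peak_bin] == 8))
})

test_that("the STFT is Parseval-exact per frame", {
  set.seed(31)
  rec <- lfp_recording(rnorm(3500, sd = 40), fs = 1000)
  map <- stft_power(rec)
  w <- as.numeric(signal::hamming(1000))
  starts <- seq(1, 3500 - 1000 + 1, by = 500)
  for (j in seq_along(starts)) {
    frame_energy <- sum((rec$samples[starts[j]:(starts[j] + 999)] * w)^2)
    expect_equal(sum(map$power[, j]), frame_energy,
      tolerance = 1e-6
    )
  }
})

test_that("white-noise power is flat over 1-200 Hz after frame averaging", {
  set.seed(32)
  rec <- lfp_recording(rnorm(51000), fs = 1000) # 101 frames at 50% overlap
  map <- stft_power(rec)
  expect_gte(ncol(map$power), 100)
  mean_p <- rowMeans(map$power)
  in_band <- map$freq >= 1 & map$freq <= 200
  low <- mean(mean_p[map$freq >= 1 & map$freq < 100])
  high <- mean(mean_p[map$freq >= 100 & map$freq <= 200])
  expect_lt(abs(low / high - 1), 0.10)
  expect_lt(abs(mean(mean_p[in_band]) / mean(mean_p[!in_band][-1]) - 1), 0.10)
})

test_that("stft_power validates its input", {
  expect_error(stft_power(lfp_recording(rnorm(100), fs = 200)), "400")
  expect_error(stft_power(lfp_recording(rnorm(500), fs = 1000)), "shorter")
})

# band and relative power -------------------------------------------------------

test_that("single tones give extreme relative theta power", {
  rp8 <- relative_power(stft_power(sine_rec(8)))
  expect_true(all(rp8$power >= 0.99))
  rp50 <- relative_power(stft_power(sine_rec(50)))
  expect_true(all(rp50$power <= 0.01))
})

test_that("RP is bounded and partitions of the total band sum to 1", {
  set.seed(33)
  rec <- lfp_recording(rnorm(5000, sd = 25), fs = 1000)
  map <- stft_power(rec)
  rp <- relative_power(map)
  expect_true(all(rp$power >= 0 & rp$power <= 1))
  edges <- c(1, 4, 12, 30, 80, 200)
  parts <- purrr::map(seq_len(length(edges) - 1), function(i) {
    # disjoint bin partition: [edge_i, edge_{i+1}) except the last, inclusive
    sel_band <- c(edges[i], edges[i + 1] - if (i < length(edges) - 1) 1e-9 else 0)
    relative_power(map, band = sel_band)$power
  })
  total <- Reduce(`+`, parts)
  expect_lt(max(abs(total - 1)), 1e-9)
})

test_that("amplitude scaling multiplies AP by a^2 and leaves RP unchanged", {
  set.seed(34)
  x <- rnorm(3000, sd = 30)
  a <- 3.7
  m1 <- stft_power(lfp_recording(x, 1000))
  m2 <- stft_power(lfp_recording(a * x, 1000))
  ap1 <- band_power(m1)$power
  ap2 <- band_power(m2)$power
  expect_equal(ap2, a^2 * ap1, tolerance = 1e-9)
  expect_equal(relative_power(m2)$power, relative_power(m1)$power, tolerance = 1e-9)
})

test_that("band_power validates the band", {
  map <- stft_power(sine_rec(8, duration_s = 2))
  expect_error(band_power(map, c(12, 4)), "empty")
  expect_error(relative_power(map, band = c(0.5, 12)), "within the total")
})

# MAP / MRP ----------------------------------------------------------------------

test_that("map_mrp reproduces closed forms", {
  series <- tibble::tibble(time = seq(0.5, 9.5, by = 0.5), power = 2.5)
  expect_equal(map_mrp(series, 2, 5), 2.5)
  lin <- tibble::tibble(time = seq(0.005, 0.995, by = 0.01), power = seq(0.005, 0.995, by = 0.01))
  expect_equal(map_mrp(lin, 0, 1), 0.5, tolerance = 0.02)
  expect_error(map_mrp(series, 20, 30), "no STFT frames")
})

test_that("percent_changes evaluates Eqs. 4-5", {
  pc <- percent_changes(1, 2, 0.5, 0.5)
  expect_equal(pc$dap, 1.0)
  expect_equal(pc$drp, 0)
  expect_error(percent_changes(0, 1, 0.5, 0.4), "positive")
})

# stimulation response -----------------------------------------------------------

test_that("stim_response_metrics drops triggers with incomplete windows", {
  g <- gen_theta_lfp(theta_model(), duration_s = 20, seed = 41, triggers = 10)
  met <- stim_response_metrics(g$recording, c(0.2, 10, 19.5))
  expect_equal(nrow(met), 1) # only the t = 10 trigger has full windows
  expect_equal(met$trigger, 10)
  expect_named(
    met,
    c("trigger", "map_pre", "map_post", "mrp_pre", "mrp_post", "dap", "drp")
  )
})

test_that("pre-window frames never straddle the stimulus onset", {
  # a huge square response right at the trigger must not leak into map_pre
  fs <- 1000
  x <- sin(2 * pi * 8 * seq(0, 20 - 1 / fs, by = 1 / fs)) * 10
  x[10001:12000] <- x[10001:12000] * 100
  rec <- lfp_recording(x, fs)
  met <- stim_response_metrics(rec, 10)
  base <- map_mrp(band_power(stft_power(lfp_recording(x[1:8000], fs))), 3, 7)
  expect_lt(met$map_pre / base, 1.05)
})

test_that("thin_triggers enforces the minimum spacing greedily", {
  expect_equal(thin_triggers(c(0, 1, 2, 6, 7, 12), 5), c(0, 6, 12))
  expect_equal(thin_triggers(numeric(), 5), numeric())
  expect_error(thin_triggers(c(3, 1), 5), "unsorted|sorted|is.unsorted")
})

# seizure outcomes ----------------------------------------------------------------

test_that("latency and duration follow the event table", {
  ev <- event_table(c(100, 160), c("seizure_onset", "seizure_offset"))
  out <- seizure_outcomes(ev)
  expect_equal(out$latency, 100)
  expect_equal(out$duration, 60)
  g <- glance(out)
  expect_equal(g$first_latency_s, 100)
  expect_equal(g$mean_duration_s, 60)
})

test_that("no seizures gives an empty table and flagged NA latency", {
  out <- seizure_outcomes(event_table())
  expect_equal(nrow(out), 0)
  g <- glance(out)
  expect_true(is.na(g$first_latency_s))
  expect_equal(g$n_seizures, 0)
})

test_that("repeated equal seizures give SEM 0", {
  ev <- event_table(
    c(50, 60, 110, 120, 170, 180),
    rep(c("seizure_onset", "seizure_offset"), 3)
  )
  g <- glance(seizure_outcomes(ev))
  expect_equal(g$mean_duration_s, 10)
  expect_equal(g$sem_duration_s, 0)
  out <- seizure_outcomes(ev)
  expect_equal(out$latency, c(50, 50, 50)) # each onset minus previous offset
})
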