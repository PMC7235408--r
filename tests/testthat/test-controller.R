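cfg <- load_config()

# phase mode -----------------------------------------------------------------------

test_that("noiseless 8 Hz theta yields >= 40 accurately phased triggers in 60 s", {
  # the amplitude gate is not under test here, so skip its 10 s calibration
  cfg0 <- load_config(overrides = list(amp_threshold_uv = 0))
  m <- theta_model(f_low = 8, f_high = 8, noise_rms_uv = 0, stim_response = NULL)
  ses <- theta_session(m, duration_s = 60, seed = 1)
  run <- run_phase_mode(ses, config = cfg0, target = "peak")
  expect_gte(nrow(run$triggers), 40)
  err <- phase_error_deg(ses$truth(), run$triggers$time_s, "peak")
  expect_lt(max(abs(err)), 10)
})

test_that("an all-noise recording produces no triggers", {
  # the amplitude gate is calibrated on theta-present data (nominal theta is
  # ~200 uV peak-to-peak, so the default 0.5 fraction gives 100 uV); a
  # recording in which theta never appears must then never trigger
  cfg_cal <- load_config(overrides = list(amp_threshold_uv = 100))
  set.seed(61)
  rec <- lfp_recording(pink_noise(60000, 1000, rms = 30), fs = 1000)
  run <- run_phase_mode(rec, config = cfg_cal, target = "peak")
  expect_equal(nrow(run$triggers), 0)
})

test_that("phase mode is deterministic", {
  ses1 <- theta_session(theta_model(), duration_s = 30, seed = 2)
  ses2 <- theta_session(theta_model(), duration_s = 30, seed = 2)
  r1 <- run_phase_mode(ses1, config = cfg)
  r2 <- run_phase_mode(ses2, config = cfg)
  expect_identical(r1$triggers, r2$triggers)
  expect_identical(r1$log, r2$log)
})

test_that("phase-mode triggers respect the refractory period", {
  ses <- theta_session(theta_model(), duration_s = 60, seed = 3)
  run <- run_phase_mode(ses, config = cfg)
  expect_gt(nrow(run$triggers), 5)
  refractory <- protocol_neuromodulation()$duration_s + 1
  expect_true(all(diff(run$triggers$time_s) >= refractory - 1e-9))
})

test_that("phase mode rejects too-short recordings", {
  rec <- lfp_recording(rnorm(600), fs = 1000)
  expect_error(run_phase_mode(rec, config = cfg), "shorter")
})

# seizure mode ---------------------------------------------------------------------

test_that("closed-loop TLE: every seizure triggers within 2 s of its onset", {
  ses <- tle_session(tle_model(), duration_s = 300, seed = 4)
  run <- run_seizure_mode(ses, config = cfg)
  eff <- ses$truth()
  expect_gte(nrow(eff), 2)
  expect_equal(nrow(run$triggers), nrow(eff)) # one trigger per seizure
  for (k in seq_len(nrow(eff))) {
    expect_lte(min(abs(run$triggers$time_s - eff$onset[k])), 2)
  }
})

test_that("sham detection matches closed loop and applies no effect", {
  s_closed <- tle_session(tle_model(), duration_s = 300, seed = 5)
  s_sham <- tle_session(tle_model(), duration_s = 300, seed = 5)
  r_closed <- run_seizure_mode(s_closed, config = cfg)
  r_sham <- run_seizure_mode(s_sham, config = cfg, sham = TRUE)
  # the first trigger is identical by construction (same data up to then)
  expect_equal(r_sham$triggers$time_s[1], r_closed$triggers$time_s[1])
  # sham applied no feedback: the generator remains at its natural schedule
  expect_identical(s_sham$truth(), s_sham$natural_truth())
  expect_identical(
    s_sham$recording()$samples,
    tle_session(tle_model(), duration_s = 300, seed = 5)$recording()$samples
  )
})

test_that("a seizure-free recording yields no triggers over 10 minutes", {
  ses <- tle_session(tle_model(), duration_s = 600, seed = 6, include_seizures = FALSE)
  run <- run_seizure_mode(ses, config = cfg, sham = TRUE)
  expect_equal(nrow(run$triggers), 0)
})

test_that("every trigger's causal window satisfies the 3x/2x rule (audit)", {
  ses <- tle_session(tle_model(), duration_s = 300, seed = 7)
  run <- run_seizure_mode(ses, config = cfg)
  expect_gt(nrow(run$triggers), 0)
  for (t in run$triggers$time_s) {
    row <- run$log[abs(run$log$window_end - t) < 1e-9, ]
    expect_equal(nrow(row), 1)
    expect_true(row$flag)
    expect_gte(row$h_ratio, cfg[["detect.h_mult"]])
    expect_gte(row$cl_ratio, cfg[["detect.cl_mult"]])
  }
  # no trigger during stimulation or lockout
  lock <- protocol_antiepileptic()$duration_s + cfg[["detect.lockout_extra_s"]]
  if (nrow(run$triggers) > 1) {
    expect_true(all(diff(run$triggers$time_s) >= lock - 1e-9))
  }
})

test_that("a baseline overlapping a seizure is rejected", {
  ses <- tle_session(tle_model(natural_latency_mean_s = 15, natural_latency_sd_s = 1),
    duration_s = 120, seed = 8
  )
  expect_error(run_seizure_mode(ses, config = cfg), "overlaps")
})

# paired experiment ----------------------------------------------------------------

test_that("run_experiment produces one paired row per seed and arm", {
  ex <- run_experiment(seeds = 1:2, duration_s = 300, config = cfg)
  expect_s3_class(ex, "cltus_experiment")
  expect_equal(nrow(ex), 4)
  expect_setequal(unique(ex$arm), c("cltus", "sham"))
  expect_true(all(c(
    "seed", "arm", "n_triggers", "n_seizures",
    "first_latency_s", "mean_latency_s", "mean_duration_s"
  ) %in% names(ex)))
  sm <- experiment_summary(ex)
  expect_equal(nrow(sm), 2)
  expect_true(all(c("latency_mean_s", "duration_mean_s") %in% names(sm)))
})

test_that("with suppression disabled, closed-loop and sham outcomes are identical", {
  m0 <- tle_model(stim_suppression = list(
    termination_delay_s = 5, onset_delay_gain = 0.8, gain = 0
  ))
  ex <- run_experiment(seeds = 1:2, model = m0, duration_s = 300, config = cfg)
  for (sd in 1:2) {
    a <- ex[ex$seed == sd & ex$arm == "cltus", ]
    b <- ex[ex$seed == sd & ex$arm == "sham", ]
    expect_equal(a$mean_latency_s, b$mean_latency_s)
    expect_equal(a$mean_duration_s, b$mean_duration_s)
    expect_equal(a$n_triggers, b$n_triggers)
  }
})

test_that("run reports print and tidy cleanly", {
  ses <- theta_session(theta_model(), duration_s = 30, seed = 9)
  run <- run_phase_mode(ses, config = cfg)
  expect_output(print(run), "cltus_run")
  expect_identical(tidy(run), run$triggers)
  g <- glance(run)
  expect_equal(g$n_triggers, nrow(run$triggers))
})
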