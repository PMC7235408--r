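#' Default controller configuration
#'
#' Flat namespaced key-value configuration for the whole pipeline. The
#' defaults are the published operating point: 4-12 Hz theta band with a 4 Hz
#' transition, 0.08-0.25 s period thresholds, 1 s analysis buffer, H/CL
#' multipliers 3 and 2, the 500 kHz / 1 kHz PRF / 400 ms / 40% neuromodulation
#' protocol and the 500 kHz / 500 Hz / 30 s / 5% anti-seizure protocol at
#' 0.23 MPa, and a 1000-point Hamming STFT window.
#'
#' @return Named list of configuration values.
#' @export
cltus_defaults <- function() {
  list(
    # theta band-pass
    band.low_hz = 4, band.high_hz = 12, band.transition_hz = 4,
    # phase prediction
    period.min_s = 0.08, period.max_s = 0.25,
    buffer_s = 1.0, hop_s = 0.1,
    amp_threshold_frac = 0.5, amp_threshold_uv = NA_real_,
    calibration_s = 10, t_c_s = 0.01,
    phase.max_skips = 8, phase.min_cycles = 3,
    # seizure detection
    detect.window_s = 1.0, detect.hop_s = 0.5,
    detect.h_mult = 3.0, detect.cl_mult = 2.0,
    detect.baseline_s = 30, detect.offset_windows = 2,
    detect.lockout_extra_s = 5,
    # stimulation protocols
    stim.fundamental_hz = 5e5, stim.pressure_mpa = 0.23,
    stim.phase.prf_hz = 1000, stim.phase.duration_s = 0.4,
    stim.phase.duty_frac = 0.40,
    stim.seizure.prf_hz = 500, stim.seizure.duration_s = 30,
    stim.seizure.duty_frac = 0.05,
    # spectral analysis
    spectral.window_samples = 1000, spectral.overlap = 0.5,
    spectral.total_low_hz = 1, spectral.total_high_hz = 200
  )
}

#' Load and validate a configuration
#'
#' Reads a flat key-value YAML file (or starts from the defaults), applies
#' overrides, rejects unknown keys, and validates ranges. Validation errors
#' name the offending key.
#'
#' @param path Optional YAML file of flat `key: value` pairs.
#' @param overrides Named list applied after the file.
#' @return Validated named list of class `cltus_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- cltus_defaults()
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  user <- utils::modifyList(user, as.list(overrides))
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (k in names(user)) {
    v <- user[[k]]
    if (identical(k, "amp_threshold_uv") && length(v) == 1L && is.na(v)) {
      cfg[[k]] <- NA_real_ # NA = calibrate the threshold from the data
      next
    }
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("config key '", k, "' must be a single finite number", call. = FALSE)
    }
    cfg[[k]] <- as.numeric(v)
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  fail <- function(key, why) {
    stop("invalid config: ", key, " ", why, call. = FALSE)
  }
  pos <- c(
    "band.low_hz", "band.transition_hz", "period.min_s", "buffer_s", "hop_s",
    "calibration_s", "detect.window_s", "detect.hop_s", "detect.h_mult",
    "detect.cl_mult", "detect.baseline_s", "stim.fundamental_hz",
    "stim.pressure_mpa", "stim.phase.prf_hz", "stim.phase.duration_s",
    "stim.seizure.prf_hz", "stim.seizure.duration_s", "spectral.window_samples"
  )
  for (k in pos) if (cfg[[k]] <= 0) fail(k, "must be > 0")
  if (cfg[["band.high_hz"]] <= cfg[["band.low_hz"]]) {
    fail("band.high_hz", "must exceed band.low_hz")
  }
  if (cfg[["period.max_s"]] <= cfg[["period.min_s"]]) {
    fail("period.max_s", "must exceed period.min_s")
  }
  for (k in c("stim.phase.duty_frac", "stim.seizure.duty_frac")) {
    if (cfg[[k]] <= 0 || cfg[[k]] > 1) fail(k, "must be in (0, 1]")
  }
  if (cfg[["t_c_s"]] < 0) fail("t_c_s", "must be >= 0")
  if (cfg[["spectral.overlap"]] < 0 || cfg[["spectral.overlap"]] >= 1) {
    fail("spectral.overlap", "must be in [0, 1)")
  }
  if (cfg[["spectral.total_high_hz"]] <= cfg[["spectral.total_low_hz"]]) {
    fail("spectral.total_high_hz", "must exceed spectral.total_low_hz")
  }
  structure(cfg, class = c("cltus_config", "list"))
}

#' Write deterministic synthetic fixtures
#'
#' Generates small, seeded fixture files for tests and documentation: a 30 s
#' theta recording with its phase truth, a TLE recording with its seizure
#' truth, and a default config file. Re-running with the same seed reproduces
#' identical files.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param tle_duration_s Duration of the TLE fixture (default 300 s).
#' @return Invisibly, a character vector of the files written.
#' @export
make_fixtures <- function(out_dir, seed = 1, tle_duration_s = 300) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  th <- gen_theta_lfp(theta_model(), duration_s = 30, seed = seed)
  p <- file.path(out_dir, "theta_30s.csv")
  write_lfp(th$recording, p); paths <- c(paths, p)
  p <- file.path(out_dir, "theta_30s_truth.csv")
  readr::write_csv(th$truth, p); paths <- c(paths, p)
  tl <- gen_tle_lfp(tle_model(), duration_s = tle_duration_s, seed = seed)
  p <- file.path(out_dir, "tle.edf") # 16-bit EDF keeps the fixture compact
  write_lfp(tl$recording, p); paths <- c(paths, p)
  ev <- event_table(
    time_s = c(rbind(tl$truth$onset, tl$truth$offset)),
    kind = rep(c("seizure_onset", "seizure_offset"), nrow(tl$truth))
  )
  p <- file.path(out_dir, "tle_truth_events.csv")
  write_events(ev, p); paths <- c(paths, p)
  p <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(cltus_defaults(), p); paths <- c(paths, p)
  invisible(paths)
}
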