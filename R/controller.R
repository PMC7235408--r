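#' @importFrom rlang .data
NULL

# Accessors that make a plain recording and a synthetic session interchangeable
# inputs to the controller ("real time" is simulated time: the controller only
# ever consumes samples at their timestamps, and the processing delay t_c is an
# injected constant, so runs are reproducible).
loop_input <- function(x) {
  if (inherits(x, c("theta_session", "tle_session"))) {
    list(
      fs = x$fs, duration = x$duration_s,
      window = function(from, to) x$samples_window(from, to),
      session = x
    )
  } else if (inherits(x, "lfp_recording")) {
    list(
      fs = x$fs, duration = lfp_duration(x),
      window = function(from, to) lfp_slice(x, x$t0 + from, x$t0 + to),
      session = NULL
    )
  } else {
    stop("input must be an lfp_recording or a synthetic session", call. = FALSE)
  }
}

new_run_report <- function(mode, target, triggers, events, log, config, seed,
                           protocol, duration_s, sham, baseline = NULL) {
  structure(list(
    mode = mode, target = target, triggers = triggers, events = events,
    log = log, config = config, seed = seed, protocol = protocol,
    duration_s = duration_s, sham = sham, baseline = baseline
  ), class = "cltus_run")
}

#' @export
print.cltus_run <- function(x, ...) {
  cat(sprintf(
    "<cltus_run> mode = %s%s%s: %d trigger(s) over %.1f s\n",
    x$mode, if (!is.null(x$target)) paste0(" (", x$target, ")") else "",
    if (x$sham) " [sham]" else "", nrow(x$triggers), x$duration_s
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cltus_run <- function(x, ...) x$triggers

#' @exportS3Method generics::glance
glance.cltus_run <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    target = if (is.null(x$target)) NA_character_ else x$target,
    sham = x$sham,
    n_triggers = nrow(x$triggers),
    duration_s = x$duration_s,
    seed = if (is.null(x$seed)) NA_integer_ else x$seed
  )
}

#' Run the phase-locked stimulation loop
#'
#' Simulates the online theta-targeting controller over a recording or a
#' live synthetic theta generator: every `hop_s` it takes the most recent
#' analysis buffer (plus one filter-kernel length of history), estimates the
#' theta cycles ([estimate_theta_cycles()]), predicts the wait to the next
#' target extremum ([predict_phase_time()]), and emits a trigger event
#' carrying the neuromodulation protocol at the predicted time. A refractory
#' period of `protocol duration + 1 s` follows every trigger so the
#' post-stimulus response is not immediately re-targeted.
#'
#' The amplitude threshold is `amp_threshold_uv` if set in the config;
#' otherwise it is calibrated as `amp_threshold_frac` times the median filtered
#' peak-to-peak amplitude over the first `calibration_s` seconds.
#'
#' @param x An [lfp_recording()] or a [theta_session()] (closed loop).
#' @param target `"peak"` or `"trough"`.
#' @param config A [load_config()] configuration.
#' @param protocol The [stim_protocol()] carried by triggers (default
#'   [protocol_neuromodulation()]).
#' @param sham If TRUE the full pipeline runs but no stimulus feedback is
#'   applied to a session.
#' @param seed Recorded in the report for provenance (the controller itself is
#'   deterministic).
#' @return A `cltus_run` report: trigger table, per-iteration log, config
#'   snapshot.
#' @export
run_phase_mode <- function(x, target = c("peak", "trough"),
                           config = load_config(),
                           protocol = protocol_neuromodulation(),
                           sham = FALSE, seed = NULL) {
  target <- match.arg(target)
  inp <- loop_input(x)
  spec <- filter_spec(
    config[["band.low_hz"]], config[["band.high_hz"]], config[["band.transition_hz"]]
  )
  kernel <- design_bandpass(spec, inp$fs)
  kernel_s <- kernel$length / inp$fs
  buffer_s <- config[["buffer_s"]]
  hop_s <- config[["hop_s"]]
  span <- buffer_s + kernel_s
  # earliest iteration: enough history for a fully valid filtered stretch of
  # two max periods
  min_span <- kernel_s + 2 * config[["period.max_s"]] + 2 / inp$fs
  if (inp$duration <= min_span) {
    stop("recording shorter than one analysis buffer plus filter history",
      call. = FALSE
    )
  }
  period_range <- c(config[["period.min_s"]], config[["period.max_s"]])
  min_cycles <- config[["phase.min_cycles"]]
  refractory <- protocol$duration_s + 1.0

  estimate_at <- function(t_end, amp_thr) {
    buf <- inp$window(max(0, t_end - span), t_end)
    estimate_theta_cycles(buf, kernel,
      period_range = period_range,
      amp_threshold = amp_thr, min_cycles = min_cycles
    )
  }

  amp_thr <- config[["amp_threshold_uv"]]
  if (is.na(amp_thr)) {
    cal_ends <- seq(min_span, max(min_span, config[["calibration_s"]]), by = hop_s)
    p2p <- purrr::map_dbl(cal_ends, function(te) {
      est <- estimate_at(te, 0)
      if (est$valid) est$p2p else NA_real_
    })
    amp_thr <- if (all(is.na(p2p))) {
      Inf # nothing theta-like during calibration: never trigger
    } else {
      config[["amp_threshold_frac"]] * stats::median(p2p, na.rm = TRUE)
    }
    t_start <- max(min_span, config[["calibration_s"]])
  } else {
    t_start <- min_span
  }

  t_c <- config[["t_c_s"]]
  max_skips <- config[["phase.max_skips"]]
  ends <- seq(t_start, inp$duration, by = hop_s)
  trig_times <- numeric()
  log <- vector("list", length(ends))
  last_trig <- -Inf
  for (i in seq_along(ends)) {
    t_end <- ends[i]
    est <- estimate_at(t_end, amp_thr)
    pred <- predict_phase_time(est, target, t_c = t_c, max_skips = max_skips)
    t_trig <- NA_real_
    fired <- FALSE
    if (pred$valid) {
      # the trigger lands on the predicted extremum: last extremum +
      # (1 + skips) periods
      t_trig <- t_end - pred$t_last + (1 + pred$n_skips) * pred$A_p
      # a candidate just inside the refractory boundary may advance one cycle
      # (longer extrapolation degrades accuracy when the rhythm drifts; a
      # fresher buffer handles larger gaps)
      boundary <- last_trig + refractory
      if (t_trig < boundary && boundary - t_trig <= pred$A_p &&
        pred$n_skips + 1L <= max_skips) {
        t_trig <- t_trig + pred$A_p
      }
      if (t_trig >= last_trig + refractory && t_trig <= inp$duration) {
        fired <- TRUE
        last_trig <- t_trig
        trig_times <- c(trig_times, t_trig)
        if (!is.null(inp$session) && !sham) inp$session$apply_trigger(t_trig)
      }
    }
    log[[i]] <- list(
      t_buffer_end = t_end, valid = pred$valid,
      A_p = est$A_p, p2p = est$p2p, t_c = t_c,
      wait_s = pred$wait_s, n_skips = pred$n_skips,
      t_trigger = t_trig, fired = fired
    )
  }
  log <- dplyr::bind_rows(log)
  triggers <- tibble::tibble(
    time_s = trig_times,
    cause = paste0("theta_", target),
    sham = sham
  )
  events <- event_table(
    time_s = c(trig_times, trig_times, trig_times + protocol$duration_s),
    kind = c(
      rep("trigger", length(trig_times)),
      rep("stim_on", length(trig_times)),
      rep("stim_off", length(trig_times))
    ),
    payload = ""
  )
  new_run_report("phase", target, triggers, events, log, config, seed,
    protocol, inp$duration, sham
  )
}

#' Run the seizure-detection stimulation loop
#'
#' Simulates the online anti-seizure controller: calibrates the H/CL baseline
#' on the first `detect.baseline_s` seconds (which must be seizure free),
#' streams detection windows, and when a window satisfies the 3x/2x rule emits
#' a trigger carrying the anti-seizure protocol. During the stimulation plus a
#' `detect.lockout_extra_s` post-stimulation lockout no new trigger is
#' emitted. On a [tle_session()] with `sham = FALSE` each trigger is fed back
#' to the generator (closed loop); with `sham = TRUE` detection runs but the
#' feedback is suppressed, the paired control condition.
#'
#' @param x An [lfp_recording()] or a [tle_session()].
#' @param config A [load_config()] configuration.
#' @param protocol The [stim_protocol()] carried by triggers (default
#'   [protocol_antiepileptic()]).
#' @param sham Suppress stimulus feedback (default FALSE).
#' @param truth Optional tibble with `onset`/`offset` used to validate that the
#'   baseline interval is seizure free (sessions supply their own).
#' @param seed Recorded for provenance.
#' @return A `cltus_run` report; `events` contains triggers and the detected
#'   seizure onsets/offsets, `log` the per-window statistics and decisions.
#' @export
run_seizure_mode <- function(x, config = load_config(),
                             protocol = protocol_antiepileptic(),
                             sham = FALSE, truth = NULL, seed = NULL) {
  inp <- loop_input(x)
  base_s <- config[["detect.baseline_s"]]
  ws <- config[["detect.window_s"]]
  hs <- config[["detect.hop_s"]]
  if (inp$duration <= base_s + ws) {
    stop("recording shorter than baseline plus one detection window", call. = FALSE)
  }
  if (is.null(truth) && !is.null(inp$session) &&
    inherits(inp$session, "tle_session")) {
    truth <- inp$session$natural_truth()
  }
  if (!is.null(truth) && nrow(truth) &&
    any(truth$onset < base_s & truth$offset > 0)) {
    stop("baseline interval overlaps a labeled seizure", call. = FALSE)
  }
  base_rec <- inp$window(0, base_s)
  baseline <- calibrate_baseline(base_rec, c(0, base_s), ws, hs)
  h_mult <- config[["detect.h_mult"]]
  cl_mult <- config[["detect.cl_mult"]]
  lockout <- protocol$duration_s + config[["detect.lockout_extra_s"]]
  offset_windows <- config[["detect.offset_windows"]]

  starts <- seq(base_s, inp$duration - ws, by = hs)
  nw <- length(starts)
  H <- CL <- numeric(nw)
  flag <- logical(nw)
  trig_times <- numeric()
  ev_t <- numeric(); ev_k <- character()
  lock_until <- -Inf
  in_seizure <- FALSE
  below_run <- 0L
  for (i in seq_len(nw)) {
    t0w <- starts[i]
    t_end <- t0w + ws
    win <- inp$window(t0w, t_end)
    H[i] <- amplitude_sd(win$samples)
    CL[i] <- coastline(win$samples)
    flag[i] <- (H[i] >= h_mult * baseline$H_base) &&
      (CL[i] >= cl_mult * baseline$CL_base)
    if (flag[i]) {
      below_run <- 0L
      if (t_end >= lock_until) {
        trig_times <- c(trig_times, t_end)
        ev_t <- c(ev_t, t_end); ev_k <- c(ev_k, "trigger")
        lock_until <- t_end + lockout
        if (!is.null(inp$session) && !sham) inp$session$apply_trigger(t_end)
        if (!in_seizure) {
          ev_t <- c(ev_t, t_end); ev_k <- c(ev_k, "seizure_onset")
          in_seizure <- TRUE
        }
      }
    } else if (in_seizure) {
      below_run <- below_run + 1L
      if (below_run >= offset_windows) {
        ev_t <- c(ev_t, starts[i - offset_windows + 1L])
        ev_k <- c(ev_k, "seizure_offset")
        in_seizure <- FALSE
        below_run <- 0L
      }
    }
  }
  log <- tibble::tibble(
    window_start = starts, window_end = starts + ws, H = H, CL = CL,
    h_ratio = H / baseline$H_base, cl_ratio = CL / baseline$CL_base,
    flag = flag
  )
  triggers <- tibble::tibble(
    time_s = trig_times, cause = "seizure", sham = sham
  )
  ord <- order(ev_t)
  events <- tibble::tibble(time_s = ev_t[ord], kind = ev_k[ord], payload = "")
  new_run_report("seizure", NULL, triggers, events, log, config, seed,
    protocol, inp$duration, sham, baseline = baseline
  )
}

#' Paired closed-loop vs sham seizure experiment
#'
#' For each seed, generates a synthetic TLE subject and runs the seizure
#' controller twice on the identical realization: once closed loop (triggers
#' fed back, seizures truncated and subsequent onsets delayed) and once sham
#' (detection runs, feedback suppressed). Outcomes are computed from the
#' generator's effective ground-truth seizure intervals with
#' [seizure_outcomes()].
#'
#' @param seeds Integer vector of subject seeds (>= 2 subjects).
#' @param model A [tle_model()].
#' @param config A [load_config()] configuration.
#' @param duration_s Recording length per run (s).
#' @param protocol The anti-seizure [stim_protocol()].
#' @return A tibble of class `cltus_experiment`: one row per seed x arm with
#'   `n_seizures`, `first_latency_s`, `mean_latency_s`, `mean_duration_s`,
#'   `n_triggers`.
#' @export
run_experiment <- function(seeds, model = tle_model(), config = load_config(),
                           duration_s = 600,
                           protocol = protocol_antiepileptic()) {
  if (length(seeds) < 2L) stop("need at least 2 subjects (seeds)", call. = FALSE)
  rows <- purrr::map(seeds, function(sd) {
    purrr::map(c(cltus = FALSE, sham = TRUE), function(is_sham) {
      ses <- tle_session(model, duration_s, sd)
      run <- run_seizure_mode(ses, config, protocol, sham = is_sham, seed = sd)
      out <- glance(seizure_outcomes(ses$truth(), t_ref = 0))
      dplyr::bind_cols(
        tibble::tibble(
          seed = sd, arm = if (is_sham) "sham" else "cltus",
          n_triggers = nrow(run$triggers)
        ),
        out
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  class(rows) <- c("cltus_experiment", class(rows))
  rows
}

#' Summarize a paired experiment across subjects
#'
#' Mean and standard error of the per-subject mean latency and duration, per
#' arm -- the quantities compared between closed-loop and sham stimulation.
#'
#' @param experiment A [run_experiment()] result.
#' @return Tibble with one row per arm.
#' @export
experiment_summary <- function(experiment) {
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  experiment |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(
      n_subjects = dplyr::n(),
      latency_mean_s = mean(.data$mean_latency_s, na.rm = TRUE),
      latency_sem_s = sem(.data$mean_latency_s[!is.na(.data$mean_latency_s)]),
      duration_mean_s = mean(.data$mean_duration_s, na.rm = TRUE),
      duration_sem_s = sem(.data$mean_duration_s[!is.na(.data$mean_duration_s)]),
      .groups = "drop"
    )
}
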