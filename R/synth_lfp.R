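#' Seeded 1/f ("pink") noise
#'
#' Gaussian noise with a power spectrum proportional to `1/f^exponent`,
#' generated by spectral shaping of white Gaussian noise (deterministic given
#' the RNG state, reproducible across platforms up to FFT floating-point
#' determinism).
#'
#' @param n Number of samples.
#' @param fs Sampling rate (Hz).
#' @param exponent Spectral exponent (power ~ 1/f^exponent), default 1.
#' @param rms Target root-mean-square amplitude.
#' @return Numeric vector of length `n` with (near) zero mean and RMS `rms`.
#' @export
pink_noise <- function(n, fs, exponent = 1, rms = 1) {
  stopifnot(n >= 2, fs > 0, exponent >= 0)
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n
  shape <- c(0, f[-1]^(-exponent / 2))
  x <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  x <- x - mean(x)
  x * rms / sqrt(mean(x^2))
}

# Band-limited unit-RMS Gaussian noise via an FFT brick-wall mask.
band_noise <- function(n, fs, band) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n
  X[f < band[1] | f > band[2]] <- 0
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

#' Synthetic theta LFP model
#'
#' Parameters of the hippocampal theta emulation: a 4-12 Hz-band oscillation
#' whose frequency wanders slowly between `f_low` and `f_high` (sinusoidal
#' sweep of period `drift_period_s`, seed-controlled phase), riding on 1/f
#' background noise, plus a stimulation-response model in which a trigger
#' transiently multiplies the theta amplitude by `theta_gain` and injects a
#' 20-200 Hz broadband component of `broadband_gain` times the background RMS,
#' both relaxing to rest with time constant `decay_tau_s`. By construction the
#' response raises theta absolute power while lowering theta relative power.
#'
#' @param f_low,f_high Theta frequency range (Hz), default 6-10.
#' @param theta_amp_uv Theta amplitude (microvolts), default 100.
#' @param noise_exponent 1/f exponent of the background, default 1.
#' @param noise_rms_uv Background RMS; the default gives a 10 dB theta
#'   signal-to-noise ratio (`theta_amp / sqrt(2) / sqrt(10)`).
#' @param fs Sampling rate (Hz), default 1000 (supports the 1-200 Hz analysis
#'   band and a 1 s, 1000-point STFT window).
#' @param drift_period_s Period of the frequency sweep (s), default 60.
#' @param stim_response List: `theta_gain` (post-stimulus theta amplitude
#'   ratio, 1 = no effect; default 1.5), `broadband_gain` (0 = no effect;
#'   default 3), `decay_tau_s` (default 1.5).
#' @param broadband_band Frequency band of the injected broadband response.
#' @return A list of class `theta_model`.
#' @export
theta_model <- function(f_low = 6, f_high = 10, theta_amp_uv = 100,
                        noise_exponent = 1,
                        noise_rms_uv = theta_amp_uv / sqrt(2) / sqrt(10),
                        fs = 1000, drift_period_s = 60,
                        stim_response = list(
                          theta_gain = 1.5, broadband_gain = 3, decay_tau_s = 1.5
                        ),
                        broadband_band = c(20, 200)) {
  stopifnot(
    f_low > 0, f_high >= f_low, theta_amp_uv > 0, noise_rms_uv >= 0,
    fs > 2 * 200, stim_response$theta_gain >= 0,
    stim_response$broadband_gain >= 0, stim_response$decay_tau_s > 0
  )
  structure(list(
    f_low = f_low, f_high = f_high, theta_amp_uv = theta_amp_uv,
    noise_exponent = noise_exponent, noise_rms_uv = noise_rms_uv, fs = fs,
    drift_period_s = drift_period_s, stim_response = stim_response,
    broadband_band = broadband_band
  ), class = "theta_model")
}

# Most-recent-trigger decay envelope: exp(-(t - last trigger)/tau), 0 before
# the first trigger.
trigger_envelope <- function(t, triggers, tau) {
  if (!length(triggers)) return(numeric(length(t)))
  triggers <- sort(triggers)
  idx <- findInterval(t, triggers)
  env <- numeric(length(t))
  has <- idx > 0
  env[has] <- exp(-(t[has] - triggers[idx[has]]) / tau)
  env
}

#' Stateful synthetic theta generator (closed-loop feedback contract)
#'
#' Precomputes, from `seed`, every stochastic ingredient of a theta recording
#' (frequency sweep phase, background noise, broadband response carrier), so
#' the generated samples are a pure function of the trigger sequence: the same
#' seed with the same triggers reproduces samples bitwise, making paired
#' stimulated/sham comparisons exact. Triggers only influence samples at later
#' times.
#'
#' @param model A [theta_model()].
#' @param duration_s Recording length (s), >= 5.
#' @param seed Integer seed.
#' @return An environment of class `theta_session` with functions
#'   `apply_trigger(t)`, `triggers()`, `samples_window(from, to)`,
#'   `recording()`, `truth()`.
#' @export
theta_session <- function(model, duration_s, seed) {
  stopifnot(inherits(model, "theta_model"), duration_s >= 5)
  n <- round(duration_s * model$fs)
  fs <- model$fs
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(as.integer(seed))
  sweep_phi <- stats::runif(1, 0, 2 * pi)
  phi0 <- stats::runif(1, 0, 2 * pi)
  tt <- (0:(n - 1)) / fs
  fmid <- (model$f_low + model$f_high) / 2
  famp <- (model$f_high - model$f_low) / 2
  freq <- fmid + famp * sin(2 * pi * tt / model$drift_period_s + sweep_phi)
  phase <- phi0 + cumsum(2 * pi * freq / fs) - 2 * pi * freq[1] / fs
  theta <- model$theta_amp_uv * cos(phase)
  noise <- if (model$noise_rms_uv > 0) {
    pink_noise(n, fs, model$noise_exponent, model$noise_rms_uv)
  } else {
    numeric(n)
  }
  bb <- band_noise(n, fs, model$broadband_band)
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())

  self <- new.env(parent = emptyenv())
  self$fs <- fs
  self$duration_s <- n / fs
  self$model <- model
  self$seed <- seed
  trig <- numeric()

  window_samples <- function(i0, i1, triggers) {
    base <- theta[i0:i1] + noise[i0:i1]
    sr <- model$stim_response
    if (is.null(sr) || !length(triggers)) {
      return(base)
    }
    t <- tt[i0:i1]
    env <- trigger_envelope(t, triggers, sr$decay_tau_s)
    m_theta <- 1 + (sr$theta_gain - 1) * env
    a_bb <- sr$broadband_gain * model$noise_rms_uv * env
    m_theta * theta[i0:i1] + noise[i0:i1] + a_bb * bb[i0:i1]
  }
  self$apply_trigger <- function(t) {
    stopifnot(t >= 0, t <= self$duration_s)
    trig <<- sort(c(trig, t))
    invisible(t)
  }
  self$triggers <- function() trig
  self$samples_window <- function(from, to) {
    i0 <- max(1L, floor(from * fs) + 1L)
    i1 <- min(n, ceiling(to * fs))
    lfp_recording(window_samples(i0, i1, trig), fs,
      t0 = (i0 - 1) / fs, label = "synthetic theta"
    )
  }
  self$recording <- function() {
    lfp_recording(window_samples(1L, n, trig), fs, t0 = 0, label = "synthetic theta")
  }
  self$truth <- function() {
    tibble::tibble(time = tt, phase = phase, freq = freq)
  }
  class(self) <- c("theta_session", "environment")
  self
}

#' Generate a synthetic theta LFP recording
#'
#' Pure-function wrapper around [theta_session()]: generates the recording
#' with a fixed (possibly empty) trigger sequence and returns the recording
#' together with its ground truth (instantaneous unwrapped phase and frequency
#' of the theta component; peaks are at phase = 0 mod 2pi, troughs at pi).
#'
#' @inheritParams theta_session
#' @param triggers Stimulation onset times (s) whose response is baked into
#'   the samples.
#' @return List with `recording` ([lfp_recording()]), `truth` (tibble
#'   `time`, `phase`, `freq`), `session` (the underlying [theta_session()]).
#' @export
gen_theta_lfp <- function(model = theta_model(), duration_s = 60, seed = 1,
                          triggers = numeric()) {
  ses <- theta_session(model, duration_s, seed)
  for (t in triggers) ses$apply_trigger(t)
  list(recording = ses$recording(), truth = ses$truth(), session = ses)
}

#' Ground-truth theta phase at given times
#'
#' Interpolates the unwrapped ground-truth phase and wraps the offset from the
#' target phase into `(-pi, pi]`, in degrees. 0 means the time hit the target
#' exactly.
#'
#' @param truth Truth tibble from [gen_theta_lfp()] / `theta_session()$truth()`.
#' @param times Times to evaluate (s).
#' @param target `"peak"` (phase 0) or `"trough"` (phase pi).
#' @return Numeric vector of signed phase errors in degrees.
#' @export
phase_error_deg <- function(truth, times, target = c("peak", "trough")) {
  target <- match.arg(target)
  ref <- if (target == "peak") 0 else pi
  ph <- stats::approx(truth$time, truth$phase, xout = times, rule = 2)$y
  err <- (ph - ref + pi) %% (2 * pi) - pi
  err * 180 / pi
}

# ---------------------------------------------------------------------------
# Temporal-lobe-epilepsy model

#' Synthetic TLE LFP model
#'
#' Emulates a kainic-acid-style temporal lobe epilepsy recording: quiet 1/f
#' baseline, recurring seizures with amplitude multiplied by
#' `seizure_amp_mult` and sharp biphasic transients at `spike_rate_hz` (both H
#' and CL rise), and a stimulation-suppression model: a trigger during a
#' seizure terminates it `termination_delay_s` later and delays the following
#' onset by `onset_delay_gain` times the mean natural latency. Latency and
#' duration defaults are parameterized to the sham-arm statistics the design
#' emulates (they are model inputs, not claims).
#'
#' @param baseline_rms_uv Baseline noise RMS (microvolts), default 20.
#' @param noise_exponent 1/f exponent, default 1.
#' @param seizure_amp_mult Amplitude multiplier during seizures (> 1), default 5.
#' @param spike_rate_hz Rate of ictal transients (Hz), default 5.
#' @param spike_amp_uv Transient amplitude (microvolts), default 300.
#' @param natural_latency_mean_s,natural_latency_sd_s Gaussian inter-seizure
#'   latency (time from previous offset, or start, to the next onset);
#'   defaults 74 and 12 s.
#' @param natural_duration_mean_s,natural_duration_sd_s Gaussian natural
#'   seizure duration; defaults 74 and 15 s.
#' @param fs Sampling rate (Hz), default 1000.
#' @param stim_suppression List: `termination_delay_s` (seizure ends this long
#'   after a trigger; default 5), `onset_delay_gain` (next-onset delay as a
#'   fraction of the mean natural latency; default 0.8), `gain` (master
#'   switch/scale for the suppression effect; 0 disables it, making
#'   stimulated and sham runs identical).
#' @return A list of class `tle_model`.
#' @export
tle_model <- function(baseline_rms_uv = 20, noise_exponent = 1,
                      seizure_amp_mult = 5, spike_rate_hz = 5,
                      spike_amp_uv = 300,
                      natural_latency_mean_s = 74, natural_latency_sd_s = 12,
                      natural_duration_mean_s = 74, natural_duration_sd_s = 15,
                      fs = 1000,
                      stim_suppression = list(
                        termination_delay_s = 5, onset_delay_gain = 0.8, gain = 1
                      )) {
  stopifnot(
    baseline_rms_uv > 0, seizure_amp_mult > 1, spike_rate_hz >= 0,
    natural_latency_mean_s > 0, natural_duration_mean_s > 0, fs > 0,
    stim_suppression$termination_delay_s >= 0, stim_suppression$gain >= 0
  )
  structure(list(
    baseline_rms_uv = baseline_rms_uv, noise_exponent = noise_exponent,
    seizure_amp_mult = seizure_amp_mult, spike_rate_hz = spike_rate_hz,
    spike_amp_uv = spike_amp_uv,
    natural_latency_mean_s = natural_latency_mean_s,
    natural_latency_sd_s = natural_latency_sd_s,
    natural_duration_mean_s = natural_duration_mean_s,
    natural_duration_sd_s = natural_duration_sd_s,
    fs = fs, stim_suppression = stim_suppression
  ), class = "tle_model")
}

# Sequentially realize the seizure schedule given the triggers applied so far.
# Only triggers falling inside a seizure act on it: the first such trigger
# truncates the seizure at trigger + termination_delay and delays the next
# onset by gain * onset_delay_gain * mean natural latency.
tle_effective_schedule <- function(gaps, durs, triggers, model, duration_s) {
  sup <- model$stim_suppression
  triggers <- sort(triggers)
  onset <- numeric(); offset <- numeric(); stim <- logical()
  t_prev_off <- 0
  for (k in seq_along(gaps)) {
    on_k <- t_prev_off + gaps[k]
    if (on_k >= duration_s) break
    nat_off <- on_k + durs[k]
    trig_in <- triggers[triggers >= on_k & triggers < nat_off]
    if (!is.null(sup) && length(trig_in) && sup$gain > 0) {
      off_k <- min(nat_off, trig_in[1] + sup$termination_delay_s)
      delay <- sup$gain * sup$onset_delay_gain * model$natural_latency_mean_s
      stim_k <- TRUE
    } else {
      off_k <- nat_off
      delay <- 0
      stim_k <- FALSE
    }
    onset <- c(onset, on_k)
    offset <- c(offset, min(off_k, duration_s))
    stim <- c(stim, stim_k)
    t_prev_off <- off_k + delay
  }
  tibble::tibble(onset = onset, offset = offset, stimulated = stim)
}

# 30 ms biphasic transient waveform.
spike_wave <- function(fs, amp, width_s = 0.03) {
  m <- max(4L, round(width_s * fs))
  tau <- seq(0, width_s, length.out = m)
  amp * sin(2 * pi * tau / width_s) * sin(pi * tau / width_s)^2
}

#' Stateful synthetic TLE generator (closed-loop feedback contract)
#'
#' Like [theta_session()] but for the epilepsy model: the latent seizure
#' schedule (latencies, durations, ictal spike times) and the background noise
#' are all drawn up front from `seed`, so the samples are a pure function of
#' the applied trigger sequence and paired stimulated/sham runs share the
#' identical baseline realization.
#'
#' @param model A [tle_model()].
#' @param duration_s Recording length (s).
#' @param seed Integer seed.
#' @param include_seizures Generate the seizure overlay (default TRUE); FALSE
#'   yields a pure-baseline recording, e.g. for false-positive testing.
#' @return An environment of class `tle_session` with functions
#'   `apply_trigger(t)`, `triggers()`, `samples_window(from, to)`,
#'   `recording()`, `truth()` (effective seizure intervals given triggers so
#'   far), `natural_truth()`.
#' @export
tle_session <- function(model, duration_s, seed, include_seizures = TRUE) {
  stopifnot(inherits(model, "tle_model"), duration_s > 0)
  fs <- model$fs
  n <- round(duration_s * fs)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(as.integer(seed))
  noise <- pink_noise(n, fs, model$noise_exponent, model$baseline_rms_uv)
  # enough seizure candidates to cover the recording even with long delays
  n_sz <- max(3L, ceiling(3 * duration_s / model$natural_latency_mean_s) + 3L)
  gaps <- pmax(stats::rnorm(n_sz, model$natural_latency_mean_s,
    model$natural_latency_sd_s
  ), 10)
  durs <- pmax(stats::rnorm(n_sz, model$natural_duration_mean_s,
    model$natural_duration_sd_s
  ), 5)
  spikes_rel <- lapply(durs, function(d) {
    n_spk <- stats::rpois(1, model$spike_rate_hz * d)
    sort(stats::runif(n_spk, 0, d))
  })
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())

  sw <- spike_wave(fs, model$spike_amp_uv)
  m_sw <- length(sw)

  self <- new.env(parent = emptyenv())
  self$fs <- fs
  self$duration_s <- n / fs
  self$model <- model
  self$seed <- seed
  trig <- numeric()

  schedule <- function(triggers) {
    if (!include_seizures) {
      return(tibble::tibble(
        onset = numeric(), offset = numeric(), stimulated = logical()
      ))
    }
    tle_effective_schedule(gaps, durs, triggers, model, self$duration_s)
  }
  window_samples <- function(i0, i1, triggers) {
    x <- noise[i0:i1]
    sched <- schedule(triggers)
    if (!nrow(sched)) return(x)
    t0w <- (i0 - 1) / fs
    idx_t <- function(t) round(t * fs) + 1L # global 1-based sample index
    for (k in seq_len(nrow(sched))) {
      a <- max(i0, idx_t(sched$onset[k]))
      b <- min(i1, idx_t(sched$offset[k]) - 1L)
      if (b >= a) x[(a - i0 + 1L):(b - i0 + 1L)] <-
          x[(a - i0 + 1L):(b - i0 + 1L)] * model$seizure_amp_mult
      # ictal transients (only those completed before the effective offset)
      spk <- sched$onset[k] + spikes_rel[[k]]
      spk <- spk[spk + m_sw / fs < sched$offset[k]]
      spk <- spk[spk + m_sw / fs > t0w & spk < i1 / fs]
      for (ts in spk) {
        j <- idx_t(ts)
        a2 <- max(i0, j); b2 <- min(i1, j + m_sw - 1L)
        if (b2 >= a2) {
          x[(a2 - i0 + 1L):(b2 - i0 + 1L)] <-
            x[(a2 - i0 + 1L):(b2 - i0 + 1L)] + sw[(a2 - j + 1L):(b2 - j + 1L)]
        }
      }
    }
    x
  }
  self$apply_trigger <- function(t) {
    stopifnot(t >= 0, t <= self$duration_s)
    trig <<- sort(c(trig, t))
    invisible(t)
  }
  self$triggers <- function() trig
  self$samples_window <- function(from, to) {
    i0 <- max(1L, floor(from * fs) + 1L)
    i1 <- min(n, ceiling(to * fs))
    lfp_recording(window_samples(i0, i1, trig), fs,
      t0 = (i0 - 1) / fs, label = "synthetic TLE"
    )
  }
  self$recording <- function() {
    lfp_recording(window_samples(1L, n, trig), fs, t0 = 0, label = "synthetic TLE")
  }
  self$truth <- function() schedule(trig)
  self$natural_truth <- function() schedule(numeric())
  class(self) <- c("tle_session", "environment")
  self
}

#' Generate a synthetic TLE LFP recording
#'
#' Pure-function wrapper around [tle_session()] with a fixed trigger sequence.
#'
#' @inheritParams tle_session
#' @param triggers Stimulation times (s) applied to the generator.
#' @return List with `recording`, `truth` (tibble `onset`, `offset`,
#'   `stimulated`), `session`.
#' @export
gen_tle_lfp <- function(model = tle_model(), duration_s = 600, seed = 1,
                        triggers = numeric(), include_seizures = TRUE) {
  ses <- tle_session(model, duration_s, seed, include_seizures)
  for (t in triggers) ses$apply_trigger(t)
  list(recording = ses$recording(), truth = ses$truth(), session = ses)
}
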