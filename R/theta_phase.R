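#' Band-pass filter specification
#'
#' Describes the theta-band FIR filter: pass band edges and the transition
#' width used by the Hamming-window design rule. Defaults are the theta band,
#' 4-12 Hz, with a 4 Hz transition.
#'
#' @param low_hz,high_hz Pass-band edges (Hz), `0 < low_hz < high_hz`.
#' @param transition_hz Transition width (Hz) controlling kernel length via
#'   the Hamming rule `L = ceil(3.3 * fs / transition_hz)` (rounded up to odd).
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(low_hz = 4, high_hz = 12, transition_hz = 4) {
  if (!(low_hz > 0 && high_hz > low_hz)) {
    stop("need 0 < low_hz < high_hz", call. = FALSE)
  }
  if (transition_hz <= 0) stop("transition_hz must be > 0", call. = FALSE)
  structure(
    list(low_hz = low_hz, high_hz = high_hz, transition_hz = transition_hz),
    class = "filter_spec"
  )
}

#' Design the theta band-pass FIR kernel
#'
#' Linear-phase Hamming-window FIR band-pass. The kernel length follows the
#' Hamming transition-width rule `ceil(3.3 * fs / transition_hz)`, rounded up
#' to odd so the group delay `(L - 1) / (2 fs)` is an integer number of
#' samples; the delay is exposed to callers for extrema-time correction.
#'
#' @param spec A [filter_spec()].
#' @param fs Sampling rate (Hz); must exceed `2 * high_hz`.
#' @return A list of class `fir_kernel` with elements `coef`, `fs`,
#'   `group_delay_s`, `length`, `spec`.
#' @export
design_bandpass <- function(spec = filter_spec(), fs) {
  stopifnot(inherits(spec, "filter_spec"))
  if (fs <= 2 * spec$high_hz) {
    stop("fs must exceed twice the upper band edge", call. = FALSE)
  }
  L <- ceiling(3.3 * fs / spec$transition_hz)
  if (L %% 2 == 0) L <- L + 1
  coef <- as.numeric(signal::fir1(
    L - 1, c(spec$low_hz, spec$high_hz) / (fs / 2),
    type = "pass", window = signal::hamming(L)
  ))
  coef <- (coef + rev(coef)) / 2 # enforce exact symmetry (linear phase)
  structure(
    list(
      coef = coef, fs = fs, length = L,
      group_delay_s = (L - 1) / (2 * fs), spec = spec
    ),
    class = "fir_kernel"
  )
}

#' Frequency response of an FIR kernel
#' @param kernel A [design_bandpass()] kernel.
#' @param freq_hz Frequencies at which to evaluate (Hz).
#' @return Tibble with `freq_hz`, `gain` (magnitude) and `gain_db`.
#' @export
fir_response <- function(kernel, freq_hz) {
  k <- seq_along(kernel$coef) - 1
  gain <- vapply(freq_hz, function(f) {
    Mod(sum(kernel$coef * exp(-2i * pi * f * k / kernel$fs)))
  }, numeric(1))
  tibble::tibble(freq_hz = freq_hz, gain = gain, gain_db = 20 * log10(gain))
}

# Zero-phase application of the (symmetric) kernel. "valid": centered
# convolution, NA in the half-kernel edge regions -- equivalent to causal
# filtering followed by group-delay subtraction, so the most recent usable
# output is group_delay_s before the end of the data. "periodic": circular
# FFT filtering, exact for buffers holding an integer number of cycles; used
# as the short-buffer fallback.
fir_apply <- function(x, kernel, edge = c("valid", "periodic")) {
  edge <- match.arg(edge)
  L <- kernel$length
  if (edge == "valid") {
    if (length(x) < L) stop("buffer shorter than the filter kernel", call. = FALSE)
    as.numeric(stats::filter(x, kernel$coef, method = "convolution", sides = 2))
  } else {
    n <- length(x)
    h <- numeric(n)
    idx <- (seq_len(L) - (L + 1) / 2) %% n + 1 # center kernel at lag 0, circular
    for (j in seq_len(L)) h[idx[j]] <- h[idx[j]] + kernel$coef[j]
    Re(stats::fft(stats::fft(x) * stats::fft(h), inverse = TRUE)) / n
  }
}

# Local extrema by strict sign change of the first difference; plateaus take
# the plateau midpoint. Returns fractional indices (parabolic refinement).
find_extrema <- function(y) {
  n <- length(y)
  if (n < 3L) return(list(peaks = numeric(), troughs = numeric()))
  d <- diff(y)
  s <- sign(d)
  # propagate sign across zero-runs (plateaus)
  nz <- which(s != 0)
  if (length(nz) < 2L) return(list(peaks = numeric(), troughs = numeric()))
  out_p <- numeric(); out_t <- numeric()
  for (k in seq_len(length(nz) - 1L)) {
    i <- nz[k]; j <- nz[k + 1L]
    if (s[i] == s[j]) next
    # extremum between samples i+1 and j (plateau midpoint if i+1 < j)
    loc <- (i + 1 + j) / 2
    if (j == i + 1L) { # sharp extremum at sample i+1: parabolic refinement
      im <- i + 1L
      if (im > 1L && im < n) {
        denom <- y[im - 1L] - 2 * y[im] + y[im + 1L]
        if (abs(denom) > .Machine$double.eps) {
          delta <- 0.5 * (y[im - 1L] - y[im + 1L]) / denom
          if (abs(delta) <= 0.5) loc <- im + delta
        }
      }
    }
    if (s[i] > 0) out_p <- c(out_p, loc) else out_t <- c(out_t, loc)
  }
  list(peaks = out_p, troughs = out_t)
}

#' Estimate theta cycles from a buffered LFP segment
#'
#' Filters the buffer with the theta band-pass, locates peaks and troughs of
#' the filtered trace (group-delay corrected), validates inter-extremum
#' intervals against the period thresholds, and summarizes the average period
#' `A_p` and peak-to-peak amplitude. Buffers long enough for a fully valid
#' centered convolution (duration >= kernel + 2 max periods) are filtered that
#' way -- the online path; shorter standalone buffers fall back to circular
#' FFT filtering, which is exact for integer-cycle content.
#'
#' @param buffer An [lfp_recording()] (the controller passes the analysis
#'   window plus one kernel length of history).
#' @param kernel A [design_bandpass()] kernel matching `buffer$fs`.
#' @param period_range Acceptable inter-extremum interval, seconds
#'   (default `c(0.08, 0.25)`).
#' @param amp_threshold Minimum average peak-to-peak amplitude (microvolts) of
#'   the filtered trace for a valid estimate; 0 disables the check.
#' @param min_cycles Minimum number of accepted same-type intervals required
#'   to trust the period estimate (default 3).
#' @return A list of class `theta_cycles`: `peak_times` / `trough_times`
#'   (seconds relative to the buffer start), `A_p`, `p2p`, `valid`,
#'   `buffer_end` (buffer duration), `n_intervals`.
#' @export
estimate_theta_cycles <- function(buffer, kernel,
                                  period_range = c(0.08, 0.25),
                                  amp_threshold = 0, min_cycles = 3L) {
  stopifnot(inherits(buffer, "lfp_recording"), inherits(kernel, "fir_kernel"))
  if (abs(buffer$fs - kernel$fs) > 1e-9) {
    stop("kernel was designed for a different sampling rate", call. = FALSE)
  }
  fs <- buffer$fs
  x <- buffer$samples
  dur <- length(x) / fs
  need <- kernel$length / fs + 2 * period_range[2]
  edge <- if (dur >= need) "valid" else "periodic"
  y <- fir_apply(x, kernel, edge = edge)
  ok <- which(!is.na(y))
  invalid <- function() {
    structure(list(
      peak_times = numeric(), trough_times = numeric(),
      A_p = NA_real_, p2p = NA_real_, valid = FALSE,
      buffer_end = dur, n_intervals = 0L, filter_edge = edge
    ), class = "theta_cycles")
  }
  if (length(ok) < 3L) return(invalid())
  seg <- y[ok]
  ex <- find_extrema(seg)
  # fractional index within seg -> time within buffer (0 = first sample)
  to_time <- function(idx) (ok[1] - 1 + idx - 1) / fs
  pk <- to_time(ex$peaks); tr <- to_time(ex$troughs)
  if (length(pk) < 2L && length(tr) < 2L) return(invalid())
  ivals <- c(diff(pk), diff(tr))
  acc <- ivals[ivals >= period_range[1] & ivals <= period_range[2]]
  if (length(acc) < min_cycles) return(invalid())
  A_p <- mean(acc)
  # average peak-to-peak: filtered value difference between adjacent opposite
  # extrema
  all_t <- sort(c(pk, tr))
  vals <- stats::approx(seq_along(seg) / fs + (ok[1] - 1) / fs - 1 / fs,
    seg, xout = all_t
  )$y
  p2p <- if (length(vals) >= 2L) mean(abs(diff(vals))) * 1 else 0
  if (amp_threshold > 0 && (!is.finite(p2p) || p2p < amp_threshold)) {
    out <- invalid(); out$p2p <- p2p
    return(out)
  }
  structure(list(
    peak_times = pk, trough_times = tr,
    A_p = A_p, p2p = p2p, valid = TRUE,
    buffer_end = dur, n_intervals = length(acc), filter_edge = edge
  ), class = "theta_cycles")
}

#' @export
print.theta_cycles <- function(x, ...) {
  if (x$valid) {
    cat(sprintf(
      "<theta_cycles> valid: A_p = %.4f s (%d intervals), p2p = %.1f uV, %d peaks / %d troughs\n",
      x$A_p, x$n_intervals, x$p2p, length(x$peak_times), length(x$trough_times)
    ))
  } else {
    cat("<theta_cycles> invalid (no reliable theta cycle in buffer)\n")
  }
  invisible(x)
}

#' Predict the wait time to the next theta peak or trough
#'
#' Implements the phase-prediction rule: the wait from the end of the buffer
#' to the next target extremum is `A_p - t_c - t_last`, where `t_c` is the
#' processing delay and `t_last` the time elapsed since the most recent target
#' extremum. If the wait is not positive the prediction is advanced whole
#' cycles (`+ A_p` per skip, up to `max_skips`) -- necessary because the
#' filter's group delay can exceed one theta period, so the most recent
#' knowable extremum may lie several cycles in the past.
#'
#' @param est A valid [estimate_theta_cycles()] result.
#' @param target `"peak"` or `"trough"`.
#' @param t_c Processing delay in seconds (>= 0).
#' @param max_skips Maximum whole-cycle advances before giving up (default 8).
#' @return A list of class `phase_prediction`: `target`, `wait_s`, `t_c`,
#'   `t_last`, `A_p`, `n_skips`, `valid`.
#' @export
predict_phase_time <- function(est, target = c("peak", "trough"), t_c = 0.01,
                               max_skips = 8L) {
  target <- match.arg(target)
  stopifnot(inherits(est, "theta_cycles"), t_c >= 0)
  out <- structure(list(
    target = target, wait_s = NA_real_, t_c = t_c, t_last = NA_real_,
    A_p = est$A_p, n_skips = 0L, valid = FALSE
  ), class = "phase_prediction")
  if (!isTRUE(est$valid)) return(out)
  times <- if (target == "peak") est$peak_times else est$trough_times
  if (!length(times)) return(out)
  t_last <- est$buffer_end - max(times)
  out$t_last <- t_last
  wait <- est$A_p - t_c - t_last
  skips <- 0L
  while (wait <= 0 && skips < max_skips) {
    wait <- wait + est$A_p
    skips <- skips + 1L
  }
  if (wait <= 0) return(out)
  out$wait_s <- wait
  out$n_skips <- skips
  out$valid <- TRUE
  out
}
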