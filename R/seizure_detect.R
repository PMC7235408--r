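#' Amplitude standard deviation of a window
#'
#' Population-form standard deviation (divisor `N`) of a signal window,
#' `H = sqrt(mean((x - mean(x))^2))`. H rises with large-amplitude activity and
#' is one of the two online seizure features.
#'
#' @param x Numeric window of at least 2 finite samples.
#' @return H in the units of `x` (microvolts for LFP).
#' @export
amplitude_sd <- function(x) {
  if (length(x) < 2L) stop("window must contain at least 2 samples", call. = FALSE)
  if (!all(is.finite(x))) stop("window contains non-finite samples", call. = FALSE)
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

#' Coastline (line-length) coefficient of a window
#'
#' Mean absolute first difference, `CL = sum(|x[i] - x[i+1]|) / (N - 1)`.
#' CL rises with waveform roughness, the classic line-length seizure feature.
#'
#' @param x Numeric window of at least 2 finite samples.
#' @return CL in the units of `x`.
#' @export
coastline <- function(x) {
  if (length(x) < 2L) stop("window must contain at least 2 samples", call. = FALSE)
  if (!all(is.finite(x))) stop("window contains non-finite samples", call. = FALSE)
  mean(abs(diff(x)))
}

#' Per-window detector statistics
#'
#' Slides a window over the recording and computes H ([amplitude_sd()]) and
#' CL ([coastline()]) per window.
#'
#' @param rec An [lfp_recording()].
#' @param window_s Window length in seconds (default 1).
#' @param hop_s Hop between window starts in seconds (default 0.5).
#' @param from,to Restrict to windows fully inside `[from, to]` seconds
#'   relative to `rec$t0` (defaults: whole recording).
#' @return Tibble with columns `window_start`, `window_end`, `H`, `CL`, `N`, `m`.
#' @export
window_stats <- function(rec, window_s = 1, hop_s = 0.5,
                         from = 0, to = lfp_duration(rec)) {
  stopifnot(inherits(rec, "lfp_recording"), window_s > 0, hop_s > 0)
  fs <- rec$fs
  wn <- round(window_s * fs)
  if (wn < 2L) stop("window too short for the sampling rate", call. = FALSE)
  hopn <- max(1L, round(hop_s * fs))
  i_from <- max(0L, round(from * fs))
  i_to <- min(length(rec$samples), round(to * fs))
  starts <- seq.int(i_from, i_to - wn, by = hopn)
  if (!length(starts) || i_to - i_from < wn) {
    stop("interval too short for a single window", call. = FALSE)
  }
  res <- purrr::map(starts, function(s) {
    x <- rec$samples[(s + 1):(s + wn)]
    m <- mean(x)
    list(
      H = sqrt(mean((x - m)^2)),
      CL = mean(abs(diff(x))),
      m = m
    )
  })
  tibble::tibble(
    window_start = rec$t0 + starts / fs,
    window_end = rec$t0 + (starts + wn) / fs,
    H = purrr::map_dbl(res, "H"),
    CL = purrr::map_dbl(res, "CL"),
    N = wn,
    m = purrr::map_dbl(res, "m")
  )
}

#' Calibrate the detector baseline
#'
#' Computes baseline H and CL as the medians of the per-window values over a
#' seizure-free interval. Medians (not means) so a stray artifact window does
#' not inflate the baseline.
#'
#' @param rec An [lfp_recording()].
#' @param interval Two-element numeric, calibration interval in seconds
#'   relative to `rec$t0`.
#' @param window_s,hop_s Window geometry, as in [window_stats()].
#' @return A list of class `detector_baseline`: `H_base`, `CL_base`,
#'   `n_windows`, `interval`, `window_s`.
#' @export
calibrate_baseline <- function(rec, interval = c(0, 30), window_s = 1, hop_s = 0.5) {
  stats <- window_stats(rec, window_s, hop_s, from = interval[1], to = interval[2])
  if (nrow(stats) < 5L) {
    stop("calibration interval must contain at least 5 windows", call. = FALSE)
  }
  structure(list(
    H_base = stats::median(stats$H),
    CL_base = stats::median(stats$CL),
    n_windows = nrow(stats),
    interval = interval,
    window_s = window_s
  ), class = "detector_baseline")
}

#' @export
print.detector_baseline <- function(x, ...) {
  cat(sprintf(
    "<detector_baseline> H = %.3f uV, CL = %.3f uV (%d windows over [%g, %g] s)\n",
    x$H_base, x$CL_base, x$n_windows, x$interval[1], x$interval[2]
  ))
  invisible(x)
}

#' Seizure trigger rule
#'
#' The online condition for an epileptic waveform: the window's H at least
#' `h_mult` times baseline AND its CL at least `cl_mult` times baseline
#' (boundaries inclusive -- "or more"). Defaults are the 3x / 2x rule.
#'
#' @param H,CL Window statistics (vectorized).
#' @param baseline A [calibrate_baseline()] result.
#' @param h_mult,cl_mult Threshold multipliers (defaults 3 and 2).
#' @return Logical vector of seizure flags.
#' @export
evaluate_trigger <- function(H, CL, baseline, h_mult = 3, cl_mult = 2) {
  stopifnot(inherits(baseline, "detector_baseline"))
  if (baseline$H_base <= 0 || baseline$CL_base <= 0) {
    stop("baseline must be positive", call. = FALSE)
  }
  (H >= h_mult * baseline$H_base) & (CL >= cl_mult * baseline$CL_base)
}

#' Batch seizure detection over a recording
#'
#' Calibrates a baseline over `baseline_s`, then evaluates every subsequent
#' window with the 3x/2x rule. This is the batch counterpart of the streaming
#' evaluation in [run_seizure_mode()]; both produce identical flag sequences
#' on the same recording.
#'
#' @param rec An [lfp_recording()].
#' @param config A [load_config()] list (window/hop/multipliers/baseline keys).
#' @param baseline Optional precomputed [calibrate_baseline()]; if `NULL`,
#'   calibrated from the first `detect.baseline_s` seconds.
#' @return Tibble of per-window rows: `window_start`, `window_end`, `H`, `CL`,
#'   `h_ratio`, `cl_ratio`, `flag`, with the baseline in attribute `baseline`.
#' @export
detect_seizures <- function(rec, config = load_config(), baseline = NULL) {
  ws <- config[["detect.window_s"]]; hs <- config[["detect.hop_s"]]
  if (is.null(baseline)) {
    baseline <- calibrate_baseline(rec, c(0, config[["detect.baseline_s"]]), ws, hs)
  }
  st <- window_stats(rec, ws, hs, from = baseline$interval[2])
  st$h_ratio <- st$H / baseline$H_base
  st$cl_ratio <- st$CL / baseline$CL_base
  st$flag <- evaluate_trigger(st$H, st$CL, baseline,
    config[["detect.h_mult"]], config[["detect.cl_mult"]]
  )
  st <- st[, c("window_start", "window_end", "H", "CL", "h_ratio", "cl_ratio", "flag")]
  attr(st, "baseline") <- baseline
  st
}

# Turn a per-window flag sequence into trigger / detected onset / offset
# events, honouring the post-trigger lockout and the offset rule (both ratios
# below threshold for `offset_windows` consecutive windows). Shared by the
# batch and streaming paths.
flags_to_events <- function(stats, lockout_s, offset_windows = 2L) {
  time_s <- numeric(); kind <- character()
  lock_until <- -Inf
  in_seizure <- FALSE
  below_run <- 0L
  for (i in seq_len(nrow(stats))) {
    t_end <- stats$window_end[i]
    if (stats$flag[i]) {
      below_run <- 0L
      if (t_end >= lock_until) {
        time_s <- c(time_s, t_end); kind <- c(kind, "trigger")
        lock_until <- t_end + lockout_s
        if (!in_seizure) {
          time_s <- c(time_s, t_end); kind <- c(kind, "seizure_onset")
          in_seizure <- TRUE
        }
      }
    } else if (in_seizure) {
      below_run <- below_run + 1L
      if (below_run >= offset_windows) {
        off_t <- stats$window_start[i - offset_windows + 1L]
        time_s <- c(time_s, off_t); kind <- c(kind, "seizure_offset")
        in_seizure <- FALSE
        below_run <- 0L
      }
    }
  }
  tibble::tibble(time_s = time_s, kind = kind, payload = "")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.detector_baseline <- function(x, ...) {
  tibble::tibble(
    statistic = c("H_base", "CL_base"),
    value = c(x$H_base, x$CL_base),
    n_windows = x$n_windows,
    from_s = x$interval[1], to_s = x$interval[2]
  )
}
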