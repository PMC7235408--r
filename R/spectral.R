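#' Short-time Fourier transform power map
#'
#' Hamming-windowed STFT of a recording: frames of `window_samples` points
#' (default 1000, i.e. 1 s at 1000 Hz) with 50% overlap, one-sided power
#' spectrum per frame. The scaling is Parseval-exact: for each frame the sum
#' of the one-sided power bins equals the time-domain energy of the windowed
#' frame, `sum((x * w)^2)`.
#'
#' @param rec An [lfp_recording()] with `fs >= 400` (so the 1-200 Hz analysis
#'   band is representable) and at least one full window of samples.
#' @param window_samples STFT window length in samples (default 1000). Note
#'   the frequency resolution is `fs / window_samples`.
#' @param overlap Fractional overlap between consecutive frames (default 0.5).
#' @return An object of class `stft_power`: list with `power`
#'   (matrix, frequency x frame), `freq` (Hz), `time` (frame centers, s,
#'   relative to the same origin as `rec$t0`), `fs`, `window_samples`.
#' @export
stft_power <- function(rec, window_samples = 1000, overlap = 0.5) {
  stopifnot(inherits(rec, "lfp_recording"))
  if (rec$fs < 400) {
    stop("fs must be at least 400 Hz for the 1-200 Hz analysis band", call. = FALSE)
  }
  N <- as.integer(window_samples)
  x <- rec$samples
  if (length(x) < N) {
    stop("recording shorter than one STFT window", call. = FALSE)
  }
  if (!(overlap >= 0 && overlap < 1)) stop("overlap must be in [0, 1)", call. = FALSE)
  hop <- max(1L, as.integer(round(N * (1 - overlap))))
  starts <- seq.int(1L, length(x) - N + 1L, by = hop)
  w <- as.numeric(signal::hamming(N))
  frames <- vapply(starts, function(s) x[s:(s + N - 1L)] * w, numeric(N))
  X <- stats::mvfft(frames)
  K <- N %/% 2 + 1L # one-sided bins 0 .. Nyquist
  P <- Mod(X[seq_len(K), , drop = FALSE])^2 / N
  scale <- rep(2, K)
  scale[1] <- 1
  if (N %% 2 == 0) scale[K] <- 1
  P <- P * scale
  structure(list(
    power = P,
    freq = (seq_len(K) - 1) * rec$fs / N,
    time = rec$t0 + (starts - 1 + (N - 1) / 2) / rec$fs,
    fs = rec$fs, window_samples = N
  ), class = "stft_power")
}

#' @export
print.stft_power <- function(x, ...) {
  cat(sprintf(
    "<stft_power> %d frames x %d bins (0-%g Hz), frame centers %.3f-%.3f s\n",
    ncol(x$power), nrow(x$power), max(x$freq), min(x$time), max(x$time)
  ))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.stft_power <- function(x, ...) {
  tidyr::expand_grid(time = x$time, freq = x$freq) |>
    dplyr::arrange(.data$freq, .data$time) |>
    dplyr::mutate(power = as.vector(t(x$power)))
}

#' Absolute band power per STFT frame
#'
#' Sums the one-sided power bins whose frequency lies in `[band[1], band[2]]`
#' (inclusive) for each frame.
#'
#' @param map An [stft_power()] object.
#' @param band Two-element numeric frequency band (Hz); default theta, 4-12 Hz.
#' @return Tibble with columns `time` (frame center, s) and `power`.
#' @export
band_power <- function(map, band = c(4, 12)) {
  stopifnot(inherits(map, "stft_power"))
  if (band[2] <= band[1]) stop("empty frequency band", call. = FALSE)
  sel <- map$freq >= band[1] & map$freq <= band[2]
  if (!any(sel)) stop("no STFT bins in the requested band", call. = FALSE)
  tibble::tibble(time = map$time, power = colSums(map$power[sel, , drop = FALSE]))
}

#' Relative band power per STFT frame
#'
#' Band power divided by the total power over `total` (default 1-200 Hz),
#' per frame. Bounded in `[0, 1]` whenever `band` is inside `total`.
#'
#' @inheritParams band_power
#' @param total Two-element numeric total band (Hz).
#' @return Tibble with columns `time` and `power` (the relative power).
#' @export
relative_power <- function(map, band = c(4, 12), total = c(1, 200)) {
  if (band[1] < total[1] || band[2] > total[2]) {
    stop("band must lie within the total band", call. = FALSE)
  }
  ap <- band_power(map, band)
  tot <- band_power(map, total)
  tibble::tibble(time = ap$time, power = ap$power / tot$power)
}

#' Time-averaged band power over a window
#'
#' Mean of the per-frame values whose frame centers lie in `[t1, t2)`: the
#' mean absolute power (MAP) when given an absolute-power series, the mean
#' relative power (MRP) when given a relative-power series.
#'
#' @param series Tibble with columns `time`, `power` (from [band_power()] or
#'   [relative_power()]).
#' @param t1,t2 Window bounds in seconds, `t2 > t1`.
#' @return A single number.
#' @export
map_mrp <- function(series, t1, t2) {
  stopifnot(t2 > t1)
  sel <- series$time >= t1 & series$time < t2
  if (!any(sel)) {
    stop("no STFT frames with centers in [", t1, ", ", t2, ")", call. = FALSE)
  }
  mean(series$power[sel])
}

#' Percent change in mean band power
#'
#' `dAP = (MAP_post - MAP_pre) / MAP_pre` and analogously for the relative
#' power. In the stimulation analysis the pre window is -1-0 s before the
#' stimulus start and the post window 0-3 s after the stimulus end.
#'
#' @param map_pre,map_post Mean absolute power before / after.
#' @param mrp_pre,mrp_post Mean relative power before / after.
#' @return Tibble with columns `dap` and `drp` (fractional changes).
#' @export
percent_changes <- function(map_pre, map_post, mrp_pre, mrp_post) {
  if (map_pre <= 0 || mrp_pre <= 0) {
    stop("pre-window power must be positive", call. = FALSE)
  }
  tibble::tibble(
    dap = (map_post - map_pre) / map_pre,
    drp = (mrp_post - mrp_pre) / mrp_pre
  )
}

#' Per-trigger stimulation response metrics
#'
#' For each stimulation trigger, computes the mean absolute and relative theta
#' power in a pre-stimulus window (anchored at the stimulus start) and a
#' post-stimulus window (anchored at the stimulus end), and their percent
#' changes. Triggers whose windows are not fully covered by the recording are
#' dropped.
#'
#' Pre-window frames whose support extends past the stimulus onset are
#' excluded: an STFT frame is centered, so a frame whose center falls just
#' before the trigger still contains up to half a window of post-stimulus
#' response, which would otherwise contaminate the pre-stimulus baseline.
#'
#' @param rec An [lfp_recording()].
#' @param trigger_times Stimulation onset times (s).
#' @param stim_duration_s Stimulation duration (s), default 0.4; the stimulus
#'   end is `trigger + stim_duration_s`.
#' @param band Analysis band (Hz), default theta 4-12.
#' @param total Total band for relative power, default 1-200 Hz.
#' @param pre_window,post_window Two-element offsets (s) relative to their
#'   anchors; defaults `c(-1, 0)` before the start, `c(0, 3)` after the end.
#' @param anchor_pre,anchor_post `"start"` or `"end"` of the stimulation.
#' @param window_samples,overlap STFT parameters, see [stft_power()].
#' @return Tibble with one row per evaluated trigger: `trigger`, `map_pre`,
#'   `map_post`, `mrp_pre`, `mrp_post`, `dap`, `drp`.
#' @export
stim_response_metrics <- function(rec, trigger_times, stim_duration_s = 0.4,
                                  band = c(4, 12), total = c(1, 200),
                                  pre_window = c(-1, 0), post_window = c(0, 3),
                                  anchor_pre = c("start", "end"),
                                  anchor_post = c("end", "start"),
                                  window_samples = 1000, overlap = 0.5) {
  anchor_pre <- match.arg(anchor_pre)
  anchor_post <- match.arg(anchor_post)
  map <- stft_power(rec, window_samples, overlap)
  ap <- band_power(map, band)
  rp <- relative_power(map, band, total)
  res <- purrr::map(trigger_times, function(tr) {
    a_pre <- if (anchor_pre == "start") tr else tr + stim_duration_s
    a_post <- if (anchor_post == "start") tr else tr + stim_duration_s
    w_pre <- a_pre + pre_window
    w_post <- a_post + post_window
    # last admissible pre-frame center: frame support must end before the
    # stimulus onset (frames are centered, half-width (N - 1) / (2 fs))
    pre_hi <- min(w_pre[2], tr - (window_samples - 1) / (2 * map$fs))
    if (w_pre[1] < min(map$time) || w_post[2] > max(map$time) + 1e-9 ||
      pre_hi <= w_pre[1]) {
      return(NULL)
    }
    map_pre <- map_mrp(ap, w_pre[1], pre_hi)
    map_post <- map_mrp(ap, w_post[1], w_post[2])
    mrp_pre <- map_mrp(rp, w_pre[1], pre_hi)
    mrp_post <- map_mrp(rp, w_post[1], w_post[2])
    pc <- percent_changes(map_pre, map_post, mrp_pre, mrp_post)
    tibble::tibble(
      trigger = tr, map_pre = map_pre, map_post = map_post,
      mrp_pre = mrp_pre, mrp_post = mrp_post, dap = pc$dap, drp = pc$drp
    )
  })
  dplyr::bind_rows(res)
}

#' Thin trigger times to a minimum spacing
#'
#' Greedy left-to-right selection of trigger times at least `min_spacing_s`
#' apart. Used to pick stimulation trials whose pre/post analysis windows
#' (see [stim_response_metrics()]) do not overlap neighbouring trials.
#'
#' @param times Sorted numeric trigger times (s).
#' @param min_spacing_s Minimum spacing between kept triggers (s).
#' @return The kept subset of `times`.
#' @export
thin_triggers <- function(times, min_spacing_s) {
  stopifnot(min_spacing_s > 0, !is.unsorted(times))
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= min_spacing_s) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times[keep]
}

#' Seizure latency and duration outcomes
#'
#' From an event table with alternating seizure onsets/offsets: the latency of
#' each seizure (time from the previous offset -- or from `t_ref` for the
#' first seizure -- to its onset) and its duration. With no seizures the
#' per-seizure tibble is empty and the first-onset latency is `NA` (flagged).
#'
#' @param events Event tibble (see [event_table()]), or a `truth` tibble with
#'   `onset` / `offset` columns.
#' @param t_ref Reference time for the first latency (s), default 0.
#' @return An object of class `seizure_outcomes`: tibble with columns `onset`,
#'   `offset`, `duration`, `latency`, plus attributes used by [glance()].
#' @export
seizure_outcomes <- function(events, t_ref = 0) {
  iv <- if (all(c("onset", "offset") %in% names(events))) {
    tibble::tibble(
      onset = events$onset, offset = events$offset,
      duration = events$offset - events$onset
    )
  } else {
    seizure_intervals(events)
  }
  prev_off <- c(t_ref, iv$offset[-length(iv$offset)])
  iv$latency <- iv$onset - if (nrow(iv)) prev_off else numeric()
  structure(iv,
    class = c("seizure_outcomes", class(tibble::tibble())),
    t_ref = t_ref
  )
}

#' @exportS3Method generics::glance
glance.seizure_outcomes <- function(x, ...) {
  sem <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  tibble::tibble(
    n_seizures = nrow(x),
    first_latency_s = if (nrow(x)) x$onset[1] - attr(x, "t_ref") else NA_real_,
    mean_latency_s = if (nrow(x)) mean(x$latency) else NA_real_,
    sem_latency_s = sem(x$latency),
    mean_duration_s = if (nrow(x)) mean(x$duration) else NA_real_,
    sem_duration_s = sem(x$duration)
  )
}
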