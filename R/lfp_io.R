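#' Construct an LFP recording
#'
#' A uniformly sampled single-channel local field potential trace. This is the
#' universal in-memory signal type consumed by every analysis function in the
#' package. Amplitudes are in microvolts; the time of sample `i` (1-based) is
#' `t0 + (i - 1) / fs`.
#'
#' @param samples Numeric vector of amplitudes (microvolts). Must be finite and
#'   non-empty.
#' @param fs Sampling rate in Hz (> 0).
#' @param t0 Recording start time in seconds (default 0). All times in the
#'   package are seconds relative to this origin.
#' @param label Free-text channel name.
#' @return An object of class `lfp_recording`.
#' @examples
#' rec <- lfp_recording(sin(2 * pi * 8 * seq(0, 1, by = 1e-3)), fs = 1000)
#' lfp_duration(rec)
#' @export
lfp_recording <- function(samples, fs, t0 = 0, label = "LFP") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) {
    stop("an LFP recording needs at least one sample", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("all samples must be finite", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  }
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0)) {
    stop("`t0` must be a single finite number (s)", call. = FALSE)
  }
  structure(
    list(samples = samples, fs = fs, t0 = t0, label = as.character(label)[1]),
    class = "lfp_recording"
  )
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf(
    "<lfp_recording> '%s': %d samples @ %g Hz (%.3f s), t0 = %g s\n",
    x$label, length(x$samples), x$fs, lfp_duration(x), x$t0
  ))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An [lfp_recording()].
#' @return Duration `length(samples) / fs` in seconds.
#' @export
lfp_duration <- function(rec) {
  stopifnot(inherits(rec, "lfp_recording"))
  length(rec$samples) / rec$fs
}

#' Sample times of a recording
#' @param rec An [lfp_recording()].
#' @return Numeric vector of sample times in seconds.
#' @export
lfp_times <- function(rec) {
  rec$t0 + (seq_along(rec$samples) - 1) / rec$fs
}

#' @importFrom tibble as_tibble
#' @exportS3Method tibble::as_tibble
as_tibble.lfp_recording <- function(x, ...) {
  tibble::tibble(time = lfp_times(x), amplitude = x$samples)
}

#' Extract a time slice of a recording
#'
#' @param rec An [lfp_recording()].
#' @param from,to Slice bounds in seconds (same origin as `t0`); the slice is
#'   `[from, to)` on sample times, clipped to the recording.
#' @return An `lfp_recording` whose `t0` is the time of its first sample.
#' @export
lfp_slice <- function(rec, from, to) {
  stopifnot(inherits(rec, "lfp_recording"), to > from)
  i0 <- max(1L, ceiling((from - rec$t0) * rec$fs - 1e-9) + 1L)
  i1 <- min(length(rec$samples), ceiling((to - rec$t0) * rec$fs - 1e-9))
  if (i1 < i0) stop("slice contains no samples", call. = FALSE)
  lfp_recording(rec$samples[i0:i1], rec$fs,
    t0 = rec$t0 + (i0 - 1) / rec$fs, label = rec$label
  )
}

# ---------------------------------------------------------------------------
# CSV I/O ("time,amplitude", comma separator, '.' decimal, seconds / microvolts)

#' Read an LFP recording from disk
#'
#' Supported formats: two-column CSV with header `time,amplitude` (seconds,
#' microvolts, uniform spacing enforced to 1 ppm) and single-channel EDF
#' (European Data Format; amplitudes converted to microvolts from the file's
#' physical-dimension field). The reader never resamples: the returned
#' recording has exactly as many samples as the file.
#'
#' @param path File to read.
#' @param format `"auto"` (by extension), `"csv"` or `"edf"`.
#' @return An [lfp_recording()].
#' @export
read_lfp <- function(path, format = c("auto", "csv", "edf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  switch(format, csv = read_lfp_csv(path), edf = read_lfp_edf(path))
}

read_lfp_csv <- function(path) {
  # base-R reader: correctly rounded strtod parsing makes the %.17g
  # write/read round-trip bitwise
  df <- utils::read.csv(path, colClasses = "numeric", check.names = FALSE)
  if (!identical(names(df)[1:2], c("time", "amplitude")) || ncol(df) != 2L) {
    stop("malformed LFP csv: expected header 'time,amplitude'", call. = FALSE)
  }
  if (nrow(df) < 2L) {
    stop("LFP csv needs at least two rows to infer the sampling rate", call. = FALSE)
  }
  dt <- diff(df$time)
  dt0 <- stats::median(dt)
  if (dt0 <= 0 || any(abs(dt - dt0) > 1e-6 * dt0)) {
    stop("non-uniform sample spacing in csv (tolerance 1 ppm)", call. = FALSE)
  }
  lfp_recording(df$amplitude, fs = 1 / dt0, t0 = df$time[1],
    label = sub("\\.[^.]*$", "", basename(path))
  )
}

#' Write an LFP recording to disk
#'
#' CSV output stores full-precision decimals (`%.17g`) so a read/write
#' round-trip reproduces the samples bitwise. EDF output quantizes to 16 bits
#' over the declared physical range, so the round-trip error is at most
#' `range / 2^16`.
#'
#' @param rec An [lfp_recording()].
#' @param path Output file.
#' @param format `"auto"`, `"csv"` or `"edf"`. EDF requires an integer `fs`.
#' @return `path`, invisibly.
#' @export
write_lfp <- function(rec, path, format = c("auto", "csv", "edf")) {
  stopifnot(inherits(rec, "lfp_recording"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  switch(format, csv = write_lfp_csv(rec, path), edf = write_lfp_edf(rec, path))
  invisible(path)
}

write_lfp_csv <- function(rec, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("time,amplitude", con)
  writeLines(
    sprintf("%.17g,%.17g", lfp_times(rec), rec$samples),
    con
  )
}

# ---------------------------------------------------------------------------
# EDF I/O. Minimal single-channel EDF: 256-byte fixed header + 256-byte signal
# header, data records of 16-bit little-endian integers. The true sample count
# and t0 are carried in the reserved header field ("CLTUS n t0") because EDF
# pads the final record; foreign readers see a padded but valid file.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

write_lfp_edf <- function(rec, path) {
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) {
    stop("EDF output requires an integer sampling rate; use csv", call. = FALSE)
  }
  fs <- as.integer(round(fs))
  n <- length(rec$samples)
  n_rec <- ceiling(n / fs)
  pad <- n_rec * fs - n
  x <- c(rec$samples, rep(rec$samples[n], pad))
  pmin_ <- min(x); pmax_ <- max(x)
  if (pmax_ - pmin_ < 1e-12) { # constant signal: widen the range artificially
    pmin_ <- pmin_ - 1; pmax_ <- pmax_ + 1
  }
  dmin <- -32768L; dmax <- 32767L
  dig <- as.integer(round((x - pmin_) / (pmax_ - pmin_) * (dmax - dmin) + dmin))
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),
    edf_pad(paste("Startdate X X X", rec$label), 80),
    edf_pad("01.01.00", 8),
    edf_pad("00.00.00", 8),
    edf_pad(512, 8),
    edf_pad(sprintf("CLTUS %d %.9g", n, rec$t0), 44),
    edf_pad(n_rec, 8),
    edf_pad(1, 8),
    edf_pad(1, 4),
    # per-signal fields
    edf_pad(rec$label, 16),
    edf_pad("", 80),
    edf_pad("uV", 8),
    edf_pad(sprintf("%.8g", pmin_), 8),
    edf_pad(sprintf("%.8g", pmax_), 8),
    edf_pad(dmin, 8),
    edf_pad(dmax, 8),
    edf_pad("", 80),
    edf_pad(fs, 8),
    edf_pad("", 32)
  )
  writeChar(hdr, con, nchars = nchar(hdr), eos = NULL)
  writeBin(dig, con, size = 2L, endian = "little")
}

read_lfp_edf <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  rd <- function(nc) readChar(con, nc, useBytes = TRUE)
  rd(8) # version
  rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8))
  reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L || is.na(n_rec) || is.na(rec_dur)) {
    stop("malformed EDF header", call. = FALSE)
  }
  if (ns != 1L) stop("only single-channel EDF files are supported", call. = FALSE)
  label <- trimws(rd(16))
  rd(80)
  dim_ <- trimws(rd(8))
  pmin_ <- as.numeric(rd(8)); pmax_ <- as.numeric(rd(8))
  dmin <- as.numeric(rd(8)); dmax <- as.numeric(rd(8))
  rd(80)
  spr <- as.integer(rd(8))
  rd(32)
  if (anyNA(c(pmin_, pmax_, dmin, dmax, spr)) || hdr_bytes != 512L) {
    stop("malformed EDF signal header", call. = FALSE)
  }
  dig <- readBin(con, integer(), n = n_rec * spr, size = 2L, signed = TRUE,
    endian = "little"
  )
  if (length(dig) != n_rec * spr) stop("truncated EDF data section", call. = FALSE)
  x <- (dig - dmin) / (dmax - dmin) * (pmax_ - pmin_) + pmin_
  # unit conversion to microvolts
  scale <- switch(tolower(dim_), uv = 1, mv = 1e3, v = 1e6, 1)
  x <- x * scale
  n <- length(x); t0 <- 0
  m <- regmatches(reserved, regexec("CLTUS ([0-9]+) ([-0-9.eE+]+)", reserved))[[1]]
  if (length(m) == 3L) {
    n <- as.integer(m[2]); t0 <- as.numeric(m[3])
    x <- x[seq_len(n)]
  }
  lfp_recording(x, fs = spr / rec_dur, t0 = t0, label = label)
}

# ---------------------------------------------------------------------------
# Event tables

.event_kinds <- c("trigger", "seizure_onset", "seizure_offset", "stim_on", "stim_off")

#' Construct and validate an event table
#'
#' Events are timestamped markers: stimulation triggers, seizure onsets and
#' offsets, stimulation on/off. Times are seconds from the recording origin.
#' Within each kind times must be non-decreasing, and seizure onsets/offsets
#' must strictly alternate starting with an onset (a final unmatched onset is
#' permitted for recordings that end mid-seizure).
#'
#' @param time_s Numeric event times (s).
#' @param kind Character, one of `r paste(shQuote(.event_kinds), collapse = ", ")`.
#' @param payload Free-text annotation (default `""`).
#' @return A tibble with columns `time_s`, `kind`, `payload`.
#' @export
event_table <- function(time_s = numeric(), kind = character(), payload = "") {
  tbl <- tibble::tibble(
    time_s = as.numeric(time_s),
    kind = as.character(kind),
    payload = rep_len(as.character(payload), length(time_s))
  )
  validate_events(tbl)
}

#' Validate an event table's invariants
#' @param events A tibble with columns `time_s`, `kind`, `payload`.
#' @return The validated tibble (payload filled with `""` if absent).
#' @export
validate_events <- function(events) {
  if (!all(c("time_s", "kind") %in% names(events))) {
    stop("event table must have columns time_s and kind", call. = FALSE)
  }
  if (!"payload" %in% names(events)) events$payload <- ""
  events <- tibble::as_tibble(events[, c("time_s", "kind", "payload")])
  bad <- setdiff(unique(events$kind), .event_kinds)
  if (length(bad)) {
    stop("unknown event kind(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  for (k in unique(events$kind)) {
    tk <- events$time_s[events$kind == k]
    if (is.unsorted(tk)) {
      stop("event times must be non-decreasing within kind '", k, "'", call. = FALSE)
    }
  }
  sz <- events[events$kind %in% c("seizure_onset", "seizure_offset"), ]
  sz <- sz[order(sz$time_s), ]
  expect_on <- TRUE
  for (k in sz$kind) {
    if (expect_on && k != "seizure_onset") {
      stop("seizure_offset without a preceding seizure_onset", call. = FALSE)
    }
    if (!expect_on && k != "seizure_offset") {
      stop("consecutive seizure_onset events without an offset", call. = FALSE)
    }
    expect_on <- !expect_on
  }
  events
}

#' Read / write event tables
#'
#' CSV with header `time_s,kind,payload`; invariants are enforced on read.
#'
#' @param path File path.
#' @return `read_events()` returns a validated event tibble.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, col_types = readr::cols(
    time_s = readr::col_double(),
    kind = readr::col_character(),
    payload = readr::col_character()
  ), progress = FALSE)
  df$payload[is.na(df$payload)] <- ""
  validate_events(df)
}

#' @param events A validated event tibble.
#' @rdname read_events
#' @export
write_events <- function(events, path) {
  events <- validate_events(events)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("time_s,kind,payload", con)
  if (nrow(events)) {
    writeLines(sprintf("%.17g,%s,%s", events$time_s, events$kind, events$payload), con)
  }
  invisible(path)
}

#' Seizure intervals from an event table
#'
#' @param events Event tibble containing alternating `seizure_onset` /
#'   `seizure_offset` rows.
#' @param require_matched Error on a trailing unmatched onset (default TRUE).
#' @return Tibble with columns `onset`, `offset`, `duration` (s).
#' @export
seizure_intervals <- function(events, require_matched = TRUE) {
  events <- validate_events(events)
  on <- sort(events$time_s[events$kind == "seizure_onset"])
  off <- sort(events$time_s[events$kind == "seizure_offset"])
  if (length(on) == length(off) + 1L) {
    if (require_matched) stop("unmatched seizure_onset at ", on[length(on)], call. = FALSE)
    on <- on[-length(on)]
  }
  tibble::tibble(onset = on, offset = off, duration = off - on)
}
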