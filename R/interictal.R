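#' Ripple-band envelope of an interictal recording
#'
#' Notch-filters (50 Hz, Q = `notch_q`), band-passes to the ripple band
#' (default 80-250 Hz; user-adjustable), and takes the modulus of the
#' analytic signal (Hilbert transform) per channel. The per-channel envelope
#' medians and the pooled global median (over all channels and samples) are
#' stored for the synergistic event threshold.
#'
#' @param recording A [seeg_recording]; `fs` must exceed twice the band's
#'   upper edge.
#' @param band Ripple band edges (Hz).
#' @param notch Mains frequency (Hz).
#' @param notch_q Notch quality factor.
#' @param order Butterworth order.
#' @return A `seeg_envelope`: `values` (channels x samples, >= 0), `fs`,
#'   `channel_names`, `channel_median` (per channel), `global_median`
#'   (pooled).
#' @export
ripple_envelope <- function(recording, band = c(80, 250), notch = 50,
                            notch_q = 30, order = 5L) {
  stopifnot(inherits(recording, "seeg_recording"))
  filt <- filter_bandpass_rows(recording$signal, recording$fs, band, order,
                               notch, notch_q)
  env <- analytic_envelope_rows(filt)
  structure(list(values = env, fs = recording$fs,
                 channel_names = recording$channel_names,
                 channel_median = apply(env, 1, stats::median),
                 global_median = stats::median(env)),
            class = "seeg_envelope")
}

#' Synergistic per-channel event threshold
#'
#' `threshold_i = 2 * max(median(envelope_i), median(envelope_global))`: a
#' channel's own median guards against locally noisy channels, while the
#' pooled median stops a quiet channel's threshold from collapsing.
#'
#' @param envelope A `seeg_envelope` from [ripple_envelope].
#' @return Named numeric vector of per-channel thresholds.
#' @export
event_threshold <- function(envelope) {
  stopifnot(inherits(envelope, "seeg_envelope"))
  thr <- 2 * pmax(envelope$channel_median, envelope$global_median)
  names(thr) <- envelope$channel_names
  thr
}

#' Supra-threshold event extraction with gap merging and duration filtering
#'
#' Per channel: extract maximal runs of samples whose envelope strictly
#' exceeds the threshold, merge adjacent runs separated by less than
#' `merge_gap_ms` (iterated to stability, so chains of close runs collapse
#' into one event), then discard events shorter than `min_duration_ms`. The
#' order is fixed - merge first, filter second - because the two orders give
#' different counts. A channel whose threshold is 0 (flat-zero envelope) is
#' degenerate and emits no events.
#'
#' @param envelope A `seeg_envelope`.
#' @param thresholds Per-channel thresholds (default [event_threshold]).
#' @param merge_gap_ms Gaps below this merge (ms).
#' @param min_duration_ms Events below this are excluded (ms).
#' @return A `seeg_events` object: `events`, a list (one per channel) of
#'   two-column matrices `start_s`, `end_s` (half-open, seconds);
#'   `thresholds`; `fs`; `duration_s`; `channel_names`.
#' @export
detect_events <- function(envelope, thresholds = event_threshold(envelope),
                          merge_gap_ms = 20, min_duration_ms = 50) {
  stopifnot(inherits(envelope, "seeg_envelope"))
  if (length(thresholds) != nrow(envelope$values))
    stop_seeg("bad_thresholds", "need one threshold per channel")
  fs <- envelope$fs
  gap <- merge_gap_ms / 1000 * fs
  min_len <- min_duration_ms / 1000 * fs
  evs <- lapply(seq_len(nrow(envelope$values)), function(ch) {
    if (thresholds[ch] <= 0)
      return(matrix(numeric(), 0, 2,
                    dimnames = list(NULL, c("start_s", "end_s"))))
    runs <- supra_runs(envelope$values[ch, ] > thresholds[ch])
    runs <- merge_close_runs(runs, gap)
    runs <- runs[runs[, 2] - runs[, 1] >= min_len, , drop = FALSE]
    matrix(runs / fs, ncol = 2,
           dimnames = list(NULL, c("start_s", "end_s")))
  })
  structure(list(events = evs, thresholds = thresholds, fs = fs,
                 duration_s = ncol(envelope$values) / fs,
                 channel_names = envelope$channel_names),
            class = "seeg_events")
}

# Maximal TRUE runs of a logical vector as half-open 0-based sample intervals.
supra_runs <- function(above) {
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  cbind(starts[r$values], ends[r$values])
}

# Merge intervals whose gap is strictly below `gap` samples. A single sweep
# over sorted intervals is transitive, hence already stable.
merge_close_runs <- function(runs, gap) {
  if (nrow(runs) <= 1L) return(runs)
  out <- runs[1, , drop = FALSE]
  for (i in 2:nrow(runs)) {
    if (runs[i, 1] - out[nrow(out), 2] < gap)
      out[nrow(out), 2] <- runs[i, 2]
    else out <- rbind(out, runs[i, ])
  }
  out
}

#' High-Frequency Events Index
#'
#' The per-channel count of detected interictal high-frequency events, used
#' as a relative marker of seizure-onset-zone likelihood, plus a
#' per-minute rate for convenience.
#'
#' @param events A `seeg_events` from [detect_events].
#' @param duration_s Recording duration in seconds (default: taken from
#'   `events`).
#' @return A `seeg_hi` data frame: `channel`, `HI`, `rate_per_min`.
#' @export
compute_hi <- function(events, duration_s = events$duration_s) {
  stopifnot(inherits(events, "seeg_events"))
  if (duration_s <= 0) stop_seeg("bad_duration", "duration_s must be > 0")
  hi <- vapply(events$events, nrow, integer(1))
  out <- data.frame(channel = events$channel_names, HI = hi,
                    rate_per_min = hi * 60 / duration_s)
  class(out) <- c("seeg_hi", class(out))
  out
}

#' One-call High-Frequency Events Index pipeline
#'
#' Envelope extraction, synergistic thresholding, event detection, and
#' counting, with parameters from a [seeg_config]. Long recordings are
#' processed in one pass; the FFT-based envelope handles desk-scale inputs
#' directly.
#'
#' @param recording A [seeg_recording].
#' @param config A [seeg_config].
#' @return A list with `hi` (a `seeg_hi` data frame) and `events`
#'   (a `seeg_events`).
#' @export
hfo_index <- function(recording, config = seeg_config()) {
  env <- ripple_envelope(recording, band = config$ripple_band,
                         notch = config$notch_hz, notch_q = config$notch_q,
                         order = config$filter_order)
  ev <- detect_events(env, merge_gap_ms = config$merge_gap_ms,
                      min_duration_ms = config$min_duration_ms)
  list(hi = compute_hi(ev), events = ev)
}
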