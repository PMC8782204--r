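#' High-gamma band-pass filtering of a seizure recording
#'
#' Applies a 50 Hz notch (second-order IIR, quality factor `notch_q`)
#' followed by a Butterworth band-pass of the given order, both zero-phase
#' (forward-backward), channel by channel. Zero-phase filtering is used so
#' that the filters add no group delay that would bias onset times.
#'
#' @param recording A [seeg_recording].
#' @param band High-gamma band edges in Hz (default 60-140).
#' @param notch Mains frequency to notch out (Hz).
#' @param order Butterworth order.
#' @param notch_q Notch quality factor.
#' @return A filtered [seeg_recording] of the same shape and rate.
#' @export
bandpass_highgamma <- function(recording, band = c(60, 140), notch = 50,
                               order = 5L, notch_q = 30) {
  stopifnot(inherits(recording, "seeg_recording"))
  filt <- filter_bandpass_rows(recording$signal, recording$fs, band, order,
                               notch, notch_q)
  seeg_recording(filt, recording$fs, recording$channel_names)
}

#' Normalized high-frequency energy (NHFE)
#'
#' Squares the filtered signal sample-wise, smooths it with a centered
#' moving average (`window_ms`, stepping one sample; the window shrinks at
#' the recording edges), and divides each channel by its mean smoothed
#' energy over the baseline segment. Baseline NHFE therefore averages 1 per
#' channel, and the measure is invariant to any overall amplitude scaling of
#' the recording.
#'
#' @param filtered A band-passed [seeg_recording] (see [bandpass_highgamma]).
#' @param segments A [segment_spec]; the baseline segment defines the
#'   normalizer.
#' @param window_ms Smoothing window length in ms.
#' @return A `seeg_nhfe` object: `values` (channels x samples, dimensionless,
#'   aligned sample-for-sample with the input), `fs`, `channel_names`,
#'   `segments`.
#' @export
compute_nhfe <- function(filtered, segments, window_ms = 500) {
  stopifnot(inherits(filtered, "seeg_recording"),
            inherits(segments, "seeg_segments"))
  if (segments$target[2] > n_samples(filtered))
    stop_seeg("segment_bounds", "target extends past the end of the recording")
  width <- round(window_ms / 1000 * filtered$fs)
  bl <- (segments$baseline[1] + 1L):segments$baseline[2]   # half-open, 0-based
  energy <- filtered$signal^2
  vals <- t(apply(energy, 1, moving_average_centered, width = width))
  bl_mean <- rowMeans(vals[, bl, drop = FALSE])
  bad <- which(bl_mean <= 0)
  if (length(bad))
    stop_seeg("zero_baseline",
              "zero baseline energy in channel(s): ",
              paste(filtered$channel_names[bad], collapse = ", "))
  structure(list(values = vals / bl_mean, fs = filtered$fs,
                 channel_names = filtered$channel_names, segments = segments),
            class = "seeg_nhfe")
}

#' Per-channel onset detection against a baseline-derived threshold
#'
#' Each channel's threshold is the maximum of its baseline NHFE plus
#' `k_sigma` baseline standard deviations (sample SD, n-1 denominator). The
#' onset is the first target-segment sample whose NHFE strictly exceeds the
#' threshold; channels that never exceed it have no onset. Onset channels
#' are ranked 1..m by onset sample, ties broken by channel order.
#'
#' @param nhfe A `seeg_nhfe` from [compute_nhfe].
#' @param segments A [segment_spec]; defaults to the one stored in `nhfe`.
#' @param k_sigma Threshold multiplier on the baseline SD.
#' @return A `seeg_onsets` data frame: `channel`, `threshold`,
#'   `onset_sample` (0-based, NA if none), `onset_s`, `rank` (NA if none).
#' @export
detect_onsets <- function(nhfe, segments = nhfe$segments, k_sigma = 10) {
  stopifnot(inherits(nhfe, "seeg_nhfe"))
  bl <- (segments$baseline[1] + 1L):segments$baseline[2]
  tg <- (segments$target[1] + 1L):segments$target[2]
  if (length(bl) < 2L)
    stop_seeg("bad_segment", "baseline needs at least 2 samples for an SD")
  nch <- nrow(nhfe$values)
  thr <- onset <- rep(NA_real_, nch)
  for (ch in seq_len(nch)) {
    b <- nhfe$values[ch, bl]
    thr[ch] <- max(b) + k_sigma * stats::sd(b)
    hit <- which(nhfe$values[ch, tg] > thr[ch])
    if (length(hit)) onset[ch] <- tg[hit[1]] - 1L   # back to 0-based
  }
  rank_ <- rep(NA_integer_, nch)
  has <- which(!is.na(onset))
  if (length(has)) {
    ord <- has[order(onset[has], has)]              # ties: channel order
    rank_[ord] <- seq_along(ord)
  }
  out <- data.frame(channel = nhfe$channel_names, threshold = thr,
                    onset_sample = onset, onset_s = onset / nhfe$fs,
                    rank = rank_)
  class(out) <- c("seeg_onsets", class(out))
  out
}

#' Epileptogenicity Index
#'
#' Combines, per channel, the timing and the strength of the high-gamma
#' energy change at seizure onset: the time coefficient `TC = 1/rank` of the
#' channel's onset (0 for channels with no onset) and the energy coefficient
#' `EC`, the mean NHFE over a window of `ec_window_ms` starting at the
#' globally earliest onset. The index is `EI = TC * EC`, so the
#' earliest-onset channel keeps its full energy term and later channels are
#' progressively discounted.
#'
#' @param nhfe A `seeg_nhfe`.
#' @param onsets A `seeg_onsets` from [detect_onsets].
#' @param ec_window_ms Energy-coefficient window length (ms), anchored at
#'   the earliest onset; truncated with a warning if it runs past the end of
#'   the recording.
#' @return A `seeg_ei` data frame in channel order: `channel`, `threshold`,
#'   `onset_s`, `rank`, `TC`, `EC`, `EI`. Channels without onset have
#'   `TC = EI = 0`. If no channel has an onset, all EI are 0 (with a
#'   warning).
#' @export
compute_ei <- function(nhfe, onsets, ec_window_ms = 250) {
  stopifnot(inherits(nhfe, "seeg_nhfe"))
  nch <- nrow(nhfe$values)
  tc <- ifelse(is.na(onsets$rank), 0, 1 / onsets$rank)
  if (all(is.na(onsets$onset_sample))) {
    warning("no channel crossed its onset threshold; all EI set to 0")
    ec <- rep(0, nch)
  } else {
    t0 <- min(onsets$onset_sample, na.rm = TRUE)
    w <- round(ec_window_ms / 1000 * nhfe$fs)
    end <- t0 + w
    if (end > ncol(nhfe$values)) {
      warning("EC window truncated at the end of the recording")
      end <- ncol(nhfe$values)
    }
    win <- (t0 + 1L):end                      # 0-based [t0, end)
    ec <- rowMeans(nhfe$values[, win, drop = FALSE])
  }
  out <- data.frame(channel = onsets$channel, threshold = onsets$threshold,
                    onset_s = onsets$onset_s, rank = onsets$rank,
                    TC = tc, EC = ec, EI = tc * ec)
  class(out) <- c("seeg_ei", class(out))
  out
}

#' @export
print.seeg_ei <- function(x, ...) {
  cat("Epileptogenicity Index (sorted by EI):\n")
  print.data.frame(x[order(-x$EI), ], row.names = FALSE, digits = 4)
  invisible(x)
}

#' One-call Epileptogenicity Index pipeline
#'
#' Filter to the high-gamma band, compute NHFE, detect onsets, and compute
#' EI, all with parameters from a [seeg_config].
#'
#' @param recording A [seeg_recording] covering baseline and seizure onset.
#' @param segments A [segment_spec] with manually chosen baseline and target
#'   windows.
#' @param config A [seeg_config].
#' @return A `seeg_ei` data frame (see [compute_ei]).
#' @export
epileptogenicity_index <- function(recording, segments,
                                   config = seeg_config()) {
  filt <- bandpass_highgamma(recording, band = config$highgamma_band,
                             notch = config$notch_hz,
                             order = config$filter_order,
                             notch_q = config$notch_q)
  nhfe <- compute_nhfe(filt, segments, window_ms = config$smooth_window_ms)
  onsets <- detect_onsets(nhfe, segments, k_sigma = config$k_sigma)
  compute_ei(nhfe, onsets, ec_window_ms = config$ec_window_ms)
}
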