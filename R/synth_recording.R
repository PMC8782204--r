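# Pink (1/f-power) noise via FFT spectral shaping; flat below 1 Hz so the
# variance stays finite.
pink_noise <- function(n, fs) {
  w <- stats::rnorm(n)
  f <- c(1e-9, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  h <- 1 / sqrt(pmax(f, 1))
  Re(stats::fft(stats::fft(w) * h, inverse = TRUE) / n)
}

#' Synthetic ictal SEEG recording with planted high-gamma onsets
#'
#' Generates independent pink-noise baselines per channel; from each
#' seizure-onset-zone (SOZ) channel's onset time, adds band-limited 60-140 Hz
#' noise whose amplitude ramps up smoothly (saturating exponential, time
#' constant `ramp_tau_s`), emulating the growing high-gamma discharge at
#' seizure onset. Non-SOZ channels receive no onset. SOZ onsets are staggered
#' by `onset_lags_s` so the true onset order is known.
#'
#' @param n_channels Number of channels.
#' @param fs Sampling rate (Hz, >= 500).
#' @param duration_s Total duration (s).
#' @param soz_channels Indices (or names `chN`) of SOZ channels.
#' @param onset_time_s Onset time of the earliest SOZ channel (s).
#' @param onset_lags_s Per-SOZ-channel lags added to `onset_time_s`
#'   (same length as `soz_channels`).
#' @param snr Plateau amplitude of the planted high-gamma burst relative to
#'   the channel's baseline 60-140 Hz RMS.
#' @param ramp_tau_s Ramp time constant (s).
#' @param seed Integer seed; generation is deterministic given all arguments.
#' @return List with `recording` (a [seeg_recording]) and `truth`
#'   (`seeg_truth` with `soz_channels` as names and `onset_times` in s,
#'   NA for non-SOZ channels).
#' @export
synth_ictal_recording <- function(n_channels = 12L, fs = 1000, duration_s = 60,
                                  soz_channels = 1:3, onset_time_s = 30,
                                  onset_lags_s = NULL, snr = 5,
                                  ramp_tau_s = 1.0, seed = 1L) {
  if (fs < 500) stop_seeg("bad_fs", "ictal generator requires fs >= 500 Hz")
  ch_names <- paste0("ch", seq_len(n_channels))
  if (is.character(soz_channels)) soz_channels <- match(soz_channels, ch_names)
  if (anyNA(soz_channels) || any(soz_channels < 1 | soz_channels > n_channels))
    stop_seeg("bad_soz", "soz_channels outside the channel set")
  if (is.null(onset_lags_s))
    onset_lags_s <- (seq_along(soz_channels) - 1) * 0.5
  if (length(onset_lags_s) != length(soz_channels))
    stop_seeg("bad_soz", "need one onset lag per SOZ channel")
  onsets <- onset_time_s + onset_lags_s
  if (any(onsets < 0 | onsets >= duration_s))
    stop_seeg("onset_outside", "onset time outside the recording")
  n <- round(duration_s * fs)
  with_seed(seed, {
    sig <- t(vapply(seq_len(n_channels), function(ch) pink_noise(n, fs),
                    numeric(n)))
    bp <- signal::butter(4, c(60, 140) / (fs / 2), type = "pass")
    onset_times <- rep(NA_real_, n_channels)
    for (i in seq_along(soz_channels)) {
      ch <- soz_channels[i]
      base_rms <- stats::sd(signal::filtfilt(bp, sig[ch, ]))
      burst <- signal::filtfilt(bp, stats::rnorm(n))
      burst <- burst / stats::sd(burst)
      t_rel <- (seq_len(n) - 1) / fs - onsets[i]
      ramp <- ifelse(t_rel < 0, 0, 1 - exp(-t_rel / ramp_tau_s))
      sig[ch, ] <- sig[ch, ] + snr * base_rms * ramp * burst
      onset_times[ch] <- onsets[i]
    }
    truth <- structure(list(soz_channels = ch_names[soz_channels],
                            onset_times = stats::setNames(onset_times,
                                                          ch_names)),
                       class = "seeg_truth")
    list(recording = seeg_recording(sig, fs, ch_names), truth = truth)
  })
}

#' Synthetic interictal SEEG recording with planted ripple bursts
#'
#' Pink-noise background per channel, plus planted ripple-band bursts:
#' Tukey-windowed (flat-plateau) sinusoids with carrier frequencies drawn in
#' 100-200 Hz and durations in 60-150 ms, at least `min_gap_ms` apart within
#' a channel. Each channel's burst amplitude is calibrated on its own
#' pre-burst background so that the mean ripple-band envelope inside a
#' planted interval is `event_snr` times the channel's envelope median.
#'
#' @param n_channels Number of channels.
#' @param fs Sampling rate (Hz, > 500).
#' @param duration_s Recording length (s).
#' @param events_per_channel Number of bursts planted per channel; a vector
#'   recycles over channels, so e.g. `c(12, 0)` alternates active and silent
#'   channels. Requested counts incompatible with the gap constraint raise
#'   `seeg_rate_too_high`.
#' @param event_snr Target ratio of in-event mean envelope to the channel's
#'   envelope median.
#' @param min_gap_ms Minimum inter-event gap within a channel.
#' @param event_times Optional fixture override: list (one per channel) of
#'   two-column matrices of event start/end seconds, bypassing random
#'   placement and the gap rule (used to exercise the detector's merge
#'   logic).
#' @param seed Integer seed.
#' @return List with `recording` and `truth` (`seeg_truth` whose
#'   `event_times` is a per-channel list of `[start_s, end_s)` matrices).
#' @export
synth_interictal_recording <- function(n_channels = 8L, fs = 1000,
                                       duration_s = 60,
                                       events_per_channel = 20L,
                                       event_snr = 5, min_gap_ms = 100,
                                       event_times = NULL, seed = 1L) {
  if (fs <= 500) stop_seeg("bad_fs", "interictal generator requires fs > 500")
  ch_names <- paste0("ch", seq_len(n_channels))
  n <- round(duration_s * fs)
  counts <- rep_len(as.integer(events_per_channel), n_channels)
  with_seed(seed, {
    sig <- t(vapply(seq_len(n_channels), function(ch) pink_noise(n, fs),
                    numeric(n)))
    planted <- vector("list", n_channels)
    for (ch in seq_len(n_channels)) {
      if (is.null(event_times)) {
        iv <- place_events(counts[ch], duration_s, min_gap_ms / 1000)
      } else {
        iv <- event_times[[ch]]
        if (is.null(iv)) iv <- matrix(numeric(), 0, 2)
      }
      planted[[ch]] <- matrix(iv, ncol = 2,
                              dimnames = list(NULL, c("start_s", "end_s")))
      if (nrow(iv) == 0) next
      # calibrate on this channel's own background envelope
      med0 <- stats::median(ripple_envelope(
        seeg_recording(sig[ch, , drop = FALSE], fs, "tmp"))$values)
      for (e in seq_len(nrow(iv))) {
        i0 <- round(iv[e, 1] * fs) + 1L
        i1 <- min(round(iv[e, 2] * fs), n)
        len <- i1 - i0 + 1L
        if (len < 4L) next
        fc <- stats::runif(1, 100, 200)
        tt <- seq_len(len)
        win <- tukey_window(len, 0.5)
        # mean envelope over the interval ~ amp * mean(win); aim just above
        # the requested multiple of the median
        amp <- 1.1 * event_snr * med0 / mean(win)
        sig[ch, i0:i1] <- sig[ch, i0:i1] +
          amp * win * sin(2 * pi * fc * tt / fs + stats::runif(1, 0, 2 * pi))
      }
    }
    truth <- structure(list(soz_channels = ch_names[counts > 0],
                            event_times = stats::setNames(planted, ch_names)),
                       class = "seeg_truth")
    list(recording = seeg_recording(sig, fs, ch_names), truth = truth)
  })
}

# Draw k non-overlapping [start, end) intervals (durations 60-150 ms) with
# inter-event gaps >= gap_s, uniformly over (1, duration-1) s.
place_events <- function(k, duration_s, gap_s) {
  if (k == 0L) return(matrix(numeric(), 0, 2))
  max_dur <- 0.150
  need <- k * (max_dur + gap_s)
  if (need > duration_s - 2)
    stop_seeg("rate_too_high", k, " events do not fit in ", duration_s,
              " s with ", gap_s, " s gaps")
  for (try in 1:200) {
    starts <- sort(stats::runif(k, 1, duration_s - 1 - max_dur))
    durs <- stats::runif(k, 0.060, 0.150)
    if (k == 1L || all(diff(starts) >= durs[-k] + gap_s))
      return(cbind(starts, starts + durs))
  }
  # fall back to an evenly spaced grid with jitter
  slot <- (duration_s - 2) / k
  starts <- 1 + (seq_len(k) - 1) * slot +
    stats::runif(k, 0, max(0, slot - max_dur - gap_s))
  durs <- stats::runif(k, 0.060, 0.150)
  cbind(starts, starts + durs)
}

# Tukey (tapered cosine) window: flat central plateau, cosine ramps over
# alpha/2 of each end.
tukey_window <- function(n, alpha = 0.5) {
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < alpha / 2
  hi <- t > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - t[hi]) / alpha - 1)))
  w
}
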