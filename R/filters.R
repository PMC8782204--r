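# Shared DSP primitives for the ictal and interictal paths.

# Second-order IIR notch biquad (continuous-time prototype bilinear-mapped):
# unit gain everywhere except a notch of quality factor Q at f0.
design_notch <- function(f0, fs, q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# Zero-phase (forward-backward) notch + Butterworth band-pass applied per
# channel. Zero-phase filtering avoids the group delay a causal filter would
# add, which matters because onset *times* are the quantity of interest.
filter_bandpass_rows <- function(signal, fs, band, order, notch_hz, notch_q) {
  if (fs <= 2 * band[2])
    stop_seeg("fs_too_low", "sampling rate ", fs,
              " Hz cannot support a band up to ", band[2], " Hz")
  if (band[1] <= 0 || band[1] >= band[2])
    stop_seeg("bad_band", "band edges must satisfy 0 < low < high")
  nt <- design_notch(notch_hz, fs, notch_q)
  bp <- signal::butter(order, band / (fs / 2), type = "pass")
  out <- signal
  for (ch in seq_len(nrow(signal))) {
    x <- signal::filtfilt(filt = nt$b, a = nt$a, x = signal[ch, ])
    out[ch, ] <- signal::filtfilt(bp, x)
  }
  out
}

# Envelope (modulus) of the analytic signal, per row, via the FFT method.
analytic_envelope_rows <- function(signal) {
  n <- ncol(signal)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else if (n > 1) h[2:((n + 1) / 2)] <- 2
  out <- signal
  for (ch in seq_len(nrow(signal)))
    out[ch, ] <- Mod(stats::fft(stats::fft(signal[ch, ]) * h,
                                inverse = TRUE) / n)
  out
}

# Centered moving average whose window shrinks at the edges (the mean is
# always over the in-range part of the window).
moving_average_centered <- function(x, width) {
  n <- length(x)
  width <- max(1L, as.integer(width))
  half_lo <- (width - 1L) %/% 2L
  half_hi <- width - 1L - half_lo
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - half_lo, 1L)
  hi <- pmin(i + half_hi, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
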