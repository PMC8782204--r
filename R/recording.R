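#' Multichannel SEEG recording
#'
#' A `seeg_recording` holds a channels x samples matrix in microvolts together
#' with its sampling rate and unique channel names (stored as row names).
#'
#' @param signal Numeric matrix, one row per channel (microvolts).
#' @param fs Sampling rate in Hz, > 0.
#' @param channel_names Character vector of unique names, one per row. Taken
#'   from `rownames(signal)` when omitted; defaults to `ch1, ch2, ...`.
#' @return An object of class `seeg_recording`.
#' @examples
#' rec <- seeg_recording(matrix(rnorm(2000), nrow = 2), fs = 1000)
#' n_samples(rec)
#' @export
seeg_recording <- function(signal, fs, channel_names = NULL) {
  signal <- as.matrix(signal)
  if (is.null(channel_names)) channel_names <- rownames(signal)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nrow(signal)))
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop_seeg("bad_fs", "sampling rate must be a single positive number")
  if (length(channel_names) != nrow(signal))
    stop_seeg("bad_channel_names", "need one channel name per signal row")
  if (anyDuplicated(channel_names))
    stop_seeg("duplicate_channels", "duplicate channel names: ",
              paste(unique(channel_names[duplicated(channel_names)]),
                    collapse = ", "))
  if (!all(is.finite(signal)))
    stop_seeg("nonfinite_samples", "recording contains non-finite samples")
  storage.mode(signal) <- "double"
  rownames(signal) <- channel_names
  structure(list(signal = signal, fs = fs, channel_names = channel_names),
            class = "seeg_recording")
}

#' @export
print.seeg_recording <- function(x, ...) {
  cat("<seeg_recording> ", nrow(x$signal), " channels x ", ncol(x$signal),
      " samples @ ", x$fs, " Hz (", signif(ncol(x$signal) / x$fs, 4),
      " s)\n", sep = "")
  invisible(x)
}

#' @rdname seeg_recording
#' @param recording A `seeg_recording`.
#' @export
n_samples <- function(recording) ncol(recording$signal)

#' Baseline and target windows of a recording
#'
#' Both windows are half-open 0-based sample intervals `[start, end)`; the
#' baseline must end at or before the target starts and both must lie inside
#' the recording.
#'
#' @param baseline,target Integer vectors `c(start, end)`, 0-based, half-open.
#' @param recording Optional [seeg_recording] to validate bounds against.
#' @return An object of class `seeg_segments`.
#' @export
segment_spec <- function(baseline, target, recording = NULL) {
  chk <- function(x, what) {
    if (length(x) != 2L || !all(is.finite(x)) || x[2] <= x[1] || x[1] < 0)
      stop_seeg("bad_segment", what, " must be a non-empty [start, end) pair")
    as.integer(round(x))
  }
  baseline <- chk(baseline, "baseline")
  target <- chk(target, "target")
  if (baseline[2] > target[1])
    stop_seeg("segment_order", "baseline must end before the target starts")
  if (!is.null(recording) && target[2] > n_samples(recording))
    stop_seeg("segment_bounds", "target extends past the end of the recording")
  structure(list(baseline = baseline, target = target),
            class = "seeg_segments")
}

#' Read an SEEG recording from EDF or delimited text
#'
#' The delimited dialect is UTF-8 tab-separated text with a header row of
#' channel names and one column per channel; the sampling rate is supplied by
#' the caller because the format does not carry one. EDF files carry their own
#' rate; all channels must share it.
#'
#' @param path Input file.
#' @param format `"edf"`, `"tsv"`, or `"auto"` (by file extension).
#' @param fs Sampling rate in Hz; required for `"tsv"`, ignored for `"edf"`.
#' @return A [seeg_recording] with channels in file order, units microvolts.
#' @export
read_recording <- function(path, format = c("auto", "edf", "tsv"), fs = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_seeg("recording_missing", "recording file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "tsv"
  if (format == "edf") return(read_edf(path))
  if (is.null(fs))
    stop_seeg("bad_fs", "fs must be supplied for delimited recordings")
  tab <- utils::read.delim(path, check.names = FALSE, encoding = "UTF-8")
  if (!all(vapply(tab, is.numeric, logical(1))))
    stop_seeg("nonnumeric_samples", "delimited recording has non-numeric samples")
  seeg_recording(t(as.matrix(tab)), fs = fs, channel_names = names(tab))
}

#' Write an SEEG recording
#'
#' @param recording A [seeg_recording].
#' @param path Output file.
#' @param format `"edf"`, `"tsv"`, or `"auto"` (by extension). EDF stores
#'   16-bit integers scaled to each channel's physical range, so values round
#'   trip only to within one quantization step.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, format = c("auto", "edf", "tsv")) {
  stopifnot(inherits(recording, "seeg_recording"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "tsv"
  if (format == "edf") return(write_edf(recording, path))
  tab <- as.data.frame(t(recording$signal))
  names(tab) <- recording$channel_names
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- minimal EDF (16-bit) reader/writer ------------------------------------
# Fixed-field ASCII header (256 bytes + 256 per signal), then data records of
# little-endian int16 samples scaled linearly between the digital and physical
# ranges. One record per second; requires an integer sampling rate.

# Render a number in at most 8 ASCII characters (EDF numeric field width).
edf_num8 <- function(v) {
  for (dig in 7:1) {
    s <- sprintf("%.*g", dig, v)
    if (nchar(s) <= 8) return(s)
  }
  sprintf("%.1e", v)
}

edf_pad <- function(x, width) {
  x <- substr(format(x, width = width), 1, width)
  formatC(x, width = width, flag = "-")
}

write_edf <- function(recording, path) {
  fs <- recording$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop_seeg("bad_fs", "EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  sig <- recording$signal
  ns <- nrow(sig)
  n_rec <- ceiling(ncol(sig) / fs)
  pad <- n_rec * fs - ncol(sig)
  if (pad > 0) sig <- cbind(sig, matrix(0, ns, pad))
  pmin_ <- apply(sig, 1, min); pmax_ <- apply(sig, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  # the physical range lives in 8-character ASCII header fields; widen it
  # slightly, render to 8 characters, and scale with the *parsed* header
  # values so writer and reader use the identical calibration
  pmin_chr <- vapply(pmin_ - abs(pmin_) * 1e-4 - 1e-6, edf_num8, character(1))
  pmax_chr <- vapply(pmax_ + abs(pmax_) * 1e-4 + 1e-6, edf_num8, character(1))
  pmin_ <- as.numeric(pmin_chr)
  pmax_ <- as.numeric(pmax_chr)
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(paste0(edf_pad(x, width), collapse = ""),
                                     con, eos = NULL)
  wr("0", 8)                                   # version
  wr("synthetic", 80); wr("synthetic", 80)     # patient / recording id
  wr("01.01.00", 8); wr("00.00.00", 8)         # start date / time
  wr(as.character(256L * (1L + ns)), 8)        # header bytes
  wr("", 44)                                   # reserved
  wr(as.character(n_rec), 8)                   # number of data records
  wr("1", 8)                                   # record duration (s)
  wr(as.character(ns), 4)                      # number of signals
  wr(recording$channel_names, 16)
  wr(rep("", ns), 80)                          # transducer
  wr(rep("uV", ns), 8)                         # physical dimension
  wr(pmin_chr, 8)
  wr(pmax_chr, 8)
  wr(rep(as.character(dmin), ns), 8)
  wr(rep(as.character(dmax), ns), 8)
  wr(rep("", ns), 80)                          # prefiltering
  wr(rep(as.character(fs), ns), 8)             # samples per record
  wr(rep("", ns), 32)                          # reserved
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- as.integer(round((sig[ch, idx] - pmin_[ch]) / scale[ch]) + dmin)
      writeBin(pmin(pmax(dig, dmin), dmax), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width, n = 1) {
    trimws(vapply(seq_len(n), function(i) readChar(con, width, useBytes = TRUE),
                  character(1)))
  }
  rd(8); rd(80); rd(80); rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- rd(16, ns)
  rd(80, ns); rd(8, ns)
  pmin_ <- as.numeric(rd(8, ns)); pmax_ <- as.numeric(rd(8, ns))
  dmin <- as.numeric(rd(8, ns)); dmax <- as.numeric(rd(8, ns))
  rd(80, ns)
  spr <- as.integer(rd(8, ns))
  rd(32, ns)
  if (length(unique(spr)) != 1L)
    stop_seeg("edf_mixed_rates", "EDF channels have differing sampling rates")
  fs <- spr[1] / rec_dur
  sig <- matrix(0, ns, n_rec * spr[1])
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2, signed = TRUE,
                     endian = "little")
      sig[ch, idx] <- (dig - dmin[ch]) * scale[ch] + pmin_[ch]
    }
  }
  seeg_recording(sig, fs = fs, channel_names = labels)
}
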