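make_rec <- function(sig, fs = 1000) seeg_recording(sig, fs)

test_that("high-gamma filter passes the band and rejects out-of-band tones", {
  fs <- 1000; t <- (0:9999) / fs
  z <- bandpass_highgamma(make_rec(matrix(0, 1, 10000)))
  expect_equal(max(abs(z$signal)), 0)
  in_band <- bandpass_highgamma(make_rec(matrix(sin(2 * pi * 100 * t), 1)))
  mid <- 3000:7000
  expect_gte(max(abs(in_band$signal[1, mid])), 0.9)
  out_band <- bandpass_highgamma(make_rec(matrix(sin(2 * pi * 10 * t), 1)))
  expect_lte(max(abs(out_band$signal[1, mid])), 0.1)
  notched <- bandpass_highgamma(make_rec(matrix(sin(2 * pi * 50 * t), 1)))
  expect_lte(max(abs(notched$signal[1, mid])), 0.1)
  expect_error(bandpass_highgamma(make_rec(matrix(0, 1, 100), fs = 200)),
               class = "seeg_fs_too_low")
})

test_that("NHFE normalizes baseline energy to one and is scale invariant", {
  set.seed(7)
  sig <- matrix(rnorm(2 * 20000), 2)
  rec <- make_rec(sig)
  seg <- segment_spec(c(0, 8000), c(10000, 20000), rec)
  filt <- bandpass_highgamma(rec)
  nh <- compute_nhfe(filt, seg)
  bl_means <- rowMeans(nh$values[, 1:8000])
  expect_equal(bl_means, c(1, 1), tolerance = 1e-9, ignore_attr = TRUE)
  # statistically identical target noise stays near 1
  expect_equal(rowMeans(nh$values[, 10001:20000]), c(1, 1), tolerance = 0.15,
               ignore_attr = TRUE)
  # doubling the amplitude changes nothing
  nh2 <- compute_nhfe(bandpass_highgamma(make_rec(2 * sig)), seg)
  expect_equal(nh2$values, nh$values, tolerance = 1e-10)
})

test_that("constant filtered signal gives NHFE identically one", {
  filt <- make_rec(matrix(3.2, 1, 5000))
  seg <- segment_spec(c(0, 2000), c(2500, 5000), filt)
  nh <- compute_nhfe(filt, seg)
  expect_equal(as.numeric(nh$values), rep(1, 5000), tolerance = 1e-12)
})

test_that("zero-energy baselines are reported by channel", {
  filt <- make_rec(rbind(rep(0, 5000), rnorm(5000)))
  seg <- segment_spec(c(0, 2000), c(2500, 5000), filt)
  expect_error(compute_nhfe(filt, seg), class = "seeg_zero_baseline")
})

test_that("onset thresholds follow max + k*sd of the baseline NHFE", {
  # construct an NHFE object directly: baseline samples {1,2,3} repeated
  vals <- matrix(rep(c(1, 2, 3), length.out = 300), 1)
  vals[1, 201:300] <- 14   # above max + 10*sd = 13
  nh <- structure(list(values = vals, fs = 100, channel_names = "ch1",
                       segments = segment_spec(c(0, 3), c(150, 300))),
                  class = "seeg_nhfe")
  on <- detect_onsets(nh, segment_spec(c(0, 3), c(150, 300)), k_sigma = 10)
  expect_equal(on$threshold, 3 + 10 * 1)   # sample sd of {1,2,3} is 1
  expect_equal(on$onset_sample, 200)        # first strict exceedance, 0-based
  # constant baseline: sd 0, threshold equals the constant
  vals2 <- matrix(2, 1, 300); vals2[1, 250] <- 2.001
  nh2 <- structure(list(values = vals2, fs = 100, channel_names = "ch1"),
                   class = "seeg_nhfe")
  on2 <- detect_onsets(nh2, segment_spec(c(0, 100), c(150, 300)))
  expect_equal(on2$threshold, 2)
  expect_equal(on2$onset_sample, 249)
  # never exceeding: no onset, no rank
  vals3 <- matrix(1, 1, 300)
  nh3 <- structure(list(values = vals3, fs = 100, channel_names = "ch1"),
                   class = "seeg_nhfe")
  on3 <- detect_onsets(nh3, segment_spec(c(0, 100), c(150, 300)))
  expect_true(is.na(on3$onset_sample) && is.na(on3$rank))
})

test_that("time coefficients are reciprocal ranks over onset channels", {
  vals <- matrix(1, 4, 1000)
  vals[1, 501:1000] <- 20   # earliest
  vals[2, 601:1000] <- 20
  vals[3, 701:1000] <- 20
  nh <- structure(list(values = vals, fs = 1000,
                       channel_names = paste0("ch", 1:4)),
                  class = "seeg_nhfe")
  seg <- segment_spec(c(0, 400), c(450, 1000))
  on <- detect_onsets(nh, seg)
  ei <- compute_ei(nh, on)
  expect_equal(ei$TC, c(1, 1/2, 1/3, 0))
  expect_equal(sort(ei$TC[1:3], decreasing = TRUE), 1 / (1:3))
  expect_equal(ei$EI, ei$TC * ei$EC)
  expect_equal(ei$EI[4], 0)
})

test_that("EC is the post-earliest-onset window mean and EI the product", {
  vals <- matrix(1, 2, 2000)
  vals[1, 1001:2000] <- 4   # rank 1, EC 4
  vals[2, 1201:2000] <- 2   # rank 2
  nh <- structure(list(values = vals, fs = 1000,
                       channel_names = c("A", "B")),
                  class = "seeg_nhfe")
  seg <- segment_spec(c(0, 800), c(900, 2000))
  on <- detect_onsets(nh, seg)
  ei <- compute_ei(nh, on, ec_window_ms = 250)
  # window [1000, 1250): channel A at 4 throughout; channel B at 1 for the
  # first 200 samples and 2 for the last 50: EC_B = (200*1 + 50*2)/250
  expect_equal(ei$EC[1], 4)
  expect_equal(ei$EC[2], 1.2)
  expect_equal(ei$EI, c(4, 0.6))
  # single onset channel: its EI equals its EC, others zero
  vals2 <- matrix(1, 3, 2000); vals2[2, 1001:2000] <- 4
  nh2 <- structure(list(values = vals2, fs = 1000,
                        channel_names = c("A", "B", "C")),
                   class = "seeg_nhfe")
  ei2 <- compute_ei(nh2, detect_onsets(nh2, seg))
  expect_equal(ei2$EI, c(0, 4, 0))
})

test_that("an EC window past the end of the recording truncates with warning", {
  vals <- matrix(1, 1, 1000)
  vals[1, 951:1000] <- 10
  nh <- structure(list(values = vals, fs = 1000, channel_names = "A"),
                  class = "seeg_nhfe")
  on <- detect_onsets(nh, segment_spec(c(0, 800), c(900, 1000)))
  expect_warning(ei <- compute_ei(nh, on, ec_window_ms = 250), "truncated")
  expect_equal(ei$EC, 10)
})

test_that("whole-recording amplitude scaling leaves every EI unchanged", {
  g <- synth_ictal_recording(n_channels = 6, duration_s = 30,
                             soz_channels = c(2, 5), onset_time_s = 15,
                             onset_lags_s = c(0, 1), seed = 31)
  seg <- segment_spec(c(0, 12000), c(13000, 30000), g$recording)
  e1 <- epileptogenicity_index(g$recording, seg)
  e2 <- epileptogenicity_index(
    seeg_recording(g$recording$signal * 37.5, g$recording$fs), seg)
  expect_equal(e1$EI, e2$EI, tolerance = 1e-8)
})

test_that("EI recovers the planted onset order on synthetic seizures", {
  hits <- 0; n_seeds <- 25
  for (s in seq_len(n_seeds)) {
    g <- synth_ictal_recording(n_channels = 6, duration_s = 24,
                               soz_channels = c(2, 4, 5), onset_time_s = 12,
                               onset_lags_s = c(0, 0.5, 1), snr = 5, seed = s)
    seg <- segment_spec(c(0, 10000), c(11000, 24000), g$recording)
    ei <- epileptogenicity_index(g$recording, seg)
    if (identical(order(-ei$EI)[1:3], c(2L, 4L, 5L))) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("pure-noise target segments rarely trigger onsets at 10 sigma", {
  frac <- vapply(1:15, function(s) {
    g <- synth_ictal_recording(n_channels = 6, duration_s = 24,
                               soz_channels = integer(0), seed = 400 + s)
    seg <- segment_spec(c(0, 10000), c(11000, 24000), g$recording)
    nh <- compute_nhfe(bandpass_highgamma(g$recording), seg)
    mean(!is.na(detect_onsets(nh, seg)$onset_sample))
  }, numeric(1))
  expect_lt(mean(frac), 0.05)
})
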