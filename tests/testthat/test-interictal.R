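test_that("ripple envelope tracks in-band amplitude and rejects out-of-band", {
  fs <- 1000; t <- (0:19999) / fs
  z <- ripple_envelope(seeg_recording(matrix(0, 1, 20000), fs))
  expect_equal(max(z$values), 0)
  expect_equal(z$global_median, 0)
  a <- ripple_envelope(seeg_recording(matrix(2.5 * sin(2 * pi * 150 * t), 1),
                                      fs))
  mid <- 5000:15000
  expect_equal(median(a$values[1, mid]), 2.5, tolerance = 0.05 * 2.5)
  b <- ripple_envelope(seeg_recording(matrix(2.5 * sin(2 * pi * 10 * t), 1),
                                      fs))
  expect_lte(max(b$values[1, mid]), 0.25)
  expect_error(ripple_envelope(seeg_recording(matrix(0, 1, 100), fs = 400)),
               class = "seeg_fs_too_low")
})

test_that("the synergistic threshold is twice the larger of the two medians", {
  # channel medians 1 and 3; pooled median 2
  v <- rbind(rep(c(0.5, 1.5), 500), rep(c(2.5, 3.5), 500))
  env <- make_envelope(v, fs = 1000)
  expect_equal(env$channel_median, c(1, 3))
  expect_equal(env$global_median, 2)
  expect_equal(unname(event_threshold(env)), c(4, 6))
  # identical channels collapse to the global median
  v2 <- rbind(rep(1, 100), rep(1, 100))
  expect_equal(unname(event_threshold(make_envelope(v2, 1000))), c(2, 2))
})

test_that("detector merges close events before the duration filter", {
  fs <- 1000
  env <- matrix(0.1, 1, 3000)
  burst <- function(env, from_ms, to_ms) {
    env[1, (from_ms + 1):to_ms] <- 10; env
  }
  # 60 ms + 10 ms gap + 60 ms -> one merged 130 ms event
  e1 <- burst(burst(env, 1000, 1060), 1070, 1130)
  ev1 <- detect_events(make_envelope(e1, fs), thresholds = 1)
  expect_equal(nrow(ev1$events[[1]]), 1)
  expect_equal(ev1$events[[1]][1, ], c(start_s = 1.0, end_s = 1.13))
  # 60 ms + 30 ms gap + 60 ms -> two events
  e2 <- burst(burst(env, 1000, 1060), 1090, 1150)
  ev2 <- detect_events(make_envelope(e2, fs), thresholds = 1)
  expect_equal(nrow(ev2$events[[1]]), 2)
  # lone 40 ms burst -> excluded
  e3 <- burst(env, 1000, 1040)
  ev3 <- detect_events(make_envelope(e3, fs), thresholds = 1)
  expect_equal(nrow(ev3$events[[1]]), 0)
  # 40 ms burst 10 ms before a 60 ms burst -> one event (merge first,
  # filter second; the reverse order would discard the 40 ms burst)
  e4 <- burst(burst(env, 1000, 1040), 1050, 1110)
  ev4 <- detect_events(make_envelope(e4, fs), thresholds = 1)
  expect_equal(nrow(ev4$events[[1]]), 1)
  expect_equal(ev4$events[[1]][1, ], c(start_s = 1.0, end_s = 1.11))
})

test_that("threshold comparisons are strict and constant envelopes yield none", {
  env <- make_envelope(matrix(1, 1, 2000), fs = 1000)
  expect_equal(nrow(detect_events(env, thresholds = 1)$events[[1]]), 0)
  # degenerate zero threshold emits nothing rather than everything
  envz <- make_envelope(matrix(0, 1, 2000), fs = 1000)
  expect_equal(nrow(detect_events(envz)$events[[1]]), 0)
})

test_that("raising a threshold shrinks the supra-threshold event mass", {
  set.seed(9)
  v <- matrix(abs(rnorm(4000, 1, 0.6)), 1)
  env <- make_envelope(v, fs = 1000)
  # total time above threshold is monotone in the threshold ...
  mass <- vapply(seq(0.5, 3, by = 0.25), function(th)
    sum(v > th), integer(1))
  expect_true(all(diff(mass) <= 0))
  # ... but the *event count* deliberately is not: a long event whose
  # envelope dips mid-way splits at a higher threshold into two events that
  # both survive the duration filter
  e <- matrix(0.1, 1, 1000)
  e[1, 101:155] <- 3      # 55 ms
  e[1, 156:180] <- 1.5    # 25 ms dip
  e[1, 181:235] <- 3      # 55 ms
  lo <- detect_events(make_envelope(e, 1000), thresholds = 1)$events[[1]]
  hi <- detect_events(make_envelope(e, 1000), thresholds = 2)$events[[1]]
  expect_equal(nrow(lo), 1)
  expect_equal(nrow(hi), 2)
})

test_that("channel permutation permutes HI identically", {
  g <- synth_interictal_recording(n_channels = 4, duration_s = 30,
                                  events_per_channel = c(10, 2, 6, 0),
                                  seed = 14)
  hi1 <- hfo_index(g$recording)$hi
  perm <- c(3, 1, 4, 2)
  rec_p <- seeg_recording(g$recording$signal[perm, ], g$recording$fs,
                          g$recording$channel_names[perm])
  hi2 <- hfo_index(rec_p)$hi
  expect_equal(hi2$HI, hi1$HI[perm])
})

test_that("HI counts events and normalizes to a per-minute rate", {
  ev <- structure(list(events = list(matrix(c(1, 2, 3, 1.1, 2.1, 3.1), 3),
                                     matrix(numeric(), 0, 2)),
                       thresholds = c(1, 1), fs = 1000, duration_s = 60,
                       channel_names = c("a", "b")),
                  class = "seeg_events")
  hi <- compute_hi(ev)
  expect_equal(hi$HI, c(3L, 0L))
  expect_equal(hi$rate_per_min, c(3, 0))
  expect_error(compute_hi(ev, duration_s = 0), class = "seeg_bad_duration")
})

test_that("planted ripples dominate the HI ranking and are all recovered", {
  g <- synth_interictal_recording(n_channels = 4, duration_s = 60,
                                  events_per_channel = c(12, 0, 0, 0),
                                  event_snr = 5, seed = 2)
  out <- hfo_index(g$recording)
  expect_equal(which.max(out$hi$HI), 1L)
  # every planted interval overlaps a detected event
  oc <- overlap_counts(out$events$events[[1]], g$truth$event_times[[1]])
  expect_equal(oc[["truth_hit"]], 12)
  # the planted channel clearly outranks the noise-only channels
  expect_gt(out$hi$HI[1], 2 * max(out$hi$HI[2:4]))
})

test_that("two bursts planted 10 ms apart merge into one downstream event", {
  et <- list(rbind(c(2.0, 2.06), c(2.07, 2.13)))
  g <- synth_interictal_recording(n_channels = 1, duration_s = 10,
                                  event_snr = 8, event_times = et, seed = 5)
  out <- hfo_index(g$recording)
  ev <- out$events$events[[1]]
  hits <- ev[, 2] > 2.0 & ev[, 1] < 2.13
  expect_equal(sum(hits), 1)
  expect_lte(ev[hits, 1], 2.02)
  expect_gte(ev[hits, 2], 2.11)
})
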