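test_that("bandpass is zero-phase with the analytic gain profile", {
  fs <- 512; n <- fs * 40; tt <- (0:(n - 1)) / fs
  mid <- 5000:15000
  mk <- function(x) {
    r <- make_recording(n_s = 40)
    r$data[1, ] <- x
    r
  }
  r15 <- bandpass_zero_phase(mk(sin(2 * pi * 15 * tt)))
  gain <- stats::sd(r15$data[1, mid]) / stats::sd(sin(2 * pi * 15 * tt)[mid])
  expect_lt(abs(gain - 1), 0.01)                 # passband within 1%
  # phase: max cross-correlation at lag 0 (zero group delay)
  xc <- stats::ccf(r15$data[1, mid], sin(2 * pi * 15 * tt)[mid],
                   lag.max = 4, plot = FALSE)
  expect_equal(xc$lag[which.max(xc$acf)], 0)
  r60 <- bandpass_zero_phase(mk(sin(2 * pi * 60 * tt)))
  att <- 20 * log10(stats::sd(r60$data[1, mid]) /
                    stats::sd(sin(2 * pi * 60 * tt)[mid]))
  expect_lt(att, -20)                            # stopband > 20 dB down
  rdc <- bandpass_zero_phase(mk(rep(100, n)))
  expect_lt(max(abs(rdc$data[1, mid])), 1e-6)    # DC removed
  expect_error(bandpass_zero_phase(mk(tt), low = 40, high = 30), "band")
})

test_that("linked-ears re-referencing follows the algebra", {
  rec <- make_recording(n_s = 1)
  rec$data <- rec$data + 7
  withA <- recording(rbind(rec$data, 0, 0), rec$fs,
                     c(rec$channel_names, "A1", "A2"))
  same <- reref_linked_ears(withA, c("A1", "A2"))
  expect_equal(same$data[1:19, ], rec$data[1:19, ])  # zero ears: unchanged
  withC <- withA; withC$data[24:25, ] <- 3
  shifted <- reref_linked_ears(withC, c("A1", "A2"))
  expect_true(all(shifted$data[1:19, ] == 7 - 3))    # constant c shifts by -c
  # online-left-ear recording: output = data - A2/2
  keep <- c(1:23, 25)                            # drop A1, keep A2
  withA2 <- withA
  withA2$data <- withA$data[keep, ]
  withA2$channel_names <- withA$channel_names[keep]
  withA2$data[24, ] <- 4
  half <- reref_linked_ears(withA2, "A2")
  expect_true(all(half$data[1:19, ] == 7 - 2))
  expect_false("A2" %in% half$channel_names)
  expect_error(reref_linked_ears(rec, "A2"), "missing ear")
})

test_that("Fourier down-sampling preserves amplitude and event indices", {
  fs <- 1000; n <- fs * 30; tt <- (0:(n - 1)) / fs
  rec <- recording(matrix(sin(2 * pi * 10 * tt), 1), fs, "Fp1",
                   events = data.frame(onset_sample = fs + 1,
                                       condition = "Go", block = 1))
  rr <- resample_recording(rec, 512)
  expect_equal(rr$fs, 512)
  amp <- stats::sd(rr$data[1, 3000:12000]) * sqrt(2)
  expect_lt(abs(amp - 1), 0.01)
  # event at 1000 ms stays at 1000 ms within one sample
  expect_lt(abs((rr$events$onset_sample - 1) / 512 - 1), 1 / 512 + 1e-12)
  expect_identical(resample_recording(rec, 1000), rec)   # identity
  expect_error(resample_recording(rec, 2000), "upsampling")
})

test_that("epoch extraction follows the canonical grid", {
  fs <- 512
  ev <- data.frame(onset_sample = fs * (2:11) + 1,
                   condition = rep(c("Go", "NoGo"), 5), block = 1L)
  rp <- data.frame(sample = fs * (2:11) + 1 + round(0.35 * fs))  # all pressed
  rec <- make_recording(n_s = 14, events = ev, responses = rp)
  ep <- extract_epochs(rec)
  # only Go trials are valid when NoGo all carry presses (commissions)
  expect_equal(dim(ep$data), c(5, 23, 564))      # 564 samples
  expect_equal(ep$t0, 256)                       # 256 prestimulus samples
  expect_true(all(ep$condition == "Go"))
  expect_equal(ep$rt_ms[1], 350, tolerance = 1)
  # onset too close to the recording edge is dropped with a message
  ev2 <- data.frame(onset_sample = c(100L, fs * 3 + 1L),
                    condition = c("Go", "Go"), block = 1L)
  rp2 <- data.frame(sample = c(100L, fs * 3 + 1L) + round(0.35 * fs))
  rec2 <- make_recording(n_s = 6, events = ev2, responses = rp2)
  expect_message(ep2 <- extract_epochs(rec2), "dropped")
  expect_equal(dim(ep2$data)[1], 1)
})

test_that("EMCP recovers planted propagation and corrects blinks", {
  set.seed(4)
  n_tr <- 100
  ep <- make_epochs(n_tr, condition = rep(c("Go", "NoGo"), 50))
  ep$data <- ep$data + array(rnorm(length(ep$data), sd = 5), dim(ep$data))
  fp1 <- match("Fp1", ep$channel_names)
  veogu <- match("VEOGU", ep$channel_names)
  blink <- 200 * 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = 154)))
  blink_tr <- seq(1, n_tr, by = 3)
  for (tr in blink_tr) {
    ep$data[tr, veogu, 101:254] <- ep$data[tr, veogu, 101:254] + blink
    ep$data[tr, fp1, 101:254] <- ep$data[tr, fp1, 101:254] + 0.4 * blink
  }
  pre <- max(abs(apply(ep$data[blink_tr, fp1, ], 2, mean)))
  out <- emcp_correct(ep)
  expect_lt(abs(out$model$blink_coefficients["VEOGU", "Fp1"] - 0.4), 0.02)
  post <- max(abs(apply(out$epochs$data[blink_tr, fp1, ], 2, mean)))
  expect_lt(post, 0.1 * pre)                     # > 90% blink reduction
  # uncontaminated channels: estimated coefficients ~ 0
  expect_lt(max(abs(out$model$blink_coefficients["VEOGU", -1])), 0.02)
})

test_that("EMCP with zero EOG leaves epochs unchanged", {
  ep <- make_epochs(6)
  set.seed(2)
  eeg <- eeg_index(ep)
  ep$data[, eeg, ] <- rnorm(length(ep$data[, eeg, ]))
  expect_warning(out <- emcp_correct(ep), "zero-variance")
  expect_identical(out$epochs$data, ep$data)
  expect_true(all(out$model$blink_coefficients == 0))
})

test_that("spherical-spline interpolation reconstructs smooth fields", {
  # channel values = smooth topography sampled at electrode positions
  field <- topography_gaussian("Cz", 120, fixture_montage)
  ep <- make_epochs(2)
  eeg <- eeg_index(ep)
  for (k in seq_len(564)) ep$data[, eeg, k] <- rep(field * 10, each = 2)
  out <- interpolate_channels(ep, "C3")
  truth <- 10 * field[["C3"]]
  err <- abs(out$data[1, match("C3", ep$channel_names), 1] - truth)
  expect_lt(err, 0.1 * sqrt(mean((10 * field)^2)))  # < 10% of signal RMS
  expect_identical(interpolate_channels(ep, character()), ep)  # identity
  expect_error(interpolate_channels(ep, c("C3", "C4", "Cz", "Pz")),
               "at most 3")
})

test_that("baseline correction zeroes the window mean", {
  ep <- make_epochs(3, fill = 10)
  out <- baseline_correct(ep)
  expect_true(all(abs(out$data) < 1e-12))        # constant trial -> zeros
  ramp <- seq_len(564)
  ep$data[1, 1, ] <- ramp
  out2 <- baseline_correct(ep)
  tms <- epoch_times_ms(ep)
  win <- tms >= -100 & tms < 0
  expect_lt(abs(mean(out2$data[1, 1, win])), 1e-9)
  expect_equal(diff(out2$data[1, 1, 1:10]), diff(ramp[1:10]))  # shape kept
  expect_error(baseline_correct(ep, c(-2000, -1500)), "window")
})

test_that("automatic rejection classifies the canonical fixtures", {
  ep <- make_epochs(5)
  eeg <- eeg_index(ep)
  set.seed(6)
  # smooth in-band activity keeps every channel honest (no flatlines)
  for (tr in 1:5) {
    for (ch in eeg) {
      ep$data[tr, ch, ] <- 20 * sin(2 * pi * 10 * (1:564) / 512 + ch)
    }
  }
  ep$data[2, eeg[4], 300] <- 151                  # extreme amplitude
  ep$data[3, eeg[7], 200:564] <- ep$data[3, eeg[7], 200:564] + 60  # 60 uV step
  ep$data[4, eeg[12], ] <- 3                      # flatlined channel
  out <- artifact_reject_auto(ep)
  expect_equal(out$reason[2], "extreme")
  expect_equal(out$reason[3], "jump")
  expect_equal(out$reason[4], "flat")
  expect_true(out$accepted[1] && out$accepted[5]) # clean epochs accepted
  # strict inequality: a smooth waveform peaking at exactly 150 uV is
  # retained (no sample exceeds 150, steps stay far below 50)
  ep2 <- make_epochs(1)
  for (ch in eeg) ep2$data[1, ch, ] <- 150 * sin(2 * pi * 4 * (0:563) / 512)
  expect_equal(max(ep2$data), 150)
  expect_true(artifact_reject_auto(ep2)$accepted[1])
})

test_that("rejection is monotone in the thresholds", {
  set.seed(9)
  ep <- make_epochs(40)
  eeg <- eeg_index(ep)
  ep$data[, eeg, ] <- 60 * array(rnorm(length(ep$data[, eeg, ])),
                                 c(40, length(eeg), 564))
  strict <- default_thresholds()
  loose <- list(extreme_abs = 300, jump = 100, flat_delta = 0.01,
                flat_window_ms = 100)
  a_strict <- artifact_reject_auto(ep, strict)$accepted
  a_loose <- artifact_reject_auto(ep, loose)$accepted
  expect_true(all(a_loose[a_strict]))            # loosening never rejects more
})

test_that("prestimulus presses reject trials with the stated boundary", {
  fs <- 512
  onsets <- fs * (2:7) + 1L
  ev <- data.frame(onset_sample = onsets, condition = "Go", block = 1L)
  ep <- make_epochs(6, condition = rep("Go", 6))
  ep$trial_id <- 1:6
  # press 200 ms before trial 3 onset; press exactly at trial 5 onset
  rp <- data.frame(sample = c(onsets[3] - round(0.2 * fs), onsets[5]))
  out <- reject_prestim_response(ep, rp, onsets)
  expect_equal(out$reason[3], "prestim_press")
  expect_true(out$accepted[5])                   # press at onset is retained
  expect_equal(sum(!out$accepted), 1)
  # no presses: identity
  expect_identical(reject_prestim_response(ep, empty_responses(), onsets), ep)
})

test_that("trial-count matching mirrors the 61/68 example", {
  n_go <- 61; n_ng <- 68
  ep <- make_epochs(n_go + n_ng,
                    condition = c(rep("Go", n_go), rep("NoGo", n_ng)))
  out <- match_trial_counts(ep, seed = 4)
  expect_equal(sum(out$accepted & out$condition == "Go"), 61)
  expect_equal(sum(out$accepted & out$condition == "NoGo"), 61)
  expect_true(all(out$reason[!out$accepted] == "match"))
  # equal counts: identity; same seed: identical selection
  eq <- make_epochs(10)
  expect_identical(match_trial_counts(eq, 1), eq)
  out2 <- match_trial_counts(ep, seed = 4)
  expect_identical(out$accepted, out2$accepted)
  out3 <- match_trial_counts(ep, seed = 5)
  expect_false(identical(out$accepted, out3$accepted))
  bad <- make_epochs(4, condition = rep("Go", 4))
  expect_error(match_trial_counts(bad, 1), "zero accepted")
})
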