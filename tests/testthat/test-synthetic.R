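test_that("schedule_events honours counts, spacing, and the seed", {
  ev <- schedule_events(2, 75, 1100, seed = 7)
  expect_equal(nrow(ev), 300)
  expect_equal(sum(ev$condition == "Go"), 150)
  expect_equal(sum(ev$condition == "NoGo"), 150)
  expect_true(all(diff(ev$onset_ms) == 1100))
  # per block balance
  for (b in 1:2) {
    expect_equal(sum(ev$condition == "Go" & ev$block == b), 75)
  }
  tiny <- schedule_events(1, 1, 1100, seed = 0, t_start_ms = 0)
  expect_equal(tiny$onset_ms, c(0, 1100))
  expect_identical(schedule_events(1, 10, 1100, seed = 3)$condition,
                   schedule_events(1, 10, 1100, seed = 3)$condition)
  expect_error(schedule_events(1, 0, 1100), "positive")
  expect_error(schedule_events(1, 10, -5), "positive")
})

test_that("oscillator/template/link specs enforce their invariants", {
  topo <- topography_gaussian("Pz", 90, fixture_montage)
  expect_error(oscillator_spec("x", 0, 5, 1, topo), "1..30", fixed = TRUE)
  expect_error(oscillator_spec("x", 9, -1, 1, topo), "amplitude")
  expect_error(oscillator_spec("x", 9, 5, 1, 0.5 * topo), "max weight")
  expect_error(erp_template_spec("x", 700, 20, 5, topo), "latency")
  expect_error(erp_template_spec("x", 100, 20, 5, topo, gain_go = -1), "gains")
  expect_error(behaviour_link_spec("a", "banana", 0.5), "target")
  expect_error(behaviour_link_spec("a", "mean_rt", 1.2), "strength")
})

test_that("synth_background realises oscillator amplitude and 1/f decline", {
  topo <- topography_gaussian("Pz", 90, fixture_montage)
  os <- oscillator_spec("alpha", 9, 6, 2, topo)
  sig <- synth_background(60, 512, list(os), one_over_f_scale = 0, seed = 3)
  ch <- which.max(topo)
  amps <- vapply(1:100, function(w) {
    amplitude_spectrum(sig[ch, ((w - 1) * 256 + 1):(w * 256)])[["9"]]
  }, 0)
  expect_lt(abs(mean(amps) - 6) / 6, 0.05)      # stated amplitude within 5%
  # empty source list, zero 1/f -> all-zero signal
  z <- synth_background(2, 512, list(), one_over_f_scale = 0, seed = 1)
  expect_true(all(z == 0))
  # two oscillators -> two local maxima at the stated bins; 1/f declines
  os2 <- oscillator_spec("delta", 2, 6, 1, topo)
  sig2 <- synth_background(60, 512, list(os2, os), one_over_f_scale = 1,
                           seed = 4)
  spec <- Reduce(`+`, lapply(1:100, function(w) {
    amplitude_spectrum(sig2[ch, ((w - 1) * 256 + 1):(w * 256)])
  })) / 100
  peaks <- which(diff(sign(diff(spec))) == -2)  # positions = frequency in Hz
  expect_true(all(c(2, 9) %in% peaks))
  pink <- synth_background(60, 512, list(), one_over_f_scale = 2, seed = 5,
                           n_channels = 1)
  pspec <- Reduce(`+`, lapply(1:100, function(w) {
    amplitude_spectrum(pink[1, ((w - 1) * 256 + 1):(w * 256)])
  })) / 100
  expect_gt(pspec[["1"]], pspec[["6"]])
  expect_gt(pspec[["6"]], pspec[["25"]])
  expect_error(synth_background(10, 256, list(os)), "fs")
})

test_that("inject_erp adds templates recoverable by condition averaging", {
  topo <- topography_gaussian("Cz", 100, fixture_montage)
  ev <- schedule_events(1, 20, 1100, seed = 2)
  n <- round((max(ev$onset_ms) + 2000) / 1000 * 512)
  sig0 <- matrix(0, 19, n)
  tp <- erp_template_spec("t", 100, 20, 5, topo, gain_go = 1, gain_nogo = 0)
  sig <- inject_erp(sig0, ev, list(tp), fs = 512)
  cz <- which.max(topo)
  onsets <- round(ev$onset_ms / 1000 * 512) + 1
  avg_at <- function(cond, lag) {
    mean(sig[cz, onsets[ev$condition == cond] + lag])
  }
  lag100 <- round(0.1 * 512)
  expect_equal(avg_at("Go", lag100), 5, tolerance = 1e-3)
  expect_equal(avg_at("NoGo", lag100), 0)
  # identity and linearity
  expect_identical(inject_erp(sig0, ev, list(), fs = 512), sig0)
  tp2 <- erp_template_spec("t", 100, 20, 5, topo, gain_go = 2, gain_nogo = 0)
  sig2 <- inject_erp(sig0, ev, list(tp2), fs = 512)
  expect_equal(max(sig2), 2 * max(sig), tolerance = 1e-9)
  # template beyond the SOA
  late <- erp_template_spec("late", 599, 400, 5, topo)
  expect_error(inject_erp(sig0, ev, list(late), fs = 512), "SOA")
})

test_that("inject_eog propagates linearly and reproducibly", {
  n <- 512 * 30
  sig0 <- matrix(0, 19, n)
  prop0 <- matrix(0, 4, 19)
  out0 <- inject_eog(sig0, 512, blink_rate = 10, propagation = prop0,
                     seed = 5, eog_noise = 0)
  expect_identical(out0$signal, sig0)           # zero propagation: unchanged
  expect_gt(nrow(out0$blink_intervals), 0)
  # single-channel propagation: Fp1 deflection = 0.4 x VEOGU
  prop <- prop0; prop["VEOGU" == eog_labels(), match("Fp1", eeg_labels())] <- 0.4
  out <- inject_eog(sig0, 512, blink_rate = 10, propagation = prop,
                    seed = 5, saccade_rate = 0, eog_noise = 0)
  expect_equal(out$signal[match("Fp1", eeg_labels()), ],
               0.4 * out$eog[1, ], tolerance = 1e-12)
  expect_true(all(out$signal[-match("Fp1", eeg_labels()), ] == 0))
  # seed determinism
  out2 <- inject_eog(sig0, 512, blink_rate = 10, propagation = prop,
                     seed = 5, saccade_rate = 0, eog_noise = 0)
  expect_identical(out$blink_intervals, out2$blink_intervals)
  expect_error(inject_eog(sig0, 512, propagation = matrix(0, 2, 19)), "4 x")
})

test_that("synth_behaviour degenerate and boundary settings are exact", {
  ev <- schedule_events(1, 30, 1100, seed = 1)
  base0 <- behaviour_base_rates()
  base0$omission <- 0; base0$fast_rt <- 0; base0$slow_rt <- 0
  base0$commission <- 0; base0$rt_sd <- 0
  base0$rt_between_sd <- 0; base0$rt_var_spread <- 0; base0$rate_spread <- 0
  beh <- synth_behaviour(ev, base_rt = 350, base = base0, seed = 2)
  rt <- beh$responses$press_ms - ev$onset_ms
  go <- ev$condition == "Go"
  expect_true(all(rt[go] == 350))               # all Go RTs = base_rt
  expect_equal(stats::sd(rt[go]), 0)
  expect_true(all(is.na(beh$responses$press_ms[!go])))  # commission rate 0
  expect_error(
    synth_behaviour(ev, c(a = 0), list(list(driver = "a", target = "mean_rt",
                                            strength = 2)), seed = 1),
    "strength")
})

test_that("planted Spearman link is recovered across simulated subjects", {
  # Monte-Carlo with the linkage module as oracle: 40 subjects, rho = 0.8
  # between a driver amplitude and rt_variability
  n_sub <- 40
  link <- list(behaviour_link_spec("osc", "rt_variability", 0.8))
  ev <- schedule_events(4, 75, 1100, seed = 9)  # recovery improves with trials
  set.seed(11)
  z <- rnorm(n_sub)
  meas <- t(vapply(seq_len(n_sub), function(s) {
    beh <- synth_behaviour(ev, driver_z = c(osc = z[s]), links = link,
                           seed = 100 + s)
    cls <- classify_trials(ev, beh$responses)
    sm <- summarise_behaviour(cls)
    c(amp = exp(0.4 * z[s]), rtv = sm$rt_variability)
  }, c(amp = 0, rtv = 0)))
  rho <- spearman_rho(meas[, "amp"], meas[, "rtv"])
  ci <- spearman_ci(rho, n_sub)
  expect_true(0.8 >= ci[1] && 0.8 <= ci[2])
})

test_that("simulation is bit-reproducible under a fixed seed", {
  cfg <- sim_config(n_subjects = 1, per_condition = 10)
  s1 <- simulate_subject(cfg, seed = 5)
  s2 <- simulate_subject(cfg, seed = 5)
  expect_identical(s1$recording$data, s2$recording$data)
  expect_identical(s1$truth$press_ms, s2$truth$press_ms)
  s3 <- simulate_subject(cfg, seed = 6)
  expect_false(identical(s1$recording$data, s3$recording$data))
})
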