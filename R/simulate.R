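#' Default simulation configuration
#'
#' The stated world of the generator: an equiprobable auditory Go/NoGo
#' task (2 blocks of 75 Go + 75 NoGo tones, fixed 1100 ms SOA) recorded
#' from the 19-channel 10-20 montage plus 4 EOG channels at 512 Hz.  The
#' background holds a 1/f decline plus three narrowband oscillators
#' (parietal 2 Hz delta, parietal 9 Hz alpha, frontal 18 Hz beta); three
#' Gaussian ERP templates (an early posterior positivity, a central
#' negativity, and a late parietal positivity larger for NoGo) are
#' injected poststimulus; blinks and saccades contaminate the EEG through
#' fixed propagation factors; behaviour carries planted rank correlations
#' with the alpha and delta subject amplitudes.
#'
#' @param n_subjects number of subjects (default 20).
#' @param fs sampling rate (default 512).
#' @param n_blocks,per_condition,soa_ms task schedule parameters.
#' @return list of class `plk_sim_config`.
#' @export
sim_config <- function(n_subjects = 20, fs = 512, n_blocks = 2,
                       per_condition = 75, soa_ms = 1100) {
  m <- montage_1020()
  cfg <- list(
    n_subjects = n_subjects, fs = fs, n_blocks = n_blocks,
    per_condition = per_condition, soa_ms = soa_ms, t_start_ms = 2000,
    pad_end_ms = 2000,
    oscillators = list(
      oscillator_spec("delta2", 2, 3.0, 1.0, topography_gaussian("Pz", 110, m),
                      trial_sd = 0.8, subject_sd = 0.4),
      oscillator_spec("alpha9", 9, 6.0, 2.0, topography_gaussian("Pz", 90, m),
                      trial_sd = 2.0, subject_sd = 0.4),
      oscillator_spec("beta18", 18, 1.8, 3.0, topography_gaussian("Fz", 90, m),
                      trial_sd = 0.5, subject_sd = 0.4)),
    one_over_f_scale = 2.0, one_over_f_exponent = 1, one_over_f_subject_sd = 0.2,
    sensor_noise = 0.3,
    erps = list(
      erp_template_spec("P1", 100, 20, 4, topography_gaussian("O1", 100, m),
                        1, 1),
      erp_template_spec("N1", 160, 25, -6, topography_gaussian("Cz", 100, m),
                        1, 1.1),
      erp_template_spec("P3", 350, 60, 8, topography_gaussian("Pz", 110, m),
                        1, 1.25)),
    links = list(
      behaviour_link_spec("alpha9", "rt_variability", 0.5),
      behaviour_link_spec("delta2", "mean_rt", -0.4),
      behaviour_link_spec("P3", "commission", -0.4)),
    base_rt = 389, behaviour = behaviour_base_rates(),
    blink_rate = 8, saccade_rate = 4,
    propagation = default_propagation(m))
  class(cfg) <- "plk_sim_config"
  cfg
}

#' Simulate one subject's continuous recording with ground truth
#'
#' Composes [schedule_events()], [synth_background()] (with per-trial
#' amplitude envelopes), [inject_erp()], [synth_behaviour()] and
#' [inject_eog()] into a 23-channel `plk_recording` (19 EEG + 4 EOG) and a
#' truth record carrying every planted quantity.
#'
#' @param config `plk_sim_config`.
#' @param seed integer seed (all randomness derives from it).
#' @param subject subject identifier string.
#' @return list: `recording` (`plk_recording`), `truth` (list: subject
#'   gains, driver latents, per-trial amplitudes, blink intervals,
#'   behavioural parameters, seed).
#' @export
simulate_subject <- function(config = sim_config(), seed = 1,
                             subject = "S01") {
  fs <- config$fs
  events <- schedule_events(config$n_blocks, config$per_condition,
                            config$soa_ms, seed = derive_seed(seed, "ev"),
                            t_start_ms = config$t_start_ms)
  n_trials <- nrow(events)
  duration_s <- (max(events$onset_ms) + config$soa_ms + config$pad_end_ms) / 1000
  n <- round(duration_s * fs)

  set.seed(derive_seed(seed, "gains"))
  osc_z <- stats::rnorm(length(config$oscillators))
  names(osc_z) <- vapply(config$oscillators, `[[`, "", "name")
  osc_gain <- exp(vapply(config$oscillators, `[[`, 0, "subject_sd") * osc_z)
  erp_z <- stats::rnorm(length(config$erps))
  names(erp_z) <- vapply(config$erps, `[[`, "", "name")
  erp_gain <- exp(vapply(config$erps, `[[`, 0, "subject_sd") * erp_z)
  pink_gain <- exp(config$one_over_f_subject_sd * stats::rnorm(1))

  # per-trial multiplicative modulation (log-normal, mean 1); envelope is
  # piecewise constant on the SOA interval ending at each stimulus onset,
  # so trial i's prestimulus segment carries trial i's amplitude
  onset_smp <- round(events$onset_ms / 1000 * fs) + 1L
  envelopes <- vector("list", length(config$oscillators))
  trial_mult <- matrix(1, n_trials, length(config$oscillators),
                       dimnames = list(NULL, names(osc_z)))
  for (i in seq_along(config$oscillators)) {
    os <- config$oscillators[[i]]
    cv <- os$trial_sd / os$amplitude
    s2 <- log(1 + cv^2)
    m <- exp(stats::rnorm(n_trials, -s2 / 2, sqrt(s2)))
    trial_mult[, i] <- m
    env <- rep(m[n_trials], n)
    env[seq_len(onset_smp[1])] <- m[1]
    for (tr in 2:n_trials) {
      env[(onset_smp[tr - 1] + 1):onset_smp[tr]] <- m[tr]
    }
    envelopes[[i]] <- env
  }

  eegm <- synth_background(duration_s, fs, config$oscillators,
                           one_over_f_scale = config$one_over_f_scale * pink_gain,
                           seed = derive_seed(seed, "bg"),
                           envelopes = envelopes, gains = osc_gain,
                           one_over_f_exponent = config$one_over_f_exponent,
                           sensor_noise = config$sensor_noise)
  eegm <- inject_erp(eegm, events, config$erps, fs, soa_ms = config$soa_ms,
                     gains = erp_gain)

  beh <- synth_behaviour(events, driver_z = c(osc_z, erp_z),
                         links = config$links, base_rt = config$base_rt,
                         base = config$behaviour, soa_ms = config$soa_ms,
                         seed = derive_seed(seed, "beh"))
  press_ms <- beh$responses$press_ms
  responses <- data.frame(sample = round(press_ms[!is.na(press_ms)] / 1000 * fs) + 1L)

  contaminated <- inject_eog(eegm, fs, blink_rate = config$blink_rate,
                             propagation = config$propagation,
                             seed = derive_seed(seed, "eogart"),
                             saccade_rate = config$saccade_rate)

  data <- rbind(contaminated$signal, contaminated$eog)
  rec <- recording(data, fs, c(eeg_labels(), eog_labels()),
                   events = data.frame(onset_sample = onset_smp,
                                       condition = events$condition,
                                       block = events$block,
                                       stringsAsFactors = FALSE),
                   responses = responses)
  amps <- vapply(config$oscillators, `[[`, 0, "amplitude")
  truth <- list(
    subject = subject, seed = seed,
    oscillator_gain = osc_gain, erp_gain = erp_gain,
    driver_z = c(osc_z, erp_z),
    per_trial_amplitudes = sweep(trial_mult, 2, amps * osc_gain, `*`),
    blink_intervals = contaminated$blink_intervals,
    saccade_intervals = contaminated$saccade_intervals,
    behaviour_params = beh$params,
    events = events, press_ms = press_ms)
  list(recording = rec, truth = truth)
}

#' Simulate a full group
#'
#' @param config `plk_sim_config`.
#' @param seed master seed; subject s uses child seed
#'   `derive_seed(seed, paste0("subj", s))`.
#' @return list with one `simulate_subject()` result per subject.
#' @export
simulate_group <- function(config = sim_config(), seed = 1) {
  lapply(seq_len(config$n_subjects), function(s) {
    simulate_subject(config, seed = derive_seed(seed, paste0("subj", s)),
                     subject = sprintf("S%02d", s))
  })
}
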