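#' Oscillator specification for the synthetic EEG background
#'
#' A narrowband spectral component of the prestimulus EEG: realised as
#' narrowband-filtered Gaussian noise (not a pure tone), so that spectra
#' show realistic peak widths and PCA recovery is non-degenerate.
#'
#' @param name identifier (used by behaviour links).
#' @param peak_frequency integer Hz in 1..30.
#' @param amplitude target spectral amplitude at the peak, microvolts (> 0),
#'   as measured by [amplitude_spectrum()] on 500 ms segments.
#' @param bandwidth half-power width of the spectral peak, Hz.
#' @param topography unit-max weight per channel (max exactly 1).
#' @param trial_sd between-trial SD of the peak amplitude, microvolts.
#' @param subject_sd between-subject log-normal SD of the amplitude gain.
#' @return list of class `plk_oscillator`.
#' @export
oscillator_spec <- function(name, peak_frequency, amplitude, bandwidth,
                            topography, trial_sd = 0, subject_sd = 0.4) {
  if (peak_frequency < 1 || peak_frequency > 30 ||
      peak_frequency != round(peak_frequency)) {
    stop_invalid("peak_frequency must be an integer in 1..30")
  }
  if (amplitude <= 0) stop_invalid("amplitude must be > 0")
  if (bandwidth <= 0) stop_invalid("bandwidth must be > 0")
  if (trial_sd < 0) stop_invalid("trial_sd must be >= 0")
  if (abs(max(topography) - 1) > 1e-12) {
    stop_invalid("topography must have max weight exactly 1")
  }
  structure(list(name = name, peak_frequency = as.integer(peak_frequency),
                 amplitude = amplitude, bandwidth = bandwidth,
                 topography = topography, trial_sd = trial_sd,
                 subject_sd = subject_sd),
            class = "plk_oscillator")
}

#' ERP template specification
#'
#' A Gaussian-shaped poststimulus component injected into every trial,
#' scaled per condition.
#'
#' @param name identifier.
#' @param latency_ms peak latency, 0 < latency < 600 ms.
#' @param width_ms Gaussian SD in ms (> 0).
#' @param amplitude_uv signed peak amplitude, microvolts.
#' @param topography unit-max weight per channel.
#' @param gain_go,gain_nogo nonnegative per-condition scale factors.
#' @param subject_sd between-subject log-normal SD of the gain.
#' @return list of class `plk_erp_template`.
#' @export
erp_template_spec <- function(name, latency_ms, width_ms, amplitude_uv,
                              topography, gain_go = 1, gain_nogo = 1,
                              subject_sd = 0.3) {
  if (latency_ms <= 0 || latency_ms >= 600) {
    stop_invalid("latency must lie in (0, 600) ms")
  }
  if (width_ms <= 0) stop_invalid("width must be > 0")
  if (gain_go < 0 || gain_nogo < 0) stop_invalid("condition gains must be >= 0")
  if (abs(max(topography) - 1) > 1e-12) {
    stop_invalid("topography must have max weight exactly 1")
  }
  structure(list(name = name, latency_ms = latency_ms, width_ms = width_ms,
                 amplitude_uv = amplitude_uv, topography = topography,
                 gain_go = gain_go, gain_nogo = gain_nogo,
                 subject_sd = subject_sd),
            class = "plk_erp_template")
}

#' Behaviour link specification
#'
#' Plants a target Spearman correlation (across subjects) between a driver
#' component's subject-level amplitude and a behavioural measure, via a
#' Gaussian copula: the latent behavioural propensity is r z + sqrt(1-r^2) e
#' with r = 2 sin(pi rho / 6), so the rank correlation of the monotone
#' transforms equals rho in expectation.
#'
#' @param driver name of an oscillator or ERP template.
#' @param target one of "mean_rt", "rt_variability", "omission", "fast_rt",
#'   "slow_rt", "commission".
#' @param strength target Spearman rho in [-1, 1].
#' @return list of class `plk_link`.
#' @export
behaviour_link_spec <- function(driver, target, strength) {
  targets <- c("mean_rt", "rt_variability", "omission", "fast_rt",
               "slow_rt", "commission")
  if (!target %in% targets) {
    stop_invalid("target must be one of: %s", paste(targets, collapse = ", "))
  }
  if (abs(strength) > 1) stop_invalid("|strength| must be <= 1")
  structure(list(driver = driver, target = target, strength = strength),
            class = "plk_link")
}

#' Schedule Go/NoGo stimulus events at a fixed SOA
#'
#' Each block contains exactly `per_condition` Go and `per_condition` NoGo
#' tones in a seeded random order; consecutive onsets differ by exactly
#' `soa` ms (blocks are contiguous).
#'
#' @param n_blocks number of blocks (>= 1).
#' @param per_condition tones per condition per block (>= 1).
#' @param soa stimulus onset asynchrony, ms (> 0).
#' @param seed integer seed.
#' @param t_start_ms onset of the first stimulus, ms.
#' @return data.frame: `trial`, `block`, `onset_ms`, `condition`.
#' @export
schedule_events <- function(n_blocks = 2, per_condition = 75, soa = 1100,
                            seed = 1, t_start_ms = 2000) {
  if (soa <= 0 || n_blocks < 1 || per_condition < 1) {
    stop_invalid("n_blocks, per_condition and soa must be positive")
  }
  set.seed(derive_seed(seed, "schedule"))
  conds <- unlist(lapply(seq_len(n_blocks), function(b) {
    sample(rep(c("Go", "NoGo"), per_condition))
  }))
  n <- length(conds)
  data.frame(trial = seq_len(n),
             block = rep(seq_len(n_blocks), each = 2 * per_condition),
             onset_ms = t_start_ms + (seq_len(n) - 1) * soa,
             condition = conds, stringsAsFactors = FALSE)
}

# Narrowband Gaussian noise via spectral shaping: Gaussian band with
# half-power width bw centred at f0.  Returns a length-n signal.
narrowband_noise <- function(n, fs, f0, bw) {
  nfft <- stats::nextn(n, c(2, 3, 5))
  x <- stats::rnorm(nfft)
  X <- stats::fft(x)
  f <- c(seq(0, floor(nfft / 2)), seq(-(ceiling(nfft / 2) - 1), -1)) * fs / nfft
  sigma <- bw / (2 * sqrt(log(2)))
  H <- exp(-0.5 * ((abs(f) - f0) / sigma)^2)
  Re(stats::fft(X * H, inverse = TRUE))[seq_len(n)] / nfft
}

# 1/f^exponent amplitude-shaped Gaussian noise.
pink_noise <- function(n, fs, exponent = 1) {
  nfft <- stats::nextn(n, c(2, 3, 5))
  x <- stats::rnorm(nfft)
  X <- stats::fft(x)
  f <- c(seq(0, floor(nfft / 2)), seq(-(ceiling(nfft / 2) - 1), -1)) * fs / nfft
  H <- ifelse(abs(f) >= 0.5, (pmax(abs(f), 0.5))^(-exponent), 0)
  H[1] <- 0
  Re(stats::fft(X * H, inverse = TRUE))[seq_len(n)] / nfft
}

# Mean measured peak-bin amplitude of a signal over up to `max_win`
# contiguous 500 ms segments, through the package's own spectral pipeline.
measured_amplitude <- function(x, fs, bin_hz, n_seg = 256L, max_win = 120L) {
  nwin <- min(max_win, floor(length(x) / n_seg))
  stopifnot(nwin >= 1)
  amps <- vapply(seq_len(nwin), function(w) {
    seg <- x[((w - 1) * n_seg + 1):(w * n_seg)]
    unname(amplitude_spectrum(seg, fs = fs, n_seg = n_seg)[as.character(bin_hz)])
  }, 0)
  mean(amps)
}

#' Synthesise continuous background EEG
#'
#' Sum of a 1/f background and narrowband oscillators, each with a fixed
#' scalp topography.  Every stochastic source is calibrated through the
#' package's own spectral pipeline so that the mean measured amplitude at
#' the stated frequency equals the stated microvolt amplitude.
#'
#' @param duration_s signal length in seconds.
#' @param fs sampling rate (512 or 1000 Hz).
#' @param oscillators list of [oscillator_spec()] objects (may be empty).
#' @param one_over_f_scale amplitude of the 1/f background at 1 Hz,
#'   microvolts (0 disables it).
#' @param seed integer seed.
#' @param n_channels number of channels when `oscillators` is empty.
#' @param envelopes optional list (one numeric vector per oscillator,
#'   length = n samples) of multiplicative amplitude envelopes, e.g. the
#'   per-trial modulation; default all-ones.
#' @param gains optional numeric vector of per-oscillator scalar gains
#'   (e.g. subject-level amplitude factors); default 1.
#' @param one_over_f_exponent amplitude falloff exponent (default 1).
#' @param sensor_noise white measurement noise SD, microvolts (default 0).
#' @return channel x sample numeric matrix (microvolts).
#' @export
synth_background <- function(duration_s, fs, oscillators = list(),
                             one_over_f_scale = 0, seed = 1,
                             n_channels = 19L, envelopes = NULL, gains = NULL,
                             one_over_f_exponent = 1, sensor_noise = 0) {
  if (!fs %in% c(512, 1000)) stop_invalid("fs must be 512 or 1000 Hz")
  if (duration_s <= 0) stop_invalid("duration must be positive")
  n <- round(duration_s * fs)
  if (length(oscillators)) n_channels <- length(oscillators[[1]]$topography)
  set.seed(derive_seed(seed, "background"))
  sig <- matrix(0, n_channels, n)
  for (i in seq_along(oscillators)) {
    os <- oscillators[[i]]
    src <- narrowband_noise(n, fs, os$peak_frequency, os$bandwidth)
    cal <- os$amplitude / measured_amplitude(src, fs, os$peak_frequency)
    src <- src * cal
    if (!is.null(envelopes)) src <- src * envelopes[[i]]
    if (!is.null(gains)) src <- src * gains[i]
    sig <- sig + outer(as.numeric(os$topography), src)
  }
  if (one_over_f_scale > 0) {
    cal <- NULL
    for (ch in seq_len(n_channels)) {
      src <- pink_noise(n, fs, one_over_f_exponent)
      if (is.null(cal)) {
        # target amplitude at f is scale/f^expo; average the implied scale
        # over bins 1..5 Hz for a low-variance calibration
        implied <- vapply(1:5, function(f) {
          measured_amplitude(src, fs, f) * f^one_over_f_exponent
        }, 0)
        cal <- 1 / mean(implied)
      }
      sig[ch, ] <- sig[ch, ] + src * cal * one_over_f_scale
    }
  }
  if (sensor_noise > 0) {
    sig <- sig + matrix(stats::rnorm(length(sig), sd = sensor_noise),
                        nrow = n_channels)
  }
  sig
}

#' Inject ERP templates into a continuous signal
#'
#' Adds, at every stimulus onset, each template's Gaussian waveform scaled
#' by its condition gain and topography.  Superposition is additive.
#'
#' @param signal channel x sample matrix (EEG channels, matching the
#'   templates' topography length).
#' @param events event table from [schedule_events()].
#' @param erps list of [erp_template_spec()].
#' @param fs sampling rate, Hz.
#' @param soa_ms stimulus onset asynchrony (templates must fit within it).
#' @param gains optional per-template scalar gains (e.g. subject factors).
#' @return the signal with ERPs added.
#' @export
inject_erp <- function(signal, events, erps, fs, soa_ms = 1100, gains = NULL) {
  if (!length(erps)) return(signal)
  n <- ncol(signal)
  for (i in seq_along(erps)) {
    tp <- erps[[i]]
    if (tp$latency_ms + 3 * tp$width_ms > soa_ms) {
      stop_invalid("template '%s' extends beyond the SOA", tp$name)
    }
    span_ms <- seq(0, min(soa_ms, tp$latency_ms + 4 * tp$width_ms))
    k <- round(span_ms[length(span_ms)] / 1000 * fs)
    tt <- (0:k) / fs * 1000
    wave <- tp$amplitude_uv * exp(-0.5 * ((tt - tp$latency_ms) / tp$width_ms)^2)
    g <- if (is.null(gains)) 1 else gains[i]
    topo <- as.numeric(tp$topography)
    for (e in seq_len(nrow(events))) {
      s0 <- round(events$onset_ms[e] / 1000 * fs) + 1L
      idx <- s0:min(n, s0 + k)
      cg <- if (events$condition[e] == "Go") tp$gain_go else tp$gain_nogo
      if (cg == 0 || g == 0) next
      signal[, idx] <- signal[, idx] +
        outer(topo, wave[seq_along(idx)] * cg * g)
    }
  }
  signal
}

#' Inject ocular (EOG) artifacts with known propagation
#'
#' Generates four EOG channels (VEOGU/VEOGL above/below the left eye,
#' HEOGL/HEOGR at the outer canthi) containing blinks (raised-cosine,
#' ~300 ms) and horizontal saccades (ramped boxcars, ~200 ms) at Poisson
#' times, and adds `t(propagation) %*% EOG` to the EEG channels.  The
#' propagation matrix rows follow [eog_labels()] order.
#'
#' @param signal channel x sample EEG matrix (19 channels).
#' @param fs sampling rate, Hz.
#' @param blink_rate blinks per minute.
#' @param propagation 4 x n_eeg coefficient matrix (EOG channel -> EEG
#'   channel); must cover all pairs.
#' @param seed integer seed.
#' @param saccade_rate saccades per minute.
#' @param blink_amp_uv mean blink amplitude at VEOGU (SD 15%).
#' @param saccade_amp_uv saccade amplitude at HEOG.
#' @param eog_noise white sensor noise SD added to the EOG channels only
#'   (never propagated), microvolts.
#' @return list: `signal` (contaminated EEG), `eog` (4 x n matrix),
#'   `blink_intervals` (data.frame onset/offset samples),
#'   `saccade_intervals`.
#' @export
inject_eog <- function(signal, fs, blink_rate = 8, propagation, seed = 1,
                       saccade_rate = 4, blink_amp_uv = 200,
                       saccade_amp_uv = 50, eog_noise = 2) {
  if (!is.matrix(propagation) || nrow(propagation) != 4 ||
      ncol(propagation) != nrow(signal)) {
    stop_invalid("propagation must be 4 x n_eeg (got %dx%d for %d EEG channels)",
                 nrow(propagation), ncol(propagation), nrow(signal))
  }
  set.seed(derive_seed(seed, "eog"))
  n <- ncol(signal)
  eog <- matrix(0, 4, n, dimnames = list(eog_labels(), NULL))
  poisson_times <- function(rate_per_min) {
    lambda <- rate_per_min / 60 / fs
    which(stats::runif(n) < lambda)
  }
  blink_on <- poisson_times(blink_rate)
  blen <- round(0.3 * fs)
  bwave <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = blen)))
  blink_iv <- data.frame(onset = integer(), offset = integer())
  for (s0 in blink_on) {
    idx <- s0:min(n, s0 + blen - 1)
    a <- stats::rnorm(1, blink_amp_uv, 0.15 * blink_amp_uv)
    eog["VEOGU", idx] <- eog["VEOGU", idx] + a * bwave[seq_along(idx)]
    eog["VEOGL", idx] <- eog["VEOGL", idx] - 0.4 * a * bwave[seq_along(idx)]
    blink_iv <- rbind(blink_iv,
                      data.frame(onset = s0, offset = idx[length(idx)]))
  }
  sac_on <- poisson_times(saccade_rate)
  slen <- round(0.2 * fs)
  ramp <- round(0.02 * fs)
  swave <- c(seq(0, 1, length.out = ramp), rep(1, slen - 2 * ramp),
             seq(1, 0, length.out = ramp))
  sac_iv <- data.frame(onset = integer(), offset = integer())
  for (s0 in sac_on) {
    idx <- s0:min(n, s0 + slen - 1)
    a <- saccade_amp_uv * sample(c(-1, 1), 1) * stats::runif(1, 0.7, 1.3)
    eog["HEOGL", idx] <- eog["HEOGL", idx] + a * swave[seq_along(idx)]
    eog["HEOGR", idx] <- eog["HEOGR", idx] - a * swave[seq_along(idx)]
    sac_iv <- rbind(sac_iv, data.frame(onset = s0, offset = idx[length(idx)]))
  }
  signal <- signal + t(propagation) %*% eog
  if (eog_noise > 0) {
    eog <- eog + matrix(stats::rnorm(length(eog), sd = eog_noise), nrow = 4)
  }
  list(signal = signal, eog = eog, blink_intervals = blink_iv,
       saccade_intervals = sac_iv)
}

#' Default EOG -> EEG propagation coefficients
#'
#' Vertical EOG propagates frontally (strongest at Fp1/Fp2), the lower
#' vertical channel with opposite sign and smaller gain; horizontal EOG
#' propagates to lateral-frontal sites with opposite signs per hemisphere.
#'
#' @param montage montage data.frame.
#' @return 4 x 19 matrix, rows in [eog_labels()] order.
#' @export
default_propagation <- function(montage = montage_1020()) {
  frontal <- (topography_gaussian("Fp1", 70, montage) +
              topography_gaussian("Fp2", 70, montage)) / 2
  frontal <- frontal / max(frontal)
  left <- topography_gaussian("F7", 60, montage)
  right <- topography_gaussian("F8", 60, montage)
  rbind(VEOGU = 0.35 * frontal, VEOGL = -0.10 * frontal,
        HEOGL = 0.12 * (left - right), HEOGR = -0.12 * (left - right))
}

#' Default behavioural base rates and spreads
#'
#' Means match the child-group behaviour the generator emulates: 6.3%
#' NoGo commissions and Go errors of 3.1% omission / 0.5% fast / 9.9%
#' slow; mean RT 389 ms (between-subject SD 38), RT variability 85 ms.
#'
#' @return named list of rates/parameters.
#' @export
behaviour_base_rates <- function() {
  list(omission = 0.031, fast_rt = 0.005, slow_rt = 0.099, commission = 0.063,
       rt_sd = 85, rt_between_sd = 38, rt_var_spread = 0.2,
       rate_spread = 0.4)
}

#' Synthesise button-press behaviour with planted rank correlations
#'
#' Generates per-trial responses whose subject-level behavioural measures
#' carry the planted Spearman correlations with the driver components'
#' subject-level amplitudes.  `driver_z` holds each driver's standard
#' normal latent (across subjects); each link contributes
#' `r = 2 sin(pi rho / 6)` of its driver's latent to the behavioural
#' propensity latent (Gaussian copula, so Spearman rho is targeted
#' directly), and the propensity is mapped monotonically onto the measure.
#'
#' @param events event table from [schedule_events()].
#' @param driver_z named numeric vector of subject-level standard-normal
#'   latents, one per driver referenced by `links`.
#' @param links list of [behaviour_link_spec()].
#' @param base_rt grand-mean reaction time, ms.
#' @param base list of base rates/spreads, see [behaviour_base_rates()].
#' @param soa_ms SOA, ms.
#' @param seed integer seed.
#' @return list: `responses` (data.frame `trial`, `press_ms` absolute time,
#'   NA when no press), `params` (realised per-subject parameters).
#' @export
synth_behaviour <- function(events, driver_z = numeric(), links = list(),
                            base_rt = 389, base = behaviour_base_rates(),
                            soa_ms = 1100, seed = 1) {
  for (lk in links) {
    if (abs(lk$strength) > 1) stop_invalid("|strength| must be <= 1")
    if (!lk$driver %in% names(driver_z)) {
      stop_invalid("link driver '%s' has no latent in driver_z", lk$driver)
    }
  }
  set.seed(derive_seed(seed, "behaviour"))
  targets <- c("mean_rt", "rt_variability", "omission", "fast_rt",
               "slow_rt", "commission")
  y <- stats::setNames(numeric(6), targets)
  for (tg in targets) {
    lks <- Filter(function(l) l$target == tg, links)
    r <- vapply(lks, function(l) 2 * sin(pi * l$strength / 6), 0)
    z <- vapply(lks, function(l) driver_z[[l$driver]], 0)
    expl <- sum(r^2)
    if (expl > 1) stop_invalid("links to '%s' over-explain the latent", tg)
    y[tg] <- sum(r * z) + sqrt(max(0, 1 - expl)) * stats::rnorm(1)
  }
  p_om <- stats::pnorm(stats::qnorm(base$omission) + base$rate_spread * y["omission"])
  p_fast <- stats::pnorm(stats::qnorm(base$fast_rt) + base$rate_spread * y["fast_rt"])
  p_slow <- stats::pnorm(stats::qnorm(base$slow_rt) + base$rate_spread * y["slow_rt"])
  p_com <- stats::pnorm(stats::qnorm(base$commission) + base$rate_spread * y["commission"])
  mu <- base_rt + base$rt_between_sd * y["mean_rt"]
  sigma <- base$rt_sd * exp(base$rt_var_spread * y["rt_variability"])
  if (base$rt_between_sd == 0) mu <- base_rt
  if (base$rt_var_spread == 0) sigma <- base$rt_sd
  rt_valid <- function(k) {            # truncated normal on (100, 600) ms
    if (sigma == 0) return(rep(pmin(599, pmax(101, mu)), k))
    lo <- stats::pnorm(101, mu, sigma); hi <- stats::pnorm(599, mu, sigma)
    stats::qnorm(stats::runif(k, lo, hi), mu, sigma)
  }
  n <- nrow(events)
  press <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (events$condition[i] == "Go") {
      u <- stats::runif(1)
      if (u < p_om) {
        next                                      # omission: no press
      } else if (u < p_om + p_fast) {
        rt <- stats::runif(1, 40, 100)
      } else if (u < p_om + p_fast + p_slow) {
        rt <- stats::runif(1, 600, min(soa_ms - 50, 950))
      } else {
        rt <- rt_valid(1)
      }
      press[i] <- events$onset_ms[i] + rt
    } else if (stats::runif(1) < p_com) {
      rt <- if (sigma == 0) mu else stats::rnorm(1, mu, sigma)
      rt <- pmin(soa_ms - 50, pmax(150, rt))
      press[i] <- events$onset_ms[i] + rt
    }
  }
  list(responses = data.frame(trial = events$trial, press_ms = press),
       params = list(y = y, mean_rt = unname(mu), rt_sd = unname(sigma),
                     p_omission = unname(p_om), p_fast = unname(p_fast),
                     p_slow = unname(p_slow), p_commission = unname(p_com)))
}
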