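#' Cosine-tapered (Tukey) window
#'
#' Window with a raised-cosine taper over a total fraction `alpha` of the
#' window (alpha/2 per end) and unity in between.  With `alpha = 0.1` the
#' mean gain is ~0.95, whose reciprocal is the 1.05 amplitude correction
#' applied by [amplitude_spectrum()].
#'
#' @param n window length in samples.
#' @param alpha total tapered fraction in (0, 1]; default 0.1.
#' @return numeric vector of length `n`.
#' @export
tukey_window <- function(n, alpha = 0.1) {
  stopifnot(n >= 2, alpha >= 0, alpha <= 1)
  if (alpha == 0) return(rep(1, n))
  w <- rep(1, n)
  m <- round(alpha * n / 2)
  if (m > 0) {
    # half-sample-offset Hann ramps sum to exactly m/2, so the mean gain
    # is exactly 1 - alpha/2 (0.95 for alpha = 0.1, correction 1.05)
    k <- 0:(m - 1)
    ramp <- 0.5 * (1 - cos(pi * (k + 0.5) / m))
    w[1:m] <- ramp
    w[n:(n - m + 1)] <- ramp
  }
  w
}

#' Corrected single-sided prestimulus amplitude spectrum
#'
#' Quantifies a 256-sample (500 ms at 512 Hz) prestimulus segment as a
#' single-sided amplitude spectrum from DC to `fmax` Hz at 1 Hz
#' resolution: the segment is DC-corrected, multiplied by a 10%
#' cosine-taper window, zero-padded to 512 points, Fourier transformed,
#' converted to single-sided amplitudes (2|X_k|/512 for k >= 1, |X_0|/512
#' at DC), and multiplied by the zero-padding correction (x2) and the
#' window correction (reciprocal of the window's mean gain, ~1.05).
#'
#' @param x numeric vector of exactly `n_seg` samples (microvolts).
#' @param fs sampling rate; must equal 512 for the canonical grid.
#' @param n_fft padded DFT length (default 512, giving 1 Hz bins).
#' @param taper_fraction total taper fraction of the window (default 0.1).
#' @param fmax highest retained frequency, Hz (default 30; 31 bins).
#' @param n_seg required segment length (default 256).
#' @return named numeric vector of `fmax + 1` amplitudes (microvolts),
#'   names "0".."30" (Hz).
#' @export
#' @examples
#' t <- (0:255) / 512
#' a <- amplitude_spectrum(6 * sin(2 * pi * 10 * t))
#' stopifnot(abs(a["10"] - 6) / 6 < 0.02)
amplitude_spectrum <- function(x, fs = 512, n_fft = 512L, taper_fraction = 0.1,
                               fmax = 30L, n_seg = 256L) {
  if (length(x) != n_seg) {
    stop_invalid("segment must have exactly %d samples, got %d",
                 n_seg, length(x))
  }
  if (n_fft < n_seg) stop_invalid("n_fft must be >= segment length")
  w <- tukey_window(n_seg, taper_fraction)
  # DC correction removes the window-weighted mean so the windowed segment
  # is exactly zero-mean (the plain mean would leave a residual DC bin)
  xw <- (x - sum(x * w) / sum(w)) * w
  X <- stats::fft(c(xw, rep(0, n_fft - n_seg)))
  df <- fs / n_fft
  bins <- seq(0, fmax, by = 1)
  idx <- round(bins / df) + 1L
  amp <- Mod(X[idx]) / n_fft
  amp[-1] <- 2 * amp[-1]                        # single-sided, k >= 1
  pad_corr <- n_fft / n_seg                     # = 2 for 256 -> 512
  win_corr <- 1 / mean(w)                       # ~= 1.05 for 10% taper
  stats::setNames(amp * pad_corr * win_corr, as.character(bins))
}

#' Spectral correction factors for the canonical settings
#'
#' @return named numeric vector with the window correction (reciprocal
#'   mean gain of the 10% taper, ~1.05) and the zero-padding correction
#'   (2 for 256 -> 512).
#' @export
spectral_corrections <- function(n_seg = 256L, n_fft = 512L,
                                 taper_fraction = 0.1) {
  c(window = 1 / mean(tukey_window(n_seg, taper_fraction)),
    padding = n_fft / n_seg)
}

#' Within-subject mean prestimulus spectra per channel and condition
#'
#' Computes the amplitude spectrum of the prestimulus segment (the `t0`
#' samples before stimulus onset) of every accepted trial and averages the
#' amplitude spectra (not complex spectra) within channel x condition.
#'
#' @param epochs `plk_epochs` after preprocessing (accepted trials used).
#' @param fmax highest frequency, Hz.
#' @return object of class `plk_spectra`: list with `amplitude` (channel x
#'   condition x frequency array, microvolts), `freqs`, `n_trials` (per
#'   condition), `channel_names`, `subject`.
#' @export
mean_spectra <- function(epochs, fmax = 30L) {
  keep <- which(epochs$accepted)
  if (!length(keep)) stop_invalid("no accepted trials")
  eeg <- eeg_index(epochs)
  pre <- seq_len(epochs$t0)                     # [-t0, -1] samples, [-500,0) ms
  conds <- c("Go", "NoGo")
  freqs <- 0:fmax
  nch <- length(eeg)
  amp <- array(0, dim = c(nch, length(conds), length(freqs)),
               dimnames = list(epochs$channel_names[eeg], conds, freqs))
  n_trials <- stats::setNames(integer(2), conds)
  for (ci in seq_along(conds)) {
    tr <- keep[epochs$condition[keep] == conds[ci]]
    if (!length(tr)) stop_invalid("no accepted %s trials", conds[ci])
    n_trials[ci] <- length(tr)
    acc <- matrix(0, nch, length(freqs))
    for (t in tr) {
      seg <- epochs$data[t, eeg, pre, drop = TRUE]
      for (ch in seq_len(nch)) {
        acc[ch, ] <- acc[ch, ] + amplitude_spectrum(seg[ch, ], fs = epochs$fs,
                                                    fmax = fmax,
                                                    n_seg = length(pre))
      }
    }
    amp[, ci, ] <- acc / length(tr)
  }
  structure(list(amplitude = amp, freqs = freqs, n_trials = n_trials,
                 channel_names = epochs$channel_names[eeg],
                 subject = epochs$subject),
            class = "plk_spectra")
}

#' Stack per-subject spectra into a subject x channel x condition x
#' frequency set
#'
#' @param spectra_list list of `plk_spectra`, one per subject.
#' @return object of class `plk_spectrum_set` with `amplitude` (4-d array),
#'   `freqs`, `subjects`, `channel_names`, `n_trials` (subject x condition).
#' @export
spectrum_set <- function(spectra_list) {
  stopifnot(length(spectra_list) >= 1)
  ch <- spectra_list[[1]]$channel_names
  freqs <- spectra_list[[1]]$freqs
  for (s in spectra_list) {
    if (!identical(s$channel_names, ch)) {
      stop_invalid("inconsistent channel sets across subjects")
    }
  }
  subjects <- vapply(spectra_list, function(s) as.character(s$subject), "")
  if (anyNA(subjects) || anyDuplicated(subjects)) {
    subjects <- sprintf("S%02d", seq_along(spectra_list))
  }
  amp <- array(0, dim = c(length(subjects), length(ch), 2, length(freqs)),
               dimnames = list(subjects, ch, c("Go", "NoGo"), freqs))
  ntr <- matrix(0L, length(subjects), 2,
                dimnames = list(subjects, c("Go", "NoGo")))
  for (i in seq_along(spectra_list)) {
    amp[i, , , ] <- spectra_list[[i]]$amplitude
    ntr[i, ] <- spectra_list[[i]]$n_trials
  }
  structure(list(amplitude = amp, freqs = freqs, subjects = subjects,
                 channel_names = ch, n_trials = ntr),
            class = "plk_spectrum_set")
}
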