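# Shared fixtures and independent oracles, all built in code.

fixture_montage <- montage_1020()

# Minimal 23-channel recording with a constant or supplied signal.
make_recording <- function(n_s = 10, fs = 512, fill = 0,
                           events = empty_events(),
                           responses = empty_responses()) {
  ch <- c(eeg_labels(), eog_labels())
  data <- matrix(fill, length(ch), n_s * fs)
  recording(data, fs, ch, events = events, responses = responses)
}

# Epoch set with the canonical grid (564 samples at 512 Hz, t0 = 256).
make_epochs <- function(n_trials = 4, fill = 0, fs = 512,
                        condition = rep(c("Go", "NoGo"), length.out = n_trials),
                        channels = c(eeg_labels(), eog_labels())) {
  arr <- array(fill, dim = c(n_trials, length(channels), 564))
  epoch_set(arr, fs, t0 = 256, channel_names = channels,
            condition = condition)
}

# Brute-force mid-rank Spearman oracle: ranks by pair counting, Pearson by
# explicit sums (independent of rank()/cor()).
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    vapply(seq_along(v), function(i) {
      1 + sum(v < v[i]) + (sum(v == v[i]) - 1) / 2
    }, 0)
  }
  rx <- midrank(x); ry <- midrank(y)
  n <- length(x)
  sx <- sum(rx); sy <- sum(ry)
  num <- n * sum(rx * ry) - sx * sy
  den <- sqrt(n * sum(rx^2) - sx^2) * sqrt(n * sum(ry^2) - sy^2)
  num / den
}

# All permutations of 1..n (matrix, one row per permutation).
all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) {
    blk <- (r + 1):(r + nrow(sub))
    out[blk, pos] <- n
    out[blk, setdiff(seq_len(n), pos)] <- sub
    r <- r + nrow(sub)
  }
  out
}

# Single-sided DFT amplitude of one exact bin, direct formula (oracle for
# the spectra module, no windowing/corrections).
oracle_bin_amplitude <- function(x, k, n_fft = length(x)) {
  n <- length(x)
  w <- exp(-2i * pi * k * (0:(n - 1)) / n_fft)
  2 * Mod(sum(x * w)) / n_fft
}
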