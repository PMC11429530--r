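#' Zero-phase band-pass filter
#'
#' Applies the squared magnitude response of an order-`order` Butterworth
#' high-pass (at `low`) cascaded with an order-`order` Butterworth
#' low-pass (at `high`) in the frequency domain.  The squared response is
#' exactly what a forward-backward (filtfilt) application of the same
#' filter produces, with exactly zero phase shift at every frequency.
#' Signals are odd-reflection padded before the transform to suppress
#' circular edge effects.
#'
#' @param rec `plk_recording`.
#' @param low,high band edges in Hz, 0 < low < high < fs/2.
#' @param order Butterworth order per edge (default 4).
#' @return filtered `plk_recording`.
#' @export
bandpass_zero_phase <- function(rec, low = 0.1, high = 30, order = 4) {
  fs <- rec$fs
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop_invalid("band edges must satisfy 0 < low < high < fs/2")
  }
  for (ch in seq_len(nrow(rec$data))) {
    rec$data[ch, ] <- fft_filter_channel(rec$data[ch, ], fs, low, high, order)
  }
  rec
}

fft_filter_channel <- function(x, fs, low, high, order) {
  n <- length(x)
  pad <- min(n - 1, max(1024L, round(10 * fs)))
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  np <- length(xp)
  nfft <- stats::nextn(np, c(2, 3, 5))
  xp <- c(xp, rep(0, nfft - np))
  f <- c(seq(0, floor(nfft / 2)), seq(-(ceiling(nfft / 2) - 1), -1)) * fs / nfft
  af <- abs(f)
  hp <- ifelse(af == 0, 0, 1 / (1 + (low / pmax(af, 1e-12))^(2 * order)))
  lp <- 1 / (1 + (af / high)^(2 * order))
  H <- hp * lp                       # |H|^2 of each edge: filtfilt response
  y <- Re(stats::fft(stats::fft(xp) * H, inverse = TRUE)) / nfft
  y[(pad + 1):(pad + n)]
}

#' Re-reference to the digital equivalent of linked ears
#'
#' Subtracts the mean of the two ear signals from every EEG channel.  When
#' the recording was referenced online to one ear and only the other ear
#' was recorded as a channel (e.g. `A2`), pass that single channel: the
#' linked-ears equivalent is then `data - A2/2`.
#'
#' @param rec `plk_recording`.
#' @param ear_channels one or two channel labels carrying the ear signals.
#' @param drop_ears drop the ear channels from the output (default TRUE).
#' @return re-referenced `plk_recording`.
#' @export
reref_linked_ears <- function(rec, ear_channels, drop_ears = TRUE) {
  idx <- match(ear_channels, rec$channel_names)
  if (anyNA(idx)) {
    stop_invalid("missing ear channel(s): %s",
                 paste(ear_channels[is.na(idx)], collapse = ", "))
  }
  ref <- if (length(idx) == 2) colMeans(rec$data[idx, , drop = FALSE])
         else rec$data[idx, ] / 2
  eeg <- eeg_index(rec)
  rec$data[eeg, ] <- sweep(rec$data[eeg, , drop = FALSE], 2, ref)
  if (drop_ears) {
    keep <- setdiff(seq_len(nrow(rec$data)), idx)
    rec$data <- rec$data[keep, , drop = FALSE]
    rec$channel_names <- rec$channel_names[keep]
  }
  rec
}

#' Down-sample a recording (Fourier method, anti-aliased)
#'
#' Band-limited resampling by spectral truncation; event and response
#' sample indices are rescaled and rounded to the nearest sample.
#' Up-sampling is not supported.
#'
#' @param rec `plk_recording`.
#' @param target_fs target rate, Hz (<= current rate).
#' @return resampled `plk_recording`.
#' @export
resample_recording <- function(rec, target_fs = 512) {
  if (target_fs > rec$fs) stop_invalid("upsampling is not supported")
  if (target_fs == rec$fs) return(rec)
  n <- ncol(rec$data)
  n_out <- floor(n * target_fs / rec$fs)
  rec$data <- t(apply(rec$data, 1, function(x) {
    X <- stats::fft(x)
    keep <- floor(n_out / 2)
    Y <- complex(length.out = n_out)
    Y[1:(keep + 1)] <- X[1:(keep + 1)]
    Y[(n_out - keep + 1):n_out] <- X[(n - keep + 1):n]
    if (n_out %% 2 == 0) Y[keep + 1] <- Re(Y[keep + 1])
    Re(stats::fft(Y, inverse = TRUE)) / n * 1  # scale preserved: /n * n_out/n_out
  }))
  # fft inverse above divides by n (input length); amplitude preserved
  rescale <- function(s) pmax(1L, pmin(n_out, as.integer(round((s - 1) * target_fs / rec$fs) + 1L)))
  if (nrow(rec$events)) rec$events$onset_sample <- rescale(rec$events$onset_sample)
  if (nrow(rec$responses)) rec$responses$sample <- rescale(rec$responses$sample)
  rec$fs <- target_fs
  rec
}

#' Extract stimulus-locked epochs for valid trials
#'
#' Epochs span `window_ms` around each stimulus onset, on the grid: sample
#' offset k (relative to onset) covers time k/fs, with
#' k in \[-round(|w1|*fs), round(w2*fs) - 1\]; at 512 Hz and (-500, 600) ms
#' this is 564 samples with 256 prestimulus samples (half-open
#' \[-500, 0) ms).  Only trials classified valid by [classify_trials()]
#' become epochs (valid Go with 100 < RT < 600 ms, valid NoGo without a
#' press in the SOA); onsets too close to the recording edge are dropped
#' with a logged reason.
#'
#' @param rec `plk_recording` with events and responses.
#' @param window_ms two-element vector, default c(-500, 600).
#' @param soa_ms SOA used for trial classification.
#' @return `plk_epochs` (all channels of the recording).
#' @export
extract_epochs <- function(rec, window_ms = c(-500, 600), soa_ms = 1100) {
  fs <- rec$fs
  n_pre <- round(abs(window_ms[1]) / 1000 * fs)        # 256 at 512 Hz
  n_post <- floor(window_ms[2] / 1000 * fs) + 1L       # offsets 0..307 incl.
  n_smp <- n_pre + n_post
  ev <- rec$events
  cls <- classify_trials(ev, rec$responses, soa_ms = soa_ms, fs = fs)
  valid <- cls$category %in% c("valid_go", "valid_nogo")
  n_total <- ncol(rec$data)
  dat <- list(); meta <- list()
  for (i in which(valid)) {
    s0 <- ev$onset_sample[i]
    lo <- s0 - n_pre; hi <- s0 + n_post - 1
    if (lo < 1 || hi > n_total) {
      message(sprintf("trial %d dropped: epoch outside recording", i))
      next
    }
    dat[[length(dat) + 1L]] <- rec$data[, lo:hi, drop = FALSE]
    meta[[length(meta) + 1L]] <- list(trial = i, cond = ev$condition[i],
                                      rt = cls$rt_ms[i])
  }
  if (!length(dat)) stop_invalid("no valid epochs could be extracted")
  arr <- array(0, dim = c(length(dat), nrow(rec$data), n_smp))
  for (j in seq_along(dat)) arr[j, , ] <- dat[[j]]
  epoch_set(arr, fs, t0 = n_pre, channel_names = rec$channel_names,
            condition = vapply(meta, `[[`, "", "cond"),
            trial_id = vapply(meta, function(m) m$trial, 0L),
            rt_ms = vapply(meta, function(m) m$rt %||% NA_real_, 0))
}

#' Automated surrogate for the manual EOG quality screen
#'
#' Rejects trials whose EOG channels contain a flatline (maximum voltage
#' change below `flat_delta` within any ~100 ms window) or a clipped
#' plateau (>= 50 ms pinned at the channel's extremum beyond `clip_uv`),
#' standing in for a manual visual inspection pass.
#'
#' @param epochs `plk_epochs` containing EOG channels.
#' @param flat_delta microvolts (default 0.05).
#' @param clip_uv plateau amplitude threshold (default 500).
#' @return `plk_epochs` with offending trials rejected (reason
#'   "eog_screen").
#' @export
screen_eog_dropouts <- function(epochs, flat_delta = 0.05, clip_uv = 500) {
  eog <- eog_index(epochs)
  fs <- epochs$fs
  nwin <- max(2L, round(0.1 * fs))
  nclip <- max(2L, round(0.05 * fs))
  n_tr <- dim(epochs$data)[1]; n_smp <- dim(epochs$data)[3]
  bad <- rep(FALSE, n_tr)
  for (ch in eog) {
    M <- matrix(epochs$data[, ch, ], n_tr, n_smp)
    bad <- bad | flat_window_rows(M, nwin, flat_delta)
    mx <- apply(abs(M), 1, max)
    for (tr in which(mx > clip_uv & !bad)) {
      at_ext <- abs(abs(M[tr, ]) - mx[tr]) < 1e-9
      if (max_run_length(at_ext) >= nclip) bad[tr] <- TRUE
    }
  }
  reject_trials(epochs, bad, "eog_screen")
}

max_run_length <- function(b) {
  if (!any(b)) return(0L)
  r <- rle(b)
  max(r$lengths[r$values])
}

# TRUE when some window of `nwin` consecutive samples has range < delta.
# Rolling extremes by doubling (O(n log w), fully vectorised).
has_flat_window <- function(x, nwin, delta) {
  n <- length(x)
  if (n < nwin) return(FALSE)
  mx <- x; mn <- x; s <- 1L
  while (2L * s <= nwin) {
    m <- length(mx) - s
    mx <- pmax(mx[1:m], mx[(s + 1):(m + s)])
    mn <- pmin(mn[1:m], mn[(s + 1):(m + s)])
    s <- 2L * s
  }
  if (s < nwin) {
    k <- nwin - s
    m <- length(mx) - k
    mx <- pmax(mx[1:m], mx[(k + 1):(m + k)])
    mn <- pmin(mn[1:m], mn[(k + 1):(m + k)])
  }
  any(mx - mn < delta)
}

#' Regression-based ocular artifact correction (EMCP)
#'
#' The eye-movement correction procedure: (1) blink samples are detected
#' on the upper vertical EOG channel (|VEOGU| beyond 3 robust SDs,
#' median-absolute-deviation based, dilated by +/-50 ms); (2) condition
#' event-related averages are subtracted from EEG and EOG to form
#' residuals; (3) propagation coefficients are estimated by least squares
#' of residual EEG on residual EOG, separately for blink and non-blink
#' samples; (4) the raw epochs are corrected by subtracting EOG times the
#' coefficients, using the blink coefficients within blink samples and the
#' saccade (non-blink) coefficients elsewhere.
#'
#' @param epochs `plk_epochs` holding both EEG and EOG channels.
#' @return list: `epochs` (corrected), `model` (list with
#'   `blink_coefficients`, `saccade_coefficients` (n_EOG x n_EEG),
#'   `blink_mask` trial x sample logical).
#' @export
emcp_correct <- function(epochs) {
  eeg <- eeg_index(epochs); eog <- eog_index(epochs)
  d <- epochs$data
  n_tr <- dim(d)[1]; n_smp <- dim(d)[3]
  veogu <- d[, eog[1], , drop = TRUE]
  if (is.null(dim(veogu))) veogu <- matrix(veogu, nrow = n_tr)
  rsd <- stats::mad(as.numeric(veogu))
  if (rsd < 1e-12) {
    zero <- matrix(0, length(eog), length(eeg),
                   dimnames = list(epochs$channel_names[eog],
                                   epochs$channel_names[eeg]))
    if (all(abs(d[, eog, ]) < 1e-12)) {
      warning("zero-variance EOG: correction skipped, coefficients zero")
      return(list(epochs = epochs,
                  model = list(blink_coefficients = zero,
                               saccade_coefficients = zero,
                               blink_mask = matrix(FALSE, n_tr, n_smp))))
    }
  }
  blink <- abs(veogu) > 3 * rsd
  dil <- max(1L, round(0.05 * epochs$fs))
  for (tr in seq_len(n_tr)) {
    idx <- which(blink[tr, ])
    if (length(idx)) {
      grow <- unique(pmax(1L, pmin(n_smp, rep(idx, each = 2 * dil + 1) +
                                     (-dil):dil)))
      blink[tr, grow] <- TRUE
    }
  }
  # residuals: remove condition-wise event-related averages
  res <- d
  for (cond in unique(epochs$condition)) {
    tr <- which(epochs$condition == cond)
    avg <- colMeans(d[tr, , , drop = FALSE], dims = 1)
    for (t in tr) res[t, , ] <- d[t, , ] - avg
  }
  # trial x sample matrices per channel (cheap reshapes)
  res_mat <- function(ch) matrix(res[, ch, ], n_tr, n_smp)
  raw_mat <- function(ch) matrix(d[, ch, ], n_tr, n_smp)
  fit_coef <- function(mask) {
    if (sum(mask) < 10 * length(eog)) {
      return(matrix(0, length(eog), length(eeg)))
    }
    Em <- vapply(eog, function(ch) res_mat(ch)[mask], numeric(sum(mask)))
    Ym <- vapply(eeg, function(ch) res_mat(ch)[mask], numeric(sum(mask)))
    XtX <- crossprod(Em)
    if (rcond(XtX) < 1e-12) return(matrix(0, length(eog), length(eeg)))
    solve(XtX, crossprod(Em, Ym))
  }
  B_blink <- fit_coef(blink)
  B_sacc <- fit_coef(!blink)
  dimnames(B_blink) <- dimnames(B_sacc) <-
    list(epochs$channel_names[eog], epochs$channel_names[eeg])
  Ek <- lapply(eog, raw_mat)
  Ek_blink <- lapply(Ek, function(M) M * blink)
  for (j in seq_along(eeg)) {
    corr <- 0
    for (k in seq_along(eog)) {
      corr <- corr + Ek[[k]] * B_sacc[k, j] +
        Ek_blink[[k]] * (B_blink[k, j] - B_sacc[k, j])
    }
    epochs$data[, eeg[j], ] <- raw_mat(eeg[j]) - corr
  }
  list(epochs = epochs,
       model = list(blink_coefficients = B_blink,
                    saccade_coefficients = B_sacc, blink_mask = blink))
}

#' Spherical-spline interpolation of bad channels
#'
#' Replaces up to 3 bad scalp channels by spherical-spline estimates
#' (Perrin-style, order m = 4, 50 Legendre terms, regularisation 1e-5)
#' from the remaining scalp channels.  More than 3 bad channels is a hard
#' error (the pipeline's cap).
#'
#' @param epochs `plk_epochs`.
#' @param bad_channels character vector of scalp labels (possibly empty).
#' @param montage montage data.frame.
#' @param m spline order (default 4).
#' @param lambda regularisation (default 1e-5).
#' @return `plk_epochs` with bad channels replaced.
#' @export
interpolate_channels <- function(epochs, bad_channels, montage = montage_1020(),
                                 m = 4, lambda = 1e-5) {
  if (!length(bad_channels)) return(epochs)
  if (length(bad_channels) > 3) {
    stop_invalid("at most 3 of the 19 channels may be interpolated (got %d)",
                 length(bad_channels))
  }
  eeg <- eeg_index(epochs)
  labs <- epochs$channel_names[eeg]
  bad <- match(bad_channels, labs)
  if (anyNA(bad)) stop_invalid("unknown scalp channel(s) to interpolate")
  good <- setdiff(seq_along(labs), bad)
  P <- as.matrix(montage_1020(labs)[, c("x", "y", "z")])
  G <- gfun_matrix(P[good, , drop = FALSE], P[good, , drop = FALSE], m)
  Gb <- gfun_matrix(P[bad, , drop = FALSE], P[good, , drop = FALSE], m)
  ng <- length(good)
  A <- rbind(cbind(G + diag(lambda, ng), rep(1, ng)), c(rep(1, ng), 0))
  # mapping matrix: interpolated = Gb C + d, with [C; d] = A^-1 [y; 0]
  Ai <- solve(A)
  M <- cbind(Gb, rep(1, length(bad))) %*% Ai[, seq_len(ng), drop = FALSE]
  for (tr in seq_len(dim(epochs$data)[1])) {
    Y <- epochs$data[tr, eeg[good], , drop = TRUE]   # ngood x nsmp
    epochs$data[tr, eeg[bad], ] <- M %*% Y
  }
  epochs
}

# Perrin g-function between two position sets (unit sphere), order m.
gfun_matrix <- function(A, B, m, n_terms = 50) {
  X <- A %*% t(B)
  X[] <- pmin(1, pmax(-1, X))     # clamp; [] keeps the matrix dims
  g <- matrix(0, nrow(X), ncol(X))
  Pn_1 <- matrix(1, nrow(X), ncol(X))   # P_0
  Pn <- X                               # P_1
  for (n in seq_len(n_terms)) {
    if (n > 1) {
      Pn_next <- ((2 * n - 1) * X * Pn - (n - 1) * Pn_1) / n
      Pn_1 <- Pn; Pn <- Pn_next
    }
    g <- g + (2 * n + 1) / (n^m * (n + 1)^m) * Pn
  }
  g / (4 * pi)
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the baseline window
#' (half-open, default \[-100, 0) ms).
#'
#' @param epochs `plk_epochs`.
#' @param window_ms two-element vector, default c(-100, 0).
#' @return baseline-corrected `plk_epochs`.
#' @export
baseline_correct <- function(epochs, window_ms = c(-100, 0)) {
  tms <- epoch_times_ms(epochs)
  sel <- which(tms >= window_ms[1] & tms < window_ms[2])
  if (!length(sel)) stop_invalid("baseline window outside the epoch")
  base <- rowMeans(epochs$data[, , sel, drop = FALSE], dims = 2)
  epochs$data <- epochs$data - c(base)   # recycles over the sample dim
  epochs
}

#' Default automatic artifact rejection thresholds
#' @return list with `extreme_abs` (150), `jump` (50), `flat_delta`
#'   (0.05, all microvolts) and `flat_window_ms` (100).
#' @export
default_thresholds <- function() {
  list(extreme_abs = 150, jump = 50, flat_delta = 0.05, flat_window_ms = 100)
}

#' Three-step automatic artifact rejection
#'
#' A trial is rejected when ANY scalp EEG channel (EOG excluded) violates
#' any criterion: absolute amplitude strictly above `extreme_abs`; a
#' voltage jump strictly above `jump` between consecutive samples; or a
#' maximum voltage change strictly below `flat_delta` within some ~100 ms
#' window (flatline).  The first violated criterion (checked in that
#' order) is recorded as the reason.
#'
#' @param epochs `plk_epochs`.
#' @param thresholds list as from [default_thresholds()].
#' @return `plk_epochs` with rejections applied.
#' @export
artifact_reject_auto <- function(epochs, thresholds = default_thresholds()) {
  stopifnot(thresholds$extreme_abs > 0, thresholds$jump > 0,
            thresholds$flat_delta > 0, thresholds$flat_window_ms > 0)
  eeg <- eeg_index(epochs)
  nwin <- max(2L, round(thresholds$flat_window_ms / 1000 * epochs$fs))
  n_smp <- dim(epochs$data)[3]
  d <- epochs$data[, eeg, , drop = FALSE]
  n_tr <- dim(d)[1]
  flat_d <- abs(matrix(d[, , -1, drop = FALSE] - d[, , -n_smp, drop = FALSE],
                       nrow = n_tr))
  jump <- apply(flat_d, 1, max) > thresholds$jump
  extreme <- apply(abs(matrix(d, nrow = n_tr)), 1, max) > thresholds$extreme_abs
  flat <- rep(FALSE, n_tr)
  for (ch in seq_along(eeg)) {
    M <- matrix(d[, ch, ], n_tr, n_smp)
    flat <- flat | flat_window_rows(M, nwin, thresholds$flat_delta)
  }
  reason <- ifelse(extreme, "extreme",
                   ifelse(jump, "jump", ifelse(flat, "flat", NA)))
  for (tr in which(epochs$accepted & !is.na(reason))) {
    epochs <- reject_trials(epochs, tr, reason[tr])
  }
  epochs
}

# Row-wise version of has_flat_window: TRUE per row when some window of
# nwin consecutive columns has range < delta.
flat_window_rows <- function(M, nwin, delta) {
  n <- ncol(M)
  if (n < nwin) return(rep(FALSE, nrow(M)))
  mx <- M; mn <- M; s <- 1L
  shrink <- function(A, k) A[, 1:(ncol(A) - k), drop = FALSE]
  shift <- function(A, k) A[, (k + 1):ncol(A), drop = FALSE]
  while (2L * s <= nwin) {
    mx <- pmax(shrink(mx, s), shift(mx, s))
    mn <- pmin(shrink(mn, s), shift(mn, s))
    s <- 2L * s
  }
  if (s < nwin) {
    k <- nwin - s
    mx <- pmax(shrink(mx, k), shift(mx, k))
    mn <- pmin(shrink(mn, k), shift(mn, k))
  }
  rowSums(mx - mn < delta) > 0
}

#' Reject trials with a button press in the prestimulus period
#'
#' A trial whose prestimulus window (half-open \[-t0/fs, 0) relative to
#' onset) overlaps any press is rejected; a press exactly at the stimulus
#' onset sample is retained.
#'
#' @param epochs `plk_epochs`.
#' @param responses response table of the source recording
#'   (`sample` column, same sample grid as the epochs' source).
#' @param onsets onset sample per trial of the source recording, indexed
#'   by `trial_id`.
#' @return `plk_epochs` with contaminated trials rejected (reason
#'   "prestim_press").
#' @export
reject_prestim_response <- function(epochs, responses, onsets) {
  if (!nrow(responses)) return(epochs)
  press <- responses$sample
  for (tr in which(epochs$accepted)) {
    s0 <- onsets[epochs$trial_id[tr]]
    if (any(press >= s0 - epochs$t0 & press < s0)) {
      epochs <- reject_trials(epochs, tr, "prestim_press")
    }
  }
  epochs
}

#' Match accepted trial counts between Go and NoGo
#'
#' Sets both conditions' accepted counts to the minimum of the two by
#' subsampling the surplus condition uniformly without replacement under
#' the seed (e.g. 61 accepted Go and 68 accepted NoGo become 61 and 61).
#'
#' @param epochs `plk_epochs`.
#' @param seed integer seed.
#' @return `plk_epochs` with surplus trials rejected (reason "match").
#' @export
match_trial_counts <- function(epochs, seed = 1) {
  go <- which(epochs$accepted & epochs$condition == "Go")
  ng <- which(epochs$accepted & epochs$condition == "NoGo")
  if (!length(go) || !length(ng)) {
    stop_invalid("zero accepted trials in one condition (Go=%d, NoGo=%d)",
                 length(go), length(ng))
  }
  k <- min(length(go), length(ng))
  set.seed(derive_seed(seed, "match"))
  if (length(go) > k) {
    drop <- setdiff(go, sort(sample(go, k)))
    epochs <- reject_trials(epochs, drop, "match")
  }
  if (length(ng) > k) {
    drop <- setdiff(ng, sort(sample(ng, k)))
    epochs <- reject_trials(epochs, drop, "match")
  }
  epochs
}

#' Full preprocessing chain for one recording
#'
#' Fixed stage order: band-pass filter -> (linked-ears re-reference when an
#' ear channel is present) -> (down-sample to 512 Hz when faster) -> epoch
#' valid trials -> EOG dropout screen -> EMCP ocular correction ->
#' spherical interpolation of listed bad channels -> baseline correction
#' -> automatic artifact rejection -> prestimulus-response rejection ->
#' Go/NoGo trial-count matching.
#'
#' @param rec `plk_recording` (19 EEG + 4 EOG channels, optional ear).
#' @param subject subject identifier carried into the epochs.
#' @param seed integer seed (used by the matching stage).
#' @param bad_channels scalp labels to interpolate (default none).
#' @param thresholds rejection thresholds.
#' @param window_ms,baseline_ms epoch and baseline windows.
#' @param soa_ms SOA, ms.
#' @param ear_channels labels of recorded ear channels, if any.
#' @return list: `epochs` (`plk_epochs`), `emcp` (fitted model), `counts`
#'   (named per-stage accepted-trial counts, the epoch-accounting
#'   manifest).
#' @export
preprocess_recording <- function(rec, subject = NA_character_, seed = 1,
                                 bad_channels = character(),
                                 thresholds = default_thresholds(),
                                 window_ms = c(-500, 600),
                                 baseline_ms = c(-100, 0), soa_ms = 1100,
                                 ear_channels = intersect(c("A1", "A2"),
                                                          rec$channel_names)) {
  counts <- c()
  rec <- bandpass_zero_phase(rec)
  if (length(ear_channels)) rec <- reref_linked_ears(rec, ear_channels)
  if (rec$fs > 512) rec <- resample_recording(rec, 512)
  ep <- extract_epochs(rec, window_ms, soa_ms = soa_ms)
  ep$subject <- subject
  counts["epoched"] <- sum(ep$accepted)
  ep <- screen_eog_dropouts(ep)
  counts["eog_screen"] <- sum(ep$accepted)
  fit <- emcp_correct(ep)
  ep <- fit$epochs
  ep <- interpolate_channels(ep, bad_channels)
  ep <- baseline_correct(ep, baseline_ms)
  ep <- artifact_reject_auto(ep, thresholds)
  counts["auto_reject"] <- sum(ep$accepted)
  ep <- reject_prestim_response(ep, rec$responses, rec$events$onset_sample)
  counts["prestim_press"] <- sum(ep$accepted)
  ep <- match_trial_counts(ep, seed = seed)
  counts["matched_go"] <- sum(ep$accepted & ep$condition == "Go")
  counts["matched_nogo"] <- sum(ep$accepted & ep$condition == "NoGo")
  list(epochs = ep, emcp = fit$model, counts = counts)
}
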