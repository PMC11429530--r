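#' Condition-mean ERPs on the half-sampled analysis grid
#'
#' Averages the accepted, matched trials per condition, crops to the ERP
#' window and half-samples to 256 Hz by keeping every second sample: from
#' the 512 Hz epoch grid (offsets k in \[-256, 307\]), even offsets are
#' kept (k256 = k/2) and the window -100..600 ms retains k256 in
#' \[-25, 153\] - exactly 179 samples at 3.90625 ms resolution.
#'
#' @param epochs preprocessed `plk_epochs` (baseline-corrected, matched).
#' @param window_ms analysis window (default c(-100, 600)).
#' @return list of class `plk_erp`: `data` (channel x condition x sample
#'   array, microvolts), `times_ms`, `channel_names`, `subject`,
#'   `n_trials` per condition.
#' @export
average_erps <- function(epochs, window_ms = c(-100, 600)) {
  keep <- which(epochs$accepted)
  if (!length(keep)) stop_invalid("no accepted trials to average")
  eeg <- eeg_index(epochs)
  n_smp <- dim(epochs$data)[3]
  k512 <- (seq_len(n_smp) - 1) - epochs$t0       # offsets relative to onset
  half <- which(k512 %% 2 == 0)
  k256 <- k512[half] / 2
  tms <- k256 / (epochs$fs / 2) * 1000
  sel <- half[tms >= window_ms[1] & tms <= window_ms[2]]
  tms <- tms[tms >= window_ms[1] & tms <= window_ms[2]]
  conds <- c("Go", "NoGo")
  out <- array(0, dim = c(length(eeg), 2, length(sel)),
               dimnames = list(epochs$channel_names[eeg], conds, NULL))
  n_trials <- stats::setNames(integer(2), conds)
  for (ci in seq_along(conds)) {
    tr <- keep[epochs$condition[keep] == conds[ci]]
    if (!length(tr)) stop_invalid("no accepted %s trials", conds[ci])
    n_trials[ci] <- length(tr)
    out[, ci, ] <- apply(epochs$data[tr, eeg, sel, drop = FALSE],
                         c(2, 3), mean)
  }
  structure(list(data = out, times_ms = tms,
                 channel_names = epochs$channel_names[eeg],
                 subject = epochs$subject, n_trials = n_trials),
            class = "plk_erp")
}

#' Stack per-subject ERPs into a subject x channel x condition x sample set
#'
#' @param erp_list list of `plk_erp`, one per subject.
#' @return `plk_erp_set` with a 4-d `data` array.
#' @export
erp_set <- function(erp_list) {
  stopifnot(length(erp_list) >= 1)
  ch <- erp_list[[1]]$channel_names
  tms <- erp_list[[1]]$times_ms
  subjects <- vapply(erp_list, function(e) as.character(e$subject), "")
  if (anyNA(subjects) || anyDuplicated(subjects)) {
    subjects <- sprintf("S%02d", seq_along(erp_list))
  }
  dat <- array(0, dim = c(length(subjects), length(ch), 2, length(tms)),
               dimnames = list(subjects, ch, c("Go", "NoGo"), NULL))
  for (i in seq_along(erp_list)) {
    stopifnot(identical(erp_list[[i]]$channel_names, ch))
    dat[i, , , ] <- erp_list[[i]]$data
  }
  structure(list(data = dat, times_ms = tms, subjects = subjects,
                 channel_names = ch), class = "plk_erp_set")
}
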