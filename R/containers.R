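#' Continuous multichannel recording
#'
#' Central container for continuous data: a channel x sample matrix in
#' microvolts, sampling rate, ordered channel labels, a stimulus event
#' table and a button-press table.  Sample indices are 1-based; event and
#' response onsets are stored as sample indices into `data`.
#'
#' @param data numeric matrix, channels x samples, microvolts.
#' @param fs sampling rate, Hz (> 0).
#' @param channel_names unique labels, one per row of `data`.
#' @param events data.frame with columns `onset_sample`, `condition`
#'   ("Go"/"NoGo"), `block`.
#' @param responses data.frame with column `sample` (button presses).
#' @return object of class `plk_recording`.
#' @export
recording <- function(data, fs, channel_names,
                      events = empty_events(), responses = empty_responses()) {
  data <- as.matrix(data)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop_invalid("fs must be a single positive number")
  }
  if (length(channel_names) != nrow(data)) {
    stop_invalid("channel_names length (%d) != number of data rows (%d)",
                 length(channel_names), nrow(data))
  }
  if (anyDuplicated(channel_names)) stop_invalid("channel_names must be unique")
  events <- as.data.frame(events)
  responses <- as.data.frame(responses)
  if (nrow(events) &&
      (any(events$onset_sample < 1) || any(events$onset_sample > ncol(data)))) {
    stop_invalid("event onsets must lie within [1, n_samples]")
  }
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 events = events, responses = responses),
            class = "plk_recording")
}

#' Empty event and response tables
#' @return zero-row data.frames with the canonical columns.
#' @export
empty_events <- function() {
  data.frame(onset_sample = integer(), condition = character(),
             block = integer(), stringsAsFactors = FALSE)
}

#' @rdname empty_events
#' @export
empty_responses <- function() data.frame(sample = integer())

#' @export
print.plk_recording <- function(x, ...) {
  cat(sprintf("<plk_recording> %d ch x %d samples @ %g Hz (%.1f s), %d events, %d presses\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              nrow(x$events), nrow(x$responses)))
  invisible(x)
}

#' Index helpers for the canonical channel sets
#' @param rec a `plk_recording` or `plk_epochs` object.
#' @return integer indices of the EEG (or EOG) channels within the object's
#'   channel ordering.
#' @export
eeg_index <- function(rec) {
  ch <- if (inherits(rec, "plk_recording")) rec$channel_names else rec$channel_names
  idx <- match(eeg_labels(), ch)
  if (anyNA(idx)) {
    stop_invalid("recording lacks EEG channel(s): %s",
                 paste(eeg_labels()[is.na(idx)], collapse = ", "))
  }
  idx
}

#' @rdname eeg_index
#' @export
eog_index <- function(rec) {
  ch <- rec$channel_names
  idx <- match(eog_labels(), ch)
  if (anyNA(idx)) {
    stop_invalid("recording lacks EOG channel(s): %s",
                 paste(eog_labels()[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Stimulus-locked epoch container
#'
#' Trials x channels x samples array with per-trial provenance.  The time
#' grid convention is: sample with offset k (0-based within the epoch,
#' relative to `t0`) has time (k - t0)/fs seconds; `t0` is the 0-based
#' index of the stimulus-onset sample.  At 512 Hz with a (-500, 600) ms
#' window the epoch has 564 samples, t0 = 256, and the prestimulus segment
#' is exactly the 256 samples before onset (half-open [-500, 0) ms).
#'
#' @param data numeric array trial x channel x sample, microvolts.
#' @param fs sampling rate, Hz.
#' @param t0 0-based sample index of stimulus onset within the epoch.
#' @param channel_names labels for dim 2.
#' @param condition factor/character per trial, "Go"/"NoGo".
#' @param trial_id original trial index per epoch (into the full trial log).
#' @param rt_ms reaction time per trial in ms, NA when no press.
#' @param accepted logical per trial; `reason` non-NA iff rejected.
#' @param reason rejection reason per trial (NA when accepted).
#' @param subject optional subject identifier.
#' @return object of class `plk_epochs`.
#' @export
epoch_set <- function(data, fs, t0, channel_names, condition,
                      trial_id = seq_len(dim(data)[1]),
                      rt_ms = rep(NA_real_, dim(data)[1]),
                      accepted = rep(TRUE, dim(data)[1]),
                      reason = rep(NA_character_, dim(data)[1]),
                      subject = NA_character_) {
  stopifnot(length(dim(data)) == 3L)
  n <- dim(data)[1]
  if (dim(data)[2] != length(channel_names)) {
    stop_invalid("channel_names must match dim 2 of data")
  }
  if (t0 < 0 || t0 >= dim(data)[3]) stop_invalid("t0 outside epoch")
  condition <- as.character(condition)
  stopifnot(length(condition) == n, length(accepted) == n,
            length(reason) == n, length(rt_ms) == n, length(trial_id) == n)
  bad <- !accepted & is.na(reason)
  if (any(bad)) stop_invalid("rejected trials must carry a reason")
  if (any(accepted & !is.na(reason))) {
    stop_invalid("accepted trials must not carry a rejection reason")
  }
  structure(list(data = data, fs = fs, t0 = as.integer(t0),
                 channel_names = channel_names, condition = condition,
                 trial_id = as.integer(trial_id), rt_ms = as.numeric(rt_ms),
                 accepted = accepted, reason = reason, subject = subject),
            class = "plk_epochs")
}

#' @export
print.plk_epochs <- function(x, ...) {
  cat(sprintf("<plk_epochs> %d trials (%d accepted) x %d ch x %d samples @ %g Hz, t0=%d\n",
              dim(x$data)[1], sum(x$accepted), dim(x$data)[2], dim(x$data)[3],
              x$fs, x$t0))
  invisible(x)
}

#' Epoch time axis in milliseconds
#' @param epochs a `plk_epochs` object.
#' @return numeric vector, one time (ms, stimulus onset = 0) per sample.
#' @export
epoch_times_ms <- function(epochs) {
  (seq_len(dim(epochs$data)[3]) - 1 - epochs$t0) / epochs$fs * 1000
}

#' Mark trials rejected with a reason
#'
#' Only currently-accepted trials can be rejected; the first recorded
#' reason for a trial is kept (exactly one reason per rejected trial).
#' @param epochs `plk_epochs`.
#' @param which logical or integer index of trials to reject.
#' @param reason single string.
#' @return updated `plk_epochs`.
#' @export
reject_trials <- function(epochs, which, reason) {
  idx <- if (is.logical(which)) which(which) else as.integer(which)
  idx <- idx[epochs$accepted[idx]]
  epochs$accepted[idx] <- FALSE
  epochs$reason[idx] <- reason
  epochs
}

#' Keep only accepted trials
#' @param epochs `plk_epochs`.
#' @return `plk_epochs` restricted to accepted trials.
#' @export
accepted_epochs <- function(epochs) {
  keep <- epochs$accepted
  epoch_set(epochs$data[keep, , , drop = FALSE], epochs$fs, epochs$t0,
            epochs$channel_names, epochs$condition[keep],
            trial_id = epochs$trial_id[keep], rt_ms = epochs$rt_ms[keep],
            subject = epochs$subject)
}

#' Per-subject measure table
#'
#' One row per subject; named measure columns tagged with a domain
#' ("EEG", "ERP-Go", "ERP-NoGo", "behaviour") used by the linkage stage to
#' enumerate cross-domain pairs.
#'
#' @param subjects subject identifiers (unique).
#' @param ... named numeric vectors (one value per subject) or a single
#'   data.frame of measures.
#' @param domains named character vector mapping measure column -> domain.
#' @return data.frame of class `plk_measures` with attribute `domains`.
#' @export
measure_table <- function(subjects, ..., domains) {
  cols <- list(...)
  if (length(cols) == 1L && is.data.frame(cols[[1]])) cols <- as.list(cols[[1]])
  if (anyDuplicated(subjects)) stop_invalid("duplicated subject ids")
  if (anyDuplicated(names(cols))) stop_invalid("duplicated measure names")
  if (!all(names(cols) %in% names(domains))) {
    stop_invalid("every measure column needs a domain tag")
  }
  out <- data.frame(subject = subjects, stringsAsFactors = FALSE)
  for (nm in names(cols)) out[[nm]] <- as.numeric(cols[[nm]])
  attr(out, "domains") <- domains[names(cols)]
  class(out) <- c("plk_measures", "data.frame")
  out
}

#' Combine measure tables by subject
#' @param ... `plk_measures` objects sharing the same subjects.
#' @return merged `plk_measures`.
#' @export
bind_measures <- function(...) {
  tabs <- list(...)
  out <- tabs[[1]]
  doms <- attr(out, "domains")
  for (tb in tabs[-1]) {
    if (!identical(tb$subject, out$subject)) {
      stop_invalid("measure tables must share an identical subject column")
    }
    for (nm in setdiff(names(tb), "subject")) {
      if (nm %in% names(out)) stop_invalid("duplicated measure name '%s'", nm)
      out[[nm]] <- tb[[nm]]
    }
    doms <- c(doms, attr(tb, "domains"))
  }
  attr(out, "domains") <- doms
  class(out) <- c("plk_measures", "data.frame")
  out
}
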