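#' Classify Go/NoGo trials from events and button presses
#'
#' The first press after each stimulus onset and strictly before
#' onset + SOA determines that trial's RT (later presses in the window are
#' ignored).  Go trials: no press in the SOA window -> omission;
#' RT <= 100 ms -> fast_rt; RT >= 600 ms -> slow_rt; otherwise (open
#' interval 100-600 ms) -> valid_go.  NoGo trials: any press in the SOA
#' window -> commission, otherwise valid_nogo.
#'
#' @param events data.frame with `condition` and either `onset_ms` or
#'   `onset_sample` (requires `fs`); must be sorted by onset.
#' @param responses data.frame with `press_ms` or `sample` (requires `fs`).
#' @param soa_ms SOA window, ms.
#' @param fs sampling rate used to convert sample columns to ms.
#' @return data.frame: `trial`, `condition`, `category`, `rt_ms` (NA when
#'   no press fell in the window).
#' @export
classify_trials <- function(events, responses, soa_ms = 1100, fs = NULL) {
  onset <- if ("onset_ms" %in% names(events)) {
    events$onset_ms
  } else {
    if (is.null(fs)) stop_invalid("fs required to convert onset samples")
    (events$onset_sample - 1) / fs * 1000
  }
  if (is.unsorted(onset)) stop_invalid("events must be sorted by onset")
  press <- if (!nrow(responses)) {
    numeric()
  } else if ("press_ms" %in% names(responses)) {
    responses$press_ms[!is.na(responses$press_ms)]
  } else {
    if (is.null(fs)) stop_invalid("fs required to convert response samples")
    (responses$sample - 1) / fs * 1000
  }
  press <- sort(press)
  n <- nrow(events)
  category <- character(n)
  rt_ms <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    w <- press[press > onset[i] & press < onset[i] + soa_ms]
    if (length(w)) rt_ms[i] <- w[1] - onset[i]
    if (events$condition[i] == "Go") {
      category[i] <- if (is.na(rt_ms[i])) "omission"
        else if (rt_ms[i] <= 100) "fast_rt"
        else if (rt_ms[i] >= 600) "slow_rt"
        else "valid_go"
    } else {
      category[i] <- if (is.na(rt_ms[i])) "valid_nogo" else "commission"
    }
  }
  data.frame(trial = seq_len(n), condition = events$condition,
             category = category, rt_ms = rt_ms, stringsAsFactors = FALSE)
}

#' Summarise behaviour: error percentages and RT statistics
#'
#' Error percentages are computed over all presented trials of the
#' relevant condition (the full trial log, before any epoch rejection);
#' mean RT and RT variability (SD, n-1 denominator) are computed over the
#' assessed Go trials only (those surviving preprocessing).  With zero
#' assessed Go trials the RT fields are NA but the summary is still
#' produced.
#'
#' @param classes output of [classify_trials()].
#' @param assessed_go_rts RTs (ms) of the Go trials that survived
#'   preprocessing; defaults to all valid Go RTs in `classes`.
#' @return one-row data.frame: `commission_pct`, `total_go_error_pct`,
#'   `omission_pct`, `fast_rt_pct`, `slow_rt_pct`, `mean_rt`,
#'   `rt_variability`.
#' @export
summarise_behaviour <- function(classes,
                                assessed_go_rts = classes$rt_ms[
                                  classes$category == "valid_go"]) {
  n_go <- sum(classes$condition == "Go")
  n_nogo <- sum(classes$condition == "NoGo")
  pct <- function(k, n) if (n > 0) 100 * k / n else NA_real_
  omission <- pct(sum(classes$category == "omission"), n_go)
  fast <- pct(sum(classes$category == "fast_rt"), n_go)
  slow <- pct(sum(classes$category == "slow_rt"), n_go)
  commission <- pct(sum(classes$category == "commission"), n_nogo)
  rts <- assessed_go_rts[!is.na(assessed_go_rts)]
  data.frame(
    commission_pct = commission,
    total_go_error_pct = omission + fast + slow,
    omission_pct = omission, fast_rt_pct = fast, slow_rt_pct = slow,
    mean_rt = if (length(rts)) mean(rts) else NA_real_,
    rt_variability = if (length(rts) > 1) stats::sd(rts) else
      if (length(rts) == 1) 0 else NA_real_)
}

#' Behavioural measure table for a group
#'
#' @param class_list list of per-subject [classify_trials()] outputs.
#' @param assessed_rts list of per-subject assessed Go RT vectors.
#' @param subjects subject identifiers.
#' @return `plk_measures` with the seven behavioural columns tagged
#'   domain "behaviour".
#' @export
behaviour_measures <- function(class_list, assessed_rts = NULL,
                               subjects = sprintf("S%02d",
                                                  seq_along(class_list))) {
  rows <- lapply(seq_along(class_list), function(i) {
    if (is.null(assessed_rts)) summarise_behaviour(class_list[[i]])
    else summarise_behaviour(class_list[[i]], assessed_rts[[i]])
  })
  tab <- do.call(rbind, rows)
  doms <- stats::setNames(rep("behaviour", ncol(tab)), names(tab))
  measure_table(subjects, tab, domains = doms)
}
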