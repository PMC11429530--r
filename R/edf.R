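#' Write a recording to EDF
#'
#' Plain EDF (16-bit, 1-second data records); physical dimension uV, per
#' channel physical range set symmetrically from the data.  Stimulus
#' events and button presses are written to CSV sidecars
#' (`<stem>_events.csv`, `<stem>_responses.csv`) - the label convention
#' documented in the README - because plain EDF carries no annotations.
#' The signal is zero-padded to a whole number of records.
#'
#' @param rec `plk_recording`.
#' @param path output path (".edf").
#' @return invisibly, the paths written.
#' @export
write_edf <- function(rec, path) {
  data <- rec$data
  ns <- nrow(data)
  fs <- round(rec$fs)
  n_rec <- ceiling(ncol(data) / fs)
  pad <- n_rec * fs - ncol(data)
  if (pad > 0) data <- cbind(data, matrix(0, ns, pad))
  # round the physical range UP at the printed precision so no sample clips
  phys_max <- ceiling(pmax(apply(abs(data), 1, max), 1) * 100 + 1e-6) / 100
  phys_min <- -phys_max
  dig_max <- 32767; dig_min <- -32768
  con <- file(path, "wb")
  on.exit(close(con))
  pad_field <- function(x, w) {
    x <- as.character(x)
    out <- formatC(substr(x, 1, w), width = -w)  # left-justified, padded
    out
  }
  wr <- function(x, w) writeChar(paste0(pad_field(x, w), collapse = ""),
                                 con, eos = NULL)
  wr("0", 8)                              # version
  wr("X X X X", 80)                       # patient id (anonymous)
  wr("Startdate X X X X", 80)             # recording id
  wr("01.01.00", 8); wr("00.00.00", 8)    # date, time
  wr(as.character(256 * (ns + 1)), 8)     # header bytes
  wr("", 44)
  wr(as.character(n_rec), 8)
  wr("1", 8)                              # record duration, s
  wr(as.character(ns), 4)
  for (f in list(list(rec$channel_names, 16), list(rep("", ns), 80),
                 list(rep("uV", ns), 8),
                 list(formatC(phys_min, format = "f", digits = 2), 8),
                 list(formatC(phys_max, format = "f", digits = 2), 8),
                 list(rep(dig_min, ns), 8), list(rep(dig_max, ns), 8),
                 list(rep("", ns), 80), list(rep(fs, ns), 8),
                 list(rep("", ns), 32))) {
    wr(f[[1]], f[[2]])
  }
  # re-read the printed physical range so scaling matches what a reader sees
  pmn <- as.numeric(formatC(phys_min, format = "f", digits = 2))
  pmx <- as.numeric(formatC(phys_max, format = "f", digits = 2))
  scale <- (dig_max - dig_min) / (pmx - pmn)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    block <- matrix(0L, fs, ns)
    for (ch in seq_len(ns)) {
      v <- round((data[ch, idx] - pmn[ch]) * scale[ch] + dig_min)
      block[, ch] <- as.integer(pmax(dig_min, pmin(dig_max, v)))
    }
    writeBin(as.vector(block), con, size = 2, endian = "little")
  }
  stem <- sub("\\.edf$", "", path)
  ev_path <- paste0(stem, "_events.csv")
  rp_path <- paste0(stem, "_responses.csv")
  utils::write.csv(rec$events, ev_path, row.names = FALSE)
  utils::write.csv(rec$responses, rp_path, row.names = FALSE)
  invisible(c(path, ev_path, rp_path))
}

#' Read a recording from EDF
#'
#' Reads a plain EDF file written by [write_edf()] (or any single-rate,
#' uV-dimension EDF), converts to microvolts, and attaches events and
#' responses from the CSV sidecars when present.  The file must declare at
#' least 20 channels and contain the four EOG labels; a format error
#' naming the absent labels is raised otherwise.
#'
#' @param path EDF path.
#' @param require_channels check the >= 20 channel / EOG-label contract
#'   (default TRUE).
#' @return `plk_recording`.
#' @export
read_edf <- function(path, require_channels = TRUE) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (require_channels && ns < 20) {
    stop_invalid("EDF declares only %d channels; >= 20 required", ns)
  }
  labels <- trimws(vapply(seq_len(ns), function(i) readChar(con, 16), ""))
  for (i in seq_len(ns)) readChar(con, 80)          # transducer
  dims <- trimws(vapply(seq_len(ns), function(i) readChar(con, 8), ""))
  pmn <- as.numeric(vapply(seq_len(ns), function(i) readChar(con, 8), ""))
  pmx <- as.numeric(vapply(seq_len(ns), function(i) readChar(con, 8), ""))
  dmn <- as.numeric(vapply(seq_len(ns), function(i) readChar(con, 8), ""))
  dmx <- as.numeric(vapply(seq_len(ns), function(i) readChar(con, 8), ""))
  for (i in seq_len(ns)) readChar(con, 80)          # prefilter
  spr <- as.integer(vapply(seq_len(ns), function(i) readChar(con, 8), ""))
  for (i in seq_len(ns)) readChar(con, 32)
  if (length(unique(spr)) != 1) stop_invalid("mixed sampling rates unsupported")
  fs <- spr[1] / rec_dur
  if (require_channels) {
    missing <- setdiff(eog_labels(), labels)
    if (length(missing)) {
      stop_invalid("EDF lacks EOG channel label(s): %s",
                   paste(missing, collapse = ", "))
    }
  }
  scale <- (pmx - pmn) / (dmx - dmn)                # to physical units
  to_uv <- ifelse(tolower(dims) %in% c("mv"), 1000,
                  ifelse(tolower(dims) %in% c("v"), 1e6, 1))
  data <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = ns * spr[1], size = 2,
                   endian = "little")
    block <- matrix(raw, spr[1], ns)
    idx <- ((r - 1) * spr[1] + 1):(r * spr[1])
    for (ch in seq_len(ns)) {
      data[ch, idx] <- (block[, ch] - dmn[ch]) * scale[ch] + pmn[ch]
    }
  }
  data <- data * rep(to_uv, each = 1)
  stem <- sub("\\.edf$", "", path)
  ev_path <- paste0(stem, "_events.csv")
  rp_path <- paste0(stem, "_responses.csv")
  events <- if (file.exists(ev_path)) utils::read.csv(ev_path) else empty_events()
  responses <- if (file.exists(rp_path)) utils::read.csv(rp_path) else empty_responses()
  recording(data, fs, labels, events = events, responses = responses)
}
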