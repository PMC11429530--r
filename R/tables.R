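#' Write tabular outputs as CSV, full precision plus presentation copies
#'
#' Every table is written twice: `<name>.csv` at full precision, and
#' `<name>_presentation.csv` with the field's rounding conventions
#' (correlations and CI bounds to 2 decimal places, p values to 2,
#' percentages to 1, RT milliseconds to 0).
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory (created if needed).
#' @return character vector of the file paths written.
#' @export
write_tables <- function(tables, out_dir) {
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_invalid("cannot create directory %s", out_dir)
  paths <- character()
  for (nm in names(tables)) {
    tab <- as.data.frame(tables[[nm]])
    p1 <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(tab, p1, row.names = FALSE)
    p2 <- file.path(out_dir, paste0(nm, "_presentation.csv"))
    utils::write.csv(round_presentation(tab), p2, row.names = FALSE)
    paths <- c(paths, p1, p2)
  }
  paths
}

#' Apply the presentation rounding conventions to a table
#'
#' @param tab data.frame.
#' @return data.frame with numeric columns rounded: rho/p/CI to 2 dp,
#'   percentage columns (`*_pct`) to 1 dp, millisecond columns to 0 dp,
#'   other numerics to 3 dp.
#' @export
round_presentation <- function(tab) {
  for (nm in names(tab)) {
    if (!is.numeric(tab[[nm]])) next
    dp <- if (nm %in% c("rho", "p", "p_bh", "ci_low", "ci_high")) 2
      else if (grepl("_pct$", nm)) 1
      else if (nm %in% c("mean_rt", "rt_variability")) 0
      else 3
    tab[[nm]] <- round(tab[[nm]], dp)
  }
  tab
}

#' Write a simulated dataset (EDF + truth) to a directory
#'
#' One EDF (plus event/response sidecars) per subject and a JSON truth
#' record with every planted quantity.
#'
#' @param sims output of [simulate_group()].
#' @param out_dir directory.
#' @return invisibly, the directory.
#' @export
write_dataset <- function(sims, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truths <- list()
  for (s in sims) {
    id <- s$truth$subject
    write_edf(s$recording, file.path(out_dir, paste0(id, ".edf")))
    tr <- s$truth
    tr$events <- NULL                      # carried by the sidecars
    truths[[id]] <- tr
  }
  jsonlite::write_json(truths, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Read a simulated dataset directory back
#'
#' @param dir directory written by [write_dataset()].
#' @return list with `recordings` (named list of `plk_recording`) and
#'   `truth` (parsed JSON).
#' @export
read_dataset <- function(dir) {
  edfs <- sort(list.files(dir, pattern = "\\.edf$", full.names = TRUE))
  recs <- lapply(edfs, read_edf)
  names(recs) <- sub("\\.edf$", "", basename(edfs))
  tpath <- file.path(dir, "truth.json")
  truth <- if (file.exists(tpath)) jsonlite::read_json(tpath) else NULL
  list(recordings = recs, truth = truth)
}
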