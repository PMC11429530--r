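#' Default analysis settings
#'
#' Serialises the pipeline's constants: 0.1-30 Hz zero-phase band-pass,
#' -500..600 ms epochs, -100..0 ms baseline, 150/50/0.05 uV rejection
#' thresholds with a 100 ms flatline window, 512-point zero-padded DFT
#' with the ~1.05 window and 2x padding corrections, a 1.5% variance
#' selection threshold, Promax rotation for spectra and Varimax for ERPs.
#'
#' @return named list of settings.
#' @export
run_settings <- function() {
  corr <- spectral_corrections()
  list(filter_low_hz = 0.1, filter_high_hz = 30,
       epoch_window_ms = c(-500, 600), baseline_ms = c(-100, 0),
       soa_ms = 1100, analysis_fs = 512,
       thresholds = default_thresholds(),
       n_fft = 512L, window_correction = unname(corr["window"]),
       padding_correction = unname(corr["padding"]),
       variance_threshold_pct = 1.5,
       fpca_rotation = "promax", tpca_rotation = "varimax",
       promax_kappa = 3)
}

#' Run the full per-group analysis
#'
#' Orchestrates preprocess -> behaviour -> prestimulus spectra -> f-PCA ->
#' ERP averaging -> t-PCA (per condition) -> measure assembly -> Spearman
#' linkage for a list of recordings, optionally writing every stage's
#' tables plus a run manifest to `out_dir`.
#'
#' @param recordings named list of `plk_recording` (one per subject).
#' @param seed integer seed; fans out to per-subject/stage child seeds.
#' @param out_dir optional output directory.
#' @param settings list from [run_settings()].
#' @return list: `measures`, `links`, `fpca`, `tpca` (Go/NoGo),
#'   `spectra`, `erps`, `behaviour`, `manifest`.
#' @export
run_group <- function(recordings, seed = 1, out_dir = NULL,
                      settings = run_settings()) {
  n_sub <- length(recordings)
  subjects <- names(recordings) %||% sprintf("S%02d", seq_len(n_sub))
  spectra_l <- list(); erps_l <- list(); classes_l <- list()
  rts_l <- list(); counts_l <- list()
  for (i in seq_len(n_sub)) {
    rec <- recordings[[i]]
    pp <- preprocess_recording(rec, subject = subjects[i],
                               seed = derive_seed(seed, paste0("pp", i)),
                               thresholds = settings$thresholds,
                               window_ms = settings$epoch_window_ms,
                               baseline_ms = settings$baseline_ms,
                               soa_ms = settings$soa_ms)
    ep <- pp$epochs
    classes_l[[i]] <- classify_trials(rec$events, rec$responses,
                                      soa_ms = settings$soa_ms, fs = rec$fs)
    rts_l[[i]] <- ep$rt_ms[ep$accepted & ep$condition == "Go"]
    spectra_l[[i]] <- mean_spectra(accepted_epochs(ep))
    erps_l[[i]] <- average_erps(ep)
    counts_l[[i]] <- pp$counts
  }
  behaviour <- behaviour_measures(classes_l, rts_l, subjects)
  ss <- spectrum_set(spectra_l)
  es <- erp_set(erps_l)

  fpca <- covariance_pca(assemble_fpca_input(ss))
  fpca <- rotate_components(fpca, settings$fpca_rotation,
                            kappa = settings$promax_kappa)
  fpca <- select_and_scale(fpca, settings$variance_threshold_pct)
  eeg_meas <- peak_amplitudes(fpca, "pooled", prefix = "EEG", domain = "EEG")

  tpca <- list(); erp_meas <- list()
  for (cond in c("Go", "NoGo")) {
    tp <- covariance_pca(assemble_tpca_input(es, cond))
    tp <- rotate_components(tp, settings$tpca_rotation)
    tp <- select_and_scale(tp, settings$variance_threshold_pct)
    tpca[[cond]] <- tp
    erp_meas[[cond]] <- peak_amplitudes(tp, "per_condition", prefix = "ERP",
                                        domain = paste0("ERP-", cond))
  }
  measures <- bind_measures(eeg_meas, erp_meas$Go, erp_meas$NoGo, behaviour)
  links <- build_link_table(measures)
  manifest <- list(seed = seed, settings = settings, subjects = subjects,
                   counts = stats::setNames(counts_l, subjects),
                   n_links = nrow(links))
  out <- list(measures = measures, links = links, fpca = fpca, tpca = tpca,
              spectra = ss, erps = es, behaviour = behaviour,
              manifest = manifest)
  if (!is.null(out_dir)) write_group_outputs(out, out_dir)
  out
}

#' Write the seven per-group artefacts plus the run manifest
#'
#' behaviour.csv, spectra.csv (long format), fpca/ (loadings, summary,
#' amplitudes), tpca-Go/, tpca-NoGo/, measures.csv, links.csv and
#' manifest.json.
#'
#' @param res result of [run_group()].
#' @param out_dir directory.
#' @return invisibly, `out_dir`.
#' @export
write_group_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tables(list(behaviour = res$behaviour,
                    measures = as.data.frame(res$measures),
                    links = res$links,
                    spectra = spectra_long(res$spectra)), out_dir)
  write_component_outputs(res$fpca, file.path(out_dir, "fpca"))
  write_component_outputs(res$tpca$Go, file.path(out_dir, "tpca-Go"))
  write_component_outputs(res$tpca$NoGo, file.path(out_dir, "tpca-NoGo"))
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}

spectra_long <- function(ss) {
  d <- dim(ss$amplitude)
  expand <- expand.grid(subject = ss$subjects, channel = ss$channel_names,
                        condition = c("Go", "NoGo"), freq = ss$freqs,
                        stringsAsFactors = FALSE)
  expand$amplitude <- as.vector(ss$amplitude)
  expand
}

write_component_outputs <- function(comp, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  loadings <- data.frame(variable = comp$variable_axis, comp$pattern)
  names(loadings) <- c(comp$axis_unit, comp$names)
  summary <- data.frame(component = comp$names,
                        pct_variance = comp$pct_variance,
                        peak = comp$peak_variable,
                        unit = comp$axis_unit, selected = comp$selected)
  scores <- data.frame(comp$case_meta, comp$scores)
  names(scores) <- c(names(comp$case_meta), comp$names)
  write_tables(list(loadings = loadings, summary = summary, scores = scores),
               dir)
  invisible(dir)
}
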