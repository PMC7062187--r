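#' Run the full screen-analysis pipeline
#'
#' Orchestrates artifact correction, plate QC and the chosen hit-selection
#' workflows over one screen, writing CSV score tables and a JSON run
#' manifest (seed, thresholds, plate pass/fail counts) to `out_dir`. All
#' randomness (simulation, PLS cross-validation folds) flows from the one
#' root `seed`, so two runs with the same config are byte-identical.
#'
#' The screen is either read from `screen_csv` ([read_screen()]) or
#' simulated (`simulate = TRUE`, via [simulate_screen()] with
#' `sim_config`). Supplying a YAML file path as `config` is equivalent to
#' passing the corresponding argument list.
#'
#' @param screen_csv path of a well-summary CSV, or `NULL` to simulate.
#' @param layout_name plate layout of the screen.
#' @param simulate logical; generate a synthetic screen instead of reading
#'   one.
#' @param sim_config a `ScreenSimConfig` for `simulate = TRUE` (default: a
#'   small screen with a few planted modulators).
#' @param workflows subset of `c("univariate", "pca", "pls")`.
#' @param threshold hit threshold (3 primary, 1.3 secondary).
#' @param qc_cutoff plate QC SSMD cut-off.
#' @param fdr PLS feature-selection FDR.
#' @param seed root RNG seed.
#' @param out_dir output directory (created); `NULL` skips writing.
#' @param config optional YAML file path whose keys override the above.
#' @return (invisibly) a list with `dataset` (corrected), `qc_report`,
#'   one score table per workflow, and `manifest`.
#' @export
run_screen_pipeline <- function(screen_csv = NULL, layout_name = "primary",
                                simulate = is.null(screen_csv),
                                sim_config = NULL,
                                workflows = c("univariate", "pca", "pls"),
                                threshold = 3, qc_cutoff = -2, fdr = 0.05,
                                seed = 1L, out_dir = NULL, config = NULL) {
  if (!is.null(config)) {
    cfg <- yaml::read_yaml(config)
    for (nm in names(cfg)) assign(nm, cfg[[nm]])
  }
  workflows <- match.arg(workflows, several.ok = TRUE)
  truth <- NULL
  if (simulate) {
    sim_config <- sim_config %||% screen_sim_config(
      n_plates = 2L, replicates = 3L, layout_name = layout_name,
      planted_positive_modulators = c("g0001", "g0002"),
      planted_negative_modulators = c("g0003", "g0004"),
      seed = seed
    )
    sim <- simulate_screen(sim_config)
    dataset <- sim$dataset
    truth <- sim$truth
  } else {
    dataset <- read_screen(screen_csv, layout_name = layout_name)
  }

  corr <- correct_dataset(dataset)
  qc <- qc_screen(corr$dataset, cutoff = qc_cutoff)

  results <- list(dataset = corr$dataset, qc_report = qc$report, truth = truth)
  if ("univariate" %in% workflows) {
    results$univariate <- univariate_hits(qc$dataset, threshold = threshold)
  }
  if ("pca" %in% workflows) {
    results$pca <- pca_workflow(qc$dataset, threshold = threshold)
  }
  if ("pls" %in% workflows) {
    results$pls <- pls_pipeline(corr$dataset, threshold = threshold,
                                fdr = fdr, qc_cutoff = qc_cutoff,
                                fold_seed = seed)
  }

  manifest <- list(
    seed = seed, layout = layout_name, workflows = workflows,
    threshold = threshold, qc_cutoff = qc_cutoff, fdr = fdr,
    simulated = simulate,
    n_plate_replicates = nrow(qc$report),
    n_plate_replicates_failed_qc = sum(!qc$report$pass)
  )
  results$manifest <- manifest

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (wf in intersect(workflows, names(results))) {
      readr::write_csv(results[[wf]], file.path(out_dir, paste0(wf, "_scores.csv")),
                       progress = FALSE)
    }
    readr::write_csv(qc$report, file.path(out_dir, "qc_report.csv"),
                     progress = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(results)
}

#' Run the time-lapse puncta pipeline
#'
#' Reads (or takes) a two-channel stack, runs [track_and_group()], and
#' writes the per-cell track table (CSV) plus the peak-window fraction
#' summary (JSON) to `out_dir`.
#'
#' @param stack a `TimelapseStack` or a TIFF path readable by
#'   [read_stack()].
#' @param interval_min frame interval when reading from TIFF.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param ... passed to [track_and_group()].
#' @return (invisibly) the [track_and_group()] result.
#' @export
run_timelapse <- function(stack, interval_min = 15L, out_dir = NULL, ...) {
  if (is.character(stack)) stack <- read_stack(stack, interval_min = interval_min)
  res <- track_and_group(stack, ...)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(res$tracks, file.path(out_dir, "cell_tracks.csv"),
                     progress = FALSE)
    readr::write_csv(res$counts, file.path(out_dir, "cell_counts.csv"),
                     progress = FALSE)
    jsonlite::write_json(as.list(res$summary),
                         file.path(out_dir, "window_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(res)
}
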