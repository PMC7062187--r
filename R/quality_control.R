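#' Gate plate replicates by the QC SSMD
#'
#' Computes [ssmd_qc()] per plate replicate, on either a named readout (the
#' univariate/PCA workflows gate on the lead readout
#' `pct_cells_gt3_puncta`) or on an externally supplied per-well score table
#' (the PLS workflow gates on first-model PLS scores). Plate replicates with
#' `SSMD_QC > cutoff` (default -2) are tagged poor quality and removed from
#' the returned dataset; plate replicates whose controls are missing or
#' degenerate are likewise reported and removed, so that
#' filtered + failed = original.
#'
#' @param dataset a `ScreenDataset`.
#' @param readout a parameter name, or a data frame with columns `plate_id`,
#'   `replicate`, `well`, `score` holding one score per well.
#' @param cutoff pass threshold; a plate passes iff `SSMD_QC <= cutoff`.
#' @return list with `report` (data frame: plate_id, replicate, readout,
#'   ssmd_qc, pass) and `dataset` (passing plate replicates only).
#' @export
qc_screen <- function(dataset, readout = "pct_cells_gt3_puncta", cutoff = -2) {
  stopifnot(inherits(dataset, "ScreenDataset"))
  w <- dataset$wells
  if (is.character(readout) && length(readout) == 1L) {
    if (!readout %in% dataset$parameter_names) {
      stop("lookup error: unknown readout '", readout, "'")
    }
    score <- w[[readout]]
    readout_name <- readout
  } else {
    stopifnot(is.data.frame(readout),
              all(c("plate_id", "replicate", "well", "score") %in% names(readout)))
    idx <- match(paste(w$plate_id, w$replicate, w$well),
                 paste(readout$plate_id, readout$replicate, readout$well))
    score <- readout$score[idx]
    readout_name <- "score"
  }
  pr <- plate_replicates(dataset)
  report <- vector("list", nrow(pr))
  for (i in seq_len(nrow(pr))) {
    sel <- w$plate_id == pr$plate_id[i] & w$replicate == pr$replicate[i]
    pos <- score[sel & w$role == "positive_control"]
    neg <- score[sel & w$role == "negative_control"]
    ssmd <- tryCatch(ssmd_qc(pos, neg)$value,
                     error = function(e) NA_real_,
                     warning = function(w2) NA_real_)
    report[[i]] <- data.frame(
      plate_id = pr$plate_id[i], replicate = pr$replicate[i],
      readout = readout_name, ssmd_qc = ssmd,
      pass = !is.na(ssmd) & ssmd <= cutoff,
      stringsAsFactors = FALSE
    )
  }
  report <- do.call(rbind, report)
  keep_key <- paste(report$plate_id[report$pass], report$replicate[report$pass])
  out <- dataset
  out$wells <- w[paste(w$plate_id, w$replicate) %in% keep_key, , drop = FALSE]
  list(report = report, dataset = out)
}
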