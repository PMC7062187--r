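#' Fit the row/column artifact model of one plate replicate
#'
#' Dispensing order, evaporation and edge effects produce roughly linear
#' positional gradients across a microtiter plate. For one plate replicate
#' and one readout the model
#' `value ~ intercept + row_slope * row + col_slope * col`
#' is fitted by Huber M-estimation (iteratively reweighted least squares,
#' 95\%-efficiency tuning), so a handful of genuine phenotypic outliers do
#' not masquerade as a gradient. Rows are numbered A -> 1 .. H -> 8 and
#' columns 1..12.
#'
#' @param values numeric readout per well (NA allowed, dropped).
#' @param row,col numeric row and column indices per well.
#' @return an `ArtifactFit`: list with `intercept`, `row_slope`, `col_slope`,
#'   `converged`, `n`.
#' @seealso [correct_dataset()]
#' @export
fit_plate_artifact <- function(values, row, col) {
  stopifnot(length(values) == length(row), length(values) == length(col))
  ok <- is.finite(values) & is.finite(row) & is.finite(col)
  if (sum(ok) < 6L) {
    stop("fit error: need >= 6 finite wells to fit the artifact model")
  }
  row <- as.numeric(row[ok]); col <- as.numeric(col[ok]); v <- values[ok]
  if (length(unique(row)) < 2L || length(unique(col)) < 2L) {
    stop("fit error: rank-deficient design (all wells share a row or column)")
  }
  if (stats::sd(v) == 0) {
    # constant plate: robust fit is the constant, no gradient
    return(structure(list(intercept = v[1], row_slope = 0, col_slope = 0,
                          converged = TRUE, n = length(v)),
                     class = "ArtifactFit"))
  }
  fit <- suppressWarnings(
    MASS::rlm(v ~ row + col, psi = MASS::psi.huber, maxit = 100)
  )
  co <- stats::coef(fit)
  structure(
    list(intercept = unname(co[1]), row_slope = unname(co["row"]),
         col_slope = unname(co["col"]), converged = isTRUE(fit$converged),
         n = length(v)),
    class = "ArtifactFit"
  )
}

#' Remove row/column artifacts from a screen dataset
#'
#' For every plate replicate and every listed parameter, fits
#' [fit_plate_artifact()] and subtracts the positional part
#' `row_slope * (row - mean(row)) + col_slope * (col - mean(col))` from all
#' wells of that plate replicate (controls included; the artifact is
#' positional, not biological). Centring the covariates keeps the intercept
#' and hence the plate median where it was: only the tilt is removed.
#'
#' @param dataset a `ScreenDataset`.
#' @param parameters readout names to correct; defaults to the full
#'   registry.
#' @return list with `dataset` (corrected copy) and `fits` (data frame of
#'   per-plate-replicate coefficients).
#' @export
correct_dataset <- function(dataset, parameters = NULL) {
  stopifnot(inherits(dataset, "ScreenDataset"))
  parameters <- parameters %||% dataset$parameter_names
  unknown <- setdiff(parameters, dataset$parameter_names)
  if (length(unknown) > 0) {
    stop("lookup error: unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  w <- dataset$wells
  rr <- well_row(w$well)
  cc <- well_col(w$well)
  key <- paste(w$plate_id, w$replicate, sep = "\r")
  groups <- split(seq_len(nrow(w)), key)
  fits <- vector("list", length(groups) * length(parameters))
  fi <- 0L
  for (g in groups) {
    for (p in parameters) {
      fit <- fit_plate_artifact(w[[p]][g], rr[g], cc[g])
      w[[p]][g] <- w[[p]][g] -
        fit$row_slope * (rr[g] - mean(rr[g])) -
        fit$col_slope * (cc[g] - mean(cc[g]))
      fi <- fi + 1L
      fits[[fi]] <- data.frame(
        plate_id = w$plate_id[g[1]], replicate = w$replicate[g[1]],
        parameter = p, intercept = fit$intercept, row_slope = fit$row_slope,
        col_slope = fit$col_slope, converged = fit$converged,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- dataset
  out$wells <- w
  list(dataset = out, fits = do.call(rbind, fits[seq_len(fi)]))
}
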