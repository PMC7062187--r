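#' The three readouts every workflow can reference by stable key
#' @keywords internal
LEAD_READOUTS <- c("pct_cells_gt3_puncta", "puncta_area_per_cell",
                   "puncta_intensity_per_cell")

#' Default parameter registry
#'
#' The per-well summary tables carry 84 named numeric readouts per well.
#' The registry always starts with the three canonical parkin-translocation
#' readouts (`pct_cells_gt3_puncta`, `puncta_area_per_cell`,
#' `puncta_intensity_per_cell`); the remainder are filled with generic
#' morphology-parameter names.
#'
#' @param n total number of parameters (default 84).
#' @return character vector of length `n`.
#' @export
default_parameters <- function(n = 84L) {
  stopifnot(n >= 3L)
  c(LEAD_READOUTS, sprintf("param_%03d", seq_len(n - 3L)))
}

#' Construct a screen dataset
#'
#' A `ScreenDataset` holds per-well summary readouts for a set of plates and
#' replicates sharing one [plate_layout()] and one parameter registry.
#' `wells` is a single wide data frame: one row per well of one plate
#' replicate, with identifier columns (`plate_id`, `replicate`, `well`,
#' `role`, `gene_id`, `sirna_id`) followed by one numeric column per
#' registered parameter.
#'
#' @param wells data frame as described above.
#' @param layout a `PlateLayout` or layout name.
#' @param parameter_names ordered parameter registry; defaults to the
#'   non-identifier columns of `wells`.
#' @param replicates_per_plate expected replicate count (3 for the primary
#'   screen, 6 for the secondary); informational.
#' @return a `ScreenDataset`.
#' @export
screen_dataset <- function(wells, layout = "primary", parameter_names = NULL,
                           replicates_per_plate = NULL) {
  if (is.character(layout)) layout <- plate_layout(layout)
  stopifnot(inherits(layout, "PlateLayout"))
  id_cols <- c("plate_id", "replicate", "well", "role", "gene_id", "sirna_id")
  missing_cols <- setdiff(id_cols, names(wells))
  if (length(missing_cols) > 0) {
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.null(parameter_names)) {
    parameter_names <- setdiff(names(wells), id_cols)
  }
  if (!all(LEAD_READOUTS %in% parameter_names)) {
    stop("parameter registry must include the three canonical readouts: ",
         paste(LEAD_READOUTS, collapse = ", "))
  }
  wells <- as.data.frame(wells, stringsAsFactors = FALSE)
  wells$replicate <- as.integer(wells$replicate)
  obj <- structure(
    list(
      layout = layout,
      parameter_names = parameter_names,
      wells = wells[, c(id_cols, parameter_names)],
      replicates_per_plate = replicates_per_plate %||%
        max(wells$replicate, 0L)
    ),
    class = "ScreenDataset"
  )
  validate_screen_dataset(obj)
  obj
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_screen_dataset <- function(x) {
  w <- x$wells
  lay <- x$layout
  # wells must exist in the layout
  bad <- setdiff(unique(w$well), lay$roles$well)
  if (length(bad) > 0) {
    stop("consistency error: well(s) not in layout: ", paste(bad, collapse = ", "))
  }
  # roles must agree with the layout
  expected <- lay$roles$role[match(w$well, lay$roles$well)]
  mism <- which(!is.na(w$role) & w$role != expected)
  if (length(mism) > 0) {
    stop("consistency error: role disagrees with layout '", lay$layout_name,
         "' at e.g. plate ", w$plate_id[mism[1]], " well ", w$well[mism[1]],
         " (file says ", w$role[mism[1]], ", layout says ", expected[mism[1]], ")")
  }
  # each layout well at most once per (plate, replicate)
  key <- paste(w$plate_id, w$replicate, w$well)
  if (anyDuplicated(key)) {
    stop("consistency error: duplicated well within a plate replicate: ",
         key[which(duplicated(key))[1]])
  }
  # controls carry no gene id; samples must carry one
  ctrl <- w$role %in% c("negative_control", "positive_control", "empty")
  if (any(!is.na(w$gene_id[ctrl]))) {
    stop("consistency error: control/empty wells must have gene_id NA")
  }
  if (any(is.na(w$gene_id[w$role == "sample"]))) {
    stop("consistency error: sample wells must have a gene_id")
  }
  for (p in x$parameter_names) {
    if (!is.numeric(w[[p]])) {
      stop("parse error: non-numeric readout column '", p, "'")
    }
  }
  invisible(x)
}

#' @export
print.ScreenDataset <- function(x, ...) {
  np <- length(unique(x$wells$plate_id))
  cat("ScreenDataset: ", np, " plate(s), layout '", x$layout$layout_name,
      "', ", length(x$parameter_names), " parameters, ",
      nrow(x$wells), " well records\n", sep = "")
  invisible(x)
}

#' Read a screen from a delimited table
#'
#' Expects a UTF-8 comma-separated file with a header row and columns
#' `plate_id`, `replicate`, `well`, `role`, `gene_id`, `sirna_id`, followed
#' by one numeric column per readout parameter. Missing readouts are
#' permitted as empty fields or `NA` and propagate through downstream
#' medians/MADs. The `role` column, when present, must agree with the named
#' layout.
#'
#' @param path file path of the CSV table.
#' @param layout_name name of the built-in layout ("primary"/"secondary") or
#'   a `PlateLayout`.
#' @param replicates_per_plate optional expected replicate count.
#' @return a `ScreenDataset`.
#' @seealso [write_screen()]
#' @export
read_screen <- function(path, layout_name = "primary", replicates_per_plate = NULL) {
  # base read.csv: its float parser reproduces written doubles bit-exactly
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  id_cols <- c("plate_id", "replicate", "well", "role", "gene_id", "sirna_id")
  missing_cols <- setdiff(id_cols, names(tab))
  if (length(missing_cols) > 0) {
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (cc in c("plate_id", "well", "role", "gene_id", "sirna_id")) {
    tab[[cc]] <- as.character(tab[[cc]])
  }
  param_cols <- setdiff(names(tab), id_cols)
  for (p in param_cols) {
    # empty or all-NA readout columns are guessed logical; they are numeric NA
    if (is.logical(tab[[p]]) && all(is.na(tab[[p]]))) {
      tab[[p]] <- as.numeric(tab[[p]])
    }
    if (!is.numeric(tab[[p]])) {
      bad_row <- which(!is.na(tab[[p]]) & is.na(suppressWarnings(as.numeric(tab[[p]]))))[1]
      stop("parse error: non-numeric readout in column '", p, "', row ",
           bad_row %||% NA)
    }
  }
  screen_dataset(tab, layout = layout_name, parameter_names = param_cols,
                 replicates_per_plate = replicates_per_plate)
}

#' Write a screen dataset to CSV
#'
#' Numeric values are written with enough digits to round-trip exactly, so
#' `read_screen(write_screen(d))` reproduces `d` field for field.
#'
#' @param dataset a `ScreenDataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_screen <- function(dataset, path) {
  stopifnot(inherits(dataset, "ScreenDataset"))
  readr::write_csv(dataset$wells, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Select the control wells of one plate replicate
#'
#' Returns the wells of the requested role on one plate replicate, in
#' row-major layout order (A1..A12, B1..). These are the operands of the
#' plate-wise QC score, which contrasts positive- against negative-control
#' medians.
#'
#' @param dataset a `ScreenDataset`.
#' @param plate_id,replicate plate replicate to select from.
#' @param role one of `"sample"`, `"negative_control"`, `"positive_control"`,
#'   `"empty"`.
#' @return data frame of matching well records (possibly zero rows).
#' @export
control_wells <- function(dataset, plate_id, replicate, role) {
  stopifnot(inherits(dataset, "ScreenDataset"))
  w <- dataset$wells
  sel <- w$plate_id == plate_id & w$replicate == replicate
  if (!any(sel)) {
    stop("lookup error: no such plate replicate: ", plate_id, " / ", replicate)
  }
  out <- w[sel & w$role == role, , drop = FALSE]
  ord <- match(out$well, dataset$layout$roles$well)
  out[order(ord), , drop = FALSE]
}

#' Enumerate plate replicates present in a dataset
#' @param dataset a `ScreenDataset`.
#' @return data frame with columns `plate_id`, `replicate`.
#' @export
plate_replicates <- function(dataset) {
  unique(dataset$wells[, c("plate_id", "replicate")])
}
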