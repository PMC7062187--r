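#' Built-in 96-well plate layouts
#'
#' A `PlateLayout` maps every well of an 8 x 12 plate to a role. Two layouts
#' are built in:
#' \describe{
#'   \item{`"primary"`}{non-targeting (negative) controls in the outer column
#'     wells A1, B1, C1, D1, E12, F12, G12, H12 and siPINK1 (positive)
#'     controls in A12, B12, C12, D12, E1, F1, G1, H1; all remaining wells
#'     are samples.}
#'   \item{`"secondary"`}{controls scattered across the plate to better
#'     average out row/column effects: negative controls in A2, A12, C5, C8,
#'     D10, E3, F5, F8, H2, H12 and positive controls in A1, A11, C4, C9,
#'     F4, F9, H1, H11.}
#' }
#'
#' @param name `"primary"` or `"secondary"`, or a custom role map (a named
#'   character vector well -> role) to build an ad hoc layout.
#' @param layout_name label used when `name` is a custom role map.
#' @return A `PlateLayout` object: a list with `n_rows`, `n_cols`,
#'   `layout_name` and a data frame `roles` with columns `well`, `row`,
#'   `col`, `role`.
#' @examples
#' lay <- plate_layout("primary")
#' table(lay$roles$role)
#' @export
plate_layout <- function(name = "primary", layout_name = NULL) {
  n_rows <- 8L
  n_cols <- 12L
  wells <- all_wells(n_rows, n_cols)
  if (is.character(name) && length(name) == 1L && name %in% c("primary", "secondary")) {
    neg <- switch(name,
      primary   = c("A1", "B1", "C1", "D1", "E12", "F12", "G12", "H12"),
      secondary = c("A2", "A12", "C5", "C8", "D10", "E3", "F5", "F8", "H2", "H12")
    )
    pos <- switch(name,
      primary   = c("A12", "B12", "C12", "D12", "E1", "F1", "G1", "H1"),
      secondary = c("A1", "A11", "C4", "C9", "F4", "F9", "H1", "H11")
    )
    role <- rep("sample", length(wells))
    role[match(neg, wells)] <- "negative_control"
    role[match(pos, wells)] <- "positive_control"
    layout_name <- name
  } else {
    # custom role map: named character vector well -> role
    stopifnot(is.character(name), !is.null(names(name)))
    bad <- setdiff(names(name), wells)
    if (length(bad) > 0) {
      stop("unknown well coordinates in role map: ", paste(bad, collapse = ", "))
    }
    role <- rep("sample", length(wells))
    role[match(names(name), wells)] <- unname(name)
    if (!all(role %in% c("sample", "negative_control", "positive_control", "empty"))) {
      stop("roles must be sample/negative_control/positive_control/empty")
    }
    if (is.null(layout_name)) layout_name <- "custom"
  }
  roles <- data.frame(
    well = wells,
    row = well_row(wells),
    col = well_col(wells),
    role = role,
    stringsAsFactors = FALSE
  )
  structure(
    list(n_rows = n_rows, n_cols = n_cols, layout_name = layout_name, roles = roles),
    class = "PlateLayout"
  )
}

#' @export
print.PlateLayout <- function(x, ...) {
  cat("PlateLayout '", x$layout_name, "': ", x$n_rows, " x ", x$n_cols, " wells\n", sep = "")
  print(table(x$roles$role))
  invisible(x)
}

# All well coordinates in row-major order: A1..A12, B1..B12, ...
all_wells <- function(n_rows = 8L, n_cols = 12L) {
  as.vector(t(outer(LETTERS[seq_len(n_rows)], seq_len(n_cols), paste0)))
}

#' Well coordinate helpers
#'
#' Convert between letter+number well coordinates ("A1".."H12") and numeric
#' row/column indices (A -> 1 .. H -> 8; columns 1-based). The artifact
#' correction model regresses on these numeric row and column indices.
#'
#' @param well character vector of well coordinates.
#' @return integer vector of row or column numbers.
#' @export
well_row <- function(well) {
  r <- match(substr(well, 1L, 1L), LETTERS)
  if (anyNA(r)) stop("malformed well coordinate(s): ", paste(well[is.na(r)], collapse = ", "))
  as.integer(r)
}

#' @rdname well_row
#' @export
well_col <- function(well) {
  cc <- suppressWarnings(as.integer(substr(well, 2L, nchar(well))))
  if (anyNA(cc)) stop("malformed well coordinate(s): ", paste(well[is.na(cc)], collapse = ", "))
  cc
}
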