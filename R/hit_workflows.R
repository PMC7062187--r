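# Per-well-unit SSMD table shared by the workflows.
#
# A "gene unit" is one sample well position of one plate (one smart pool in
# the primary screen, one siRNA in the secondary): its readout is replicated
# across the plate replicates, and each unit is contrasted against the
# negative controls of the same plates via ssmd_gene() with the pooled s0^2.
gene_ssmd_table <- function(dataset, parameters) {
  w <- dataset$wells
  samp <- w[w$role == "sample", , drop = FALSE]
  neg <- w[w$role == "negative_control", , drop = FALSE]
  units <- unique(samp[, c("plate_id", "well", "gene_id", "sirna_id")])
  out <- units
  s0 <- vapply(parameters, function(p) pooled_s0_squared(dataset, p), numeric(1))
  ukey <- factor(paste(samp$plate_id, samp$well, sep = "\r"),
                 levels = paste(units$plate_id, units$well, sep = "\r"))
  nkey <- factor(neg$plate_id)
  for (p in parameters) {
    out[[paste0("ssmd.", p)]] <- vec_ssmd_gene(
      split(samp[[p]], ukey), split(neg[[p]], nkey),
      units$plate_id, s0[[p]]
    )
  }
  rownames(out) <- NULL
  out
}

# vectorized per-unit evaluation of ssmd_gene(); same formula and the same
# 0/0 -> 0 convention, NA where a unit has < 2 finite replicates
vec_ssmd_gene <- function(well_split, neg_split, unit_plate, s0_squared) {
  med <- vapply(well_split, function(x) stats::median(x, na.rm = TRUE), numeric(1))
  v <- vapply(well_split, function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 2L) NA_real_ else stats::var(x)
  }, numeric(1))
  neg_med <- vapply(neg_split, function(x) stats::median(x, na.rm = TRUE), numeric(1))
  num <- med - neg_med[match(unit_plate, names(neg_split))]
  den <- sqrt(0.5 * v + 0.5 * s0_squared)
  ifelse(is.na(v), NA_real_,
         ifelse(den == 0, ifelse(num == 0, 0, sign(num) * Inf), num / den))
}

#' Univariate hit selection on named readouts
#'
#' For each of the given readouts (by default the three canonical parkin
#' translocation indicators), computes the per-gene SSMD ([ssmd_gene()],
#' with the pooled \eqn{s_0^2} of that readout) and flags hits beyond the
#' strict +/- `threshold` (default 3).
#'
#' @param dataset an artifact-corrected, QC-filtered `ScreenDataset`.
#' @param parameters readout names (default the three lead readouts).
#' @param threshold hit threshold on |SSMD| (strict inequality).
#' @return a `GeneScoreTable` data frame: one row per sample well unit with
#'   `ssmd.<param>` and `hit.<param>` columns (`"positive_hit"`,
#'   `"negative_hit"` or `"none"`).
#' @export
univariate_hits <- function(dataset, parameters = LEAD_READOUTS, threshold = 3) {
  stopifnot(inherits(dataset, "ScreenDataset"))
  missing_p <- setdiff(parameters, dataset$parameter_names)
  if (length(missing_p) > 0) {
    stop("lookup error: unknown parameter(s): ", paste(missing_p, collapse = ", "))
  }
  tab <- gene_ssmd_table(dataset, parameters)
  for (p in parameters) {
    tab[[paste0("hit.", p)]] <- hit_flag(tab[[paste0("ssmd.", p)]], threshold)
  }
  tab
}

hit_flag <- function(score, threshold) {
  ifelse(score > threshold, "positive_hit",
         ifelse(score < -threshold, "negative_hit", "none"))
}

#' Rank candidate readouts by control separation
#'
#' Ranks candidate parameters by the pooled absolute plate QC SSMD (mean of
#' |SSMD_QC| over plate replicates) and returns the top `n_select`; these
#' are the candidates whose positive- and negative-control distributions
#' differ most. A manual `override` list is returned verbatim.
#'
#' @param dataset a `ScreenDataset` with both control roles.
#' @param candidates candidate parameter names (default: the three lead
#'   readouts plus three generic parameters, mirroring a six-candidate
#'   shortlist).
#' @param n_select how many to keep (default 3).
#' @param override optional manual selection, returned as-is.
#' @return character vector of selected parameter names.
#' @export
select_parameters <- function(dataset,
                              candidates = c(LEAD_READOUTS,
                                             c("param_001", "param_002", "param_003")),
                              n_select = 3L, override = NULL) {
  if (!is.null(override)) return(override)
  stopifnot(inherits(dataset, "ScreenDataset"))
  candidates <- intersect(candidates, dataset$parameter_names)
  if (length(candidates) < n_select) {
    stop("selection error: fewer than ", n_select, " usable candidates")
  }
  pr <- plate_replicates(dataset)
  sep <- vapply(candidates, function(p) {
    ss <- vapply(seq_len(nrow(pr)), function(i) {
      pos <- control_wells(dataset, pr$plate_id[i], pr$replicate[i], "positive_control")[[p]]
      neg <- control_wells(dataset, pr$plate_id[i], pr$replicate[i], "negative_control")[[p]]
      tryCatch(abs(ssmd_qc(pos, neg)$value), error = function(e) NA_real_)
    }, numeric(1))
    mean(ss, na.rm = TRUE)
  }, numeric(1))
  candidates[order(sep, decreasing = TRUE)][seq_len(n_select)]
}

#' One-component PCA consensus score
#'
#' Combines the per-gene SSMD values of several readouts into one consensus
#' SSMD per gene by a one-component singular value decomposition
#' `X = H W' + E`: `W` is the first right singular vector (unit loading)
#' and the score vector `H` is the first left singular vector scaled by the
#' first singular value. The matrix is neither centred nor column-scaled:
#' SSMDs already share a dimensionless scale, and an all-zero row must map
#' to score 0 so the +/- threshold semantics carry over.
#'
#' The SVD sign ambiguity is fixed by requiring a positive loading on
#' `sign_anchor` (default the lead readout), so suppressed recruitment
#' always yields a negative score.
#'
#' @param ssmd_matrix numeric genes x parameters matrix, no missing values
#'   (rows with missing entries must be dropped by the caller).
#' @param sign_anchor column name (or index) anchoring the loading sign.
#' @return list with `scores` (numeric, one per row) and `model` (a
#'   `PCAModel`: `loadings`, `singular_values`, `explained_variance`,
#'   `sign_anchor`).
#' @export
pca_score <- function(ssmd_matrix, sign_anchor = "pct_cells_gt3_puncta") {
  X <- as.matrix(ssmd_matrix)
  stopifnot(nrow(X) >= 2L)
  if (anyNA(X)) stop("ssmd_matrix must not contain missing values")
  if (all(X == 0)) stop("degenerate-decomposition error: all-zero SSMD matrix")
  sv <- svd(X)
  w <- sv$v[, 1]
  h <- sv$u[, 1] * sv$d[1]
  anchor_idx <- if (is.character(sign_anchor)) {
    ai <- match(sign_anchor, colnames(X))
    if (is.na(ai)) 1L else ai
  } else as.integer(sign_anchor)
  s <- if (w[anchor_idx] != 0) sign(w[anchor_idx]) else 1
  w <- s * w; h <- s * h
  model <- structure(
    list(loadings = stats::setNames(w, colnames(X)),
         singular_values = sv$d,
         explained_variance = sv$d[1]^2 / sum(sv$d^2),
         sign_anchor = sign_anchor),
    class = "PCAModel"
  )
  list(scores = h, model = model)
}

#' Threshold PCA (or any consensus) scores into hit flags
#'
#' `positive_hit` if score > threshold, `negative_hit` if score <
#' -threshold, otherwise `none`; strictly, so a score exactly at the
#' threshold is not a hit. The conventional thresholds are 3 for a pooled
#' primary screen and 1.3 for a single-siRNA secondary screen.
#'
#' @param scores numeric vector of finite scores.
#' @param threshold positive threshold.
#' @return character vector of flags.
#' @export
pca_hits <- function(scores, threshold = 3) {
  stopifnot(all(is.finite(scores)))
  hit_flag(scores, threshold)
}

#' PCA workflow: consensus score and hits for a screen
#'
#' Convenience wrapper: computes per-gene SSMDs for the three selected
#' readouts, drops units with missing SSMDs (reported), runs [pca_score()]
#' and flags hits with [pca_hits()].
#'
#' @param dataset artifact-corrected, QC-filtered `ScreenDataset`.
#' @param parameters three readouts (default [select_parameters()] output).
#' @param threshold hit threshold (3 primary, 1.3 secondary).
#' @param sign_anchor see [pca_score()].
#' @return `GeneScoreTable` data frame with `ssmd.<param>`, `pca_score` and
#'   `pca_hit` columns; attribute `"pca_model"` carries the `PCAModel`.
#' @export
pca_workflow <- function(dataset, parameters = NULL, threshold = 3,
                         sign_anchor = "pct_cells_gt3_puncta") {
  parameters <- parameters %||% select_parameters(dataset)
  tab <- gene_ssmd_table(dataset, parameters)
  scol <- paste0("ssmd.", parameters)
  ok <- stats::complete.cases(tab[, scol, drop = FALSE])
  if (any(!ok)) {
    message(sum(!ok), " unit(s) dropped for missing SSMDs")
  }
  tab <- tab[ok, , drop = FALSE]
  X <- as.matrix(tab[, scol, drop = FALSE])
  colnames(X) <- parameters
  ps <- pca_score(X, sign_anchor = sign_anchor)
  tab$pca_score <- ps$scores
  tab$pca_hit <- pca_hits(ps$scores, threshold)
  attr(tab, "pca_model") <- ps$model
  tab
}
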