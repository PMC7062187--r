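#' Control-supervised feature selection
#'
#' Welch two-sample t test per parameter between the positive- and
#' negative-control wells, Benjamini-Hochberg adjustment across parameters,
#' and selection at an FDR cut-off (default 0.05). A parameter constant in
#' both classes gets p = 1 and is never selected.
#'
#' @param controls numeric wells x parameters matrix of control readouts.
#' @param labels factor/vector with two classes, one per row of `controls`.
#' @param fdr FDR cut-off.
#' @return a `FeatureSelection` data frame: `parameter`, `t`, `p`, `p_adj`,
#'   `selected`.
#' @export
select_features <- function(controls, labels, fdr = 0.05) {
  X <- as.matrix(controls)
  labels <- as.factor(labels)
  stopifnot(nlevels(labels) == 2L, nrow(X) == length(labels))
  if (min(table(labels)) < 2L) stop("need >= 2 wells per control class")
  g1 <- labels == levels(labels)[1]
  res <- apply(X, 2, function(v) {
    a <- v[g1]; b <- v[!g1]
    if (stats::sd(a, na.rm = TRUE) == 0 && stats::sd(b, na.rm = TRUE) == 0) {
      return(c(t = 0, p = 1))
    }
    tt <- stats::t.test(a, b, var.equal = FALSE)
    c(t = unname(tt$statistic), p = tt$p.value)
  })
  p_adj <- stats::p.adjust(res["p", ], method = "BH")
  data.frame(
    parameter = colnames(X) %||% paste0("V", seq_len(ncol(X))),
    t = res["t", ], p = res["p", ], p_adj = p_adj,
    selected = p_adj <= fdr & fdr > 0,
    row.names = NULL
  )
}

#' Hotelling's T2 outlier screen for control wells
#'
#' With more parameters than control wells the raw covariance is singular,
#' so the T2 statistic is computed in the principal-component subspace
#' capturing at least `var_explained` of the control variance (capped at
#' n - 2 components). The exclusion limit is the classical
#' `k (n - 1) / (n - k)` multiple of the F quantile at the given
#' confidence.
#'
#' @param controls numeric wells x parameters matrix.
#' @param confidence exclusion confidence (default 0.99).
#' @param var_explained minimum variance fraction of the PCA subspace.
#' @return an `OutlierReport` data frame: `t2`, `limit`, `excluded`, plus
#'   attributes `k` (subspace dimension) and `limit`.
#' @export
remove_outlier_controls <- function(controls, confidence = 0.99,
                                    var_explained = 0.90) {
  X <- as.matrix(controls)
  n <- nrow(X)
  if (n < 4L) stop("outlier-detection error: need >= 4 control wells")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  pos <- ev > max(ev) * 1e-10
  if (!any(pos)) stop("outlier-detection error: zero-variance controls")
  k <- which(cumsum(ev) / sum(ev) >= var_explained)[1]
  k <- min(k, n - 2L, sum(pos))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  t2 <- rowSums(sweep(scores^2, 2, ev[seq_len(k)], "/"))
  limit <- k * (n - 1) / (n - k) * stats::qf(confidence, k, n - k)
  out <- data.frame(t2 = t2, limit = limit, excluded = t2 > limit)
  attr(out, "k") <- k
  attr(out, "limit") <- limit
  out
}

# --- PLS1 (NIPALS) -------------------------------------------------------

# One-response PLS via NIPALS on centred data; returns weights W, X-loadings
# P, X-scores T, y-loadings q, plus centring info.
nipals_pls1 <- function(X, y, n_components) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  x_center <- attr(Xc, "scaled:center")
  y_center <- mean(y)
  yc <- y - y_center
  n <- nrow(Xc); p <- ncol(Xc)
  A <- min(n_components, p, n - 1L)
  W <- matrix(0, p, A); P <- matrix(0, p, A)
  Tm <- matrix(0, n, A); q <- numeric(A)
  Xd <- Xc; yd <- yc
  for (a in seq_len(A)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { A <- a - 1L; break }
    w <- w / nw
    t_ <- Xd %*% w
    tt <- sum(t_^2)
    if (tt < 1e-12) { A <- a - 1L; break }
    p_ <- crossprod(Xd, t_) / tt
    q_ <- sum(yd * t_) / tt
    Xd <- Xd - t_ %*% t(p_)
    yd <- yd - q_ * t_
    W[, a] <- w; P[, a] <- p_; Tm[, a] <- t_; q[a] <- q_
  }
  if (A < 1L) stop("PLS fit failed: no usable component")
  list(W = W[, seq_len(A), drop = FALSE], P = P[, seq_len(A), drop = FALSE],
       T = Tm[, seq_len(A), drop = FALSE], q = q[seq_len(A)],
       x_center = x_center, y_center = y_center, n_components = A)
}

pls1_scores <- function(fit, X, n_components = fit$n_components) {
  Xd <- sweep(as.matrix(X), 2, fit$x_center, "-")
  A <- min(n_components, fit$n_components)
  Tm <- matrix(0, nrow(Xd), A)
  for (a in seq_len(A)) {
    t_ <- Xd %*% fit$W[, a]
    Tm[, a] <- t_
    Xd <- Xd - t_ %*% t(fit$P[, a])
  }
  Tm
}

pls1_predict <- function(fit, X, n_components = fit$n_components) {
  Tm <- pls1_scores(fit, X, n_components)
  A <- ncol(Tm)
  drop(fit$y_center + Tm %*% fit$q[seq_len(A)])
}

# stratified fold assignment, deterministic given the seed
stratified_folds <- function(labels, folds, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (lv in unique(labels)) {
      idx <- which(labels == lv)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    fold
  })
}

#' Fit a cross-validated control PLS model
#'
#' Fits a one-response PLS (NIPALS) model of the control labels (coded
#' negative_control = -1, positive_control = +1) on the selected control
#' readouts. The number of components is chosen to minimize the stratified
#' `folds`-fold cross-validated squared prediction error of the label; the
#' fold split is deterministic given `fold_seed`, so the whole fit is
#' reproducible.
#'
#' The reported well score is the component-1 X-score. After fitting, the
#' score is oriented to recruitment polarity: negative controls (intact
#' recruitment) score higher than positive controls, so downstream QC and
#' SSMD stages can treat the score exactly like a recruitment readout.
#'
#' @param controls numeric wells x selected-parameters matrix.
#' @param labels two-class control labels (one per row).
#' @param max_components largest component count tried.
#' @param folds cross-validation folds (stratified).
#' @param fold_seed RNG seed for the fold split.
#' @return a `PLSModel`: NIPALS matrices (`W`, `P`, `T`, `q`), centring,
#'   `n_components`, `cv_error` (per component count), `cv_misassignment`,
#'   `selected_parameters`, `label_levels`, `score_sign`.
#' @export
fit_pls <- function(controls, labels, max_components = 10L, folds = 10L,
                    fold_seed = 1L) {
  X <- as.matrix(controls)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("label error: exactly two control classes required")
  lev <- levels(labels)
  # code so that the second level (positive control when levels are the
  # role names in alphabetical order: negative_control < positive_control)
  # sits at +1
  y <- ifelse(labels == lev[1], -1, +1)
  if (nrow(X) < folds) stop("fewer control wells than folds")
  fold <- stratified_folds(labels, folds, fold_seed)
  A_max <- min(max_components, ncol(X), nrow(X) - ceiling(nrow(X) / folds) - 1L)
  A_max <- max(A_max, 1L)
  cv_err <- rep(NA_real_, A_max)
  pred <- matrix(NA_real_, nrow(X), A_max)
  for (f in seq_len(folds)) {
    tr <- fold != f
    if (length(unique(labels[tr])) < 2L) next
    fit_f <- nipals_pls1(X[tr, , drop = FALSE], y[tr], A_max)
    for (a in seq_len(fit_f$n_components)) {
      pred[!tr, a] <- pls1_predict(fit_f, X[!tr, , drop = FALSE], a)
    }
    # folds the smaller model couldn't reach keep NA and are skipped below
  }
  for (a in seq_len(A_max)) {
    cv_err[a] <- mean((pred[, a] - y)^2, na.rm = TRUE)
  }
  best_a <- which.min(cv_err)
  fit <- nipals_pls1(X, y, best_a)
  # orient component 1 to recruitment polarity (negative controls high)
  t1 <- fit$T[, 1]
  s <- sign(stats::median(t1[y < 0]) - stats::median(t1[y > 0]))
  if (is.na(s) || s == 0) s <- 1
  misassign <- mean(sign(pred[, best_a]) != sign(y), na.rm = TRUE)
  structure(
    list(W = fit$W, P = fit$P, T = fit$T, q = fit$q,
         x_center = fit$x_center, y_center = fit$y_center,
         n_components = fit$n_components,
         cv_error = cv_err, cv_misassignment = misassign,
         selected_parameters = colnames(X),
         label_levels = lev, score_sign = s),
    class = "PLSModel"
  )
}

#' @export
print.PLSModel <- function(x, ...) {
  cat("PLSModel: ", x$n_components, " component(s), ",
      length(x$selected_parameters), " parameters, CV error ",
      format(min(x$cv_error, na.rm = TRUE), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Predict per-well PLS scores
#'
#' Projects wells onto the fitted model and returns the oriented
#' component-1 score (the scalar consumed by the QC stage and by the
#' per-gene SSMD as the well readout).
#'
#' @param model a `PLSModel`.
#' @param wells numeric matrix (or data frame) supplying all of
#'   `model$selected_parameters` as columns.
#' @return numeric score per row of `wells`.
#' @export
predict_scores <- function(model, wells) {
  stopifnot(inherits(model, "PLSModel"))
  if (is.data.frame(wells)) {
    missing_p <- setdiff(model$selected_parameters, names(wells))
    if (length(missing_p) > 0) {
      stop("projection error: missing selected parameter(s): ",
           paste(missing_p, collapse = ", "))
    }
    wells <- as.matrix(wells[, model$selected_parameters, drop = FALSE])
  }
  model$score_sign * pls1_scores(model, wells)[, 1]
}

# assemble the control matrix of a dataset (rows = control wells)
control_matrix <- function(dataset, parameters = dataset$parameter_names) {
  w <- dataset$wells
  ctrl <- w$role %in% c("negative_control", "positive_control")
  list(X = as.matrix(w[ctrl, parameters, drop = FALSE]),
       labels = w$role[ctrl],
       meta = w[ctrl, c("plate_id", "replicate", "well"), drop = FALSE])
}

#' The parameter-agnostic PLS hit-selection workflow
#'
#' End-to-end pipeline on an artifact-corrected screen:
#' \enumerate{
#'   \item [select_features()] on the control wells (FDR `fdr`);
#'   \item [remove_outlier_controls()] (Hotelling's T2) on the selected
#'     features;
#'   \item [fit_pls()] on the retained controls, cross-validated;
#'   \item [predict_scores()] for every well;
#'   \item [qc_screen()] on the per-well scores (cut-off `qc_cutoff`);
#'   \item refit (outlier removal + PLS, same features) on the plates that
#'     passed;
#'   \item [ssmd_gene()] per gene unit on the final scores, with the pooled
#'     \eqn{s_0^2} of the scores, flagged at +/- `threshold`.
#' }
#'
#' @param dataset artifact-corrected `ScreenDataset`.
#' @param threshold hit threshold on the final SSMD (3 primary, 1.3
#'   secondary).
#' @param fdr feature-selection FDR cut-off.
#' @param qc_cutoff plate QC cut-off on score SSMD_QC.
#' @param confidence Hotelling exclusion confidence.
#' @param max_components,folds,fold_seed see [fit_pls()].
#' @return `GeneScoreTable` data frame (`plate_id`, `well`, `gene_id`,
#'   `sirna_id`, `pls_score` (median across replicates), `ssmd`,
#'   `pls_hit`); attributes `features`, `outliers`, `qc_report`, `model`
#'   (final `PLSModel`), `log` (counts in/out at every filter).
#' @export
pls_pipeline <- function(dataset, threshold = 3, fdr = 0.05, qc_cutoff = -2,
                         confidence = 0.99, max_components = 10L, folds = 10L,
                         fold_seed = 1L) {
  stopifnot(inherits(dataset, "ScreenDataset"))
  log <- list()
  cm <- control_matrix(dataset)
  fs <- select_features(cm$X, cm$labels, fdr = fdr)
  sel <- fs$parameter[fs$selected]
  if (length(sel) < 2L) stop("feature selection kept fewer than 2 parameters")
  log$features_selected <- length(sel)

  Xs <- cm$X[, sel, drop = FALSE]
  outl <- remove_outlier_controls(Xs, confidence = confidence)
  keep <- !outl$excluded
  log$outlier_controls_removed <- sum(!keep)
  model1 <- fit_pls(Xs[keep, , drop = FALSE], cm$labels[keep],
                    max_components = max_components, folds = folds,
                    fold_seed = fold_seed)

  w <- dataset$wells
  score_all <- predict_scores(model1, w[, sel, drop = FALSE])
  score_tab <- data.frame(plate_id = w$plate_id, replicate = w$replicate,
                          well = w$well, score = score_all,
                          stringsAsFactors = FALSE)
  qc <- qc_screen(dataset, readout = score_tab, cutoff = qc_cutoff)
  log$plate_replicates_failed_qc <- sum(!qc$report$pass)
  surv <- qc$dataset

  cm2 <- control_matrix(surv, parameters = sel)
  outl2 <- remove_outlier_controls(cm2$X, confidence = confidence)
  keep2 <- !outl2$excluded
  log$outlier_controls_removed_refit <- sum(!keep2)
  model2 <- fit_pls(cm2$X[keep2, , drop = FALSE], cm2$labels[keep2],
                    max_components = max_components, folds = folds,
                    fold_seed = fold_seed)

  w2 <- surv$wells
  final_score <- predict_scores(model2, w2[, sel, drop = FALSE])

  # per-gene SSMD on the final scores
  samp <- w2$role == "sample"
  neg <- w2$role == "negative_control"
  units <- unique(w2[samp, c("plate_id", "well", "gene_id", "sirna_id")])
  # pooled s0^2 of the score across all wells with >= 2 replicates
  key <- paste(w2$plate_id, w2$well)
  s2 <- tapply(final_score, key, function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 2L) NA_real_ else stats::var(x)
  })
  s0 <- stats::median(s2, na.rm = TRUE)
  ukey <- factor(paste(w2$plate_id[samp], w2$well[samp], sep = "\r"),
                 levels = paste(units$plate_id, units$well, sep = "\r"))
  well_split <- split(final_score[samp], ukey)
  neg_split <- split(final_score[neg], factor(w2$plate_id[neg]))
  ssmd <- vec_ssmd_gene(well_split, neg_split, units$plate_id, s0)
  med_score <- vapply(well_split, function(x) stats::median(x, na.rm = TRUE),
                      numeric(1))
  out <- units
  out$pls_score <- med_score
  out$ssmd <- ssmd
  out$pls_hit <- hit_flag(ssmd, threshold)
  rownames(out) <- NULL
  attr(out, "features") <- fs
  attr(out, "outliers") <- list(first = outl, refit = outl2)
  attr(out, "qc_report") <- qc$report
  attr(out, "model") <- model2
  attr(out, "log") <- log
  out
}
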