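make_controls <- function(n_per = 40, p = 84, n_shift = 65, delta = 3, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per * p), 2 * n_per, p)
  colnames(X) <- default_parameters(p)
  labels <- rep(c("negative_control", "positive_control"), each = n_per)
  X[labels == "positive_control", seq_len(n_shift)] <-
    X[labels == "positive_control", seq_len(n_shift)] - delta
  list(X = X, labels = labels)
}

test_that("select_features finds shifted parameters and spares null ones", {
  cm <- make_controls(n_per = 40, n_shift = 65, delta = 3, seed = 71)
  fs <- select_features(cm$X, cm$labels, fdr = 0.05)
  shifted <- fs$parameter[1:65]
  expect_gte(sum(fs$selected[fs$parameter %in% shifted]), 60)
  expect_lte(sum(fs$selected[!fs$parameter %in% shifted]), 2)
  # a constant parameter is never selected
  X2 <- cm$X; X2[, 84] <- 5
  fs2 <- select_features(X2, cm$labels)
  expect_false(fs2$selected[84])
  expect_equal(fs2$p[84], 1)
  # fdr = 0 selects nothing
  expect_false(any(select_features(cm$X, cm$labels, fdr = 0)$selected))
})

test_that("Hotelling T2 is calibrated under the null and catches planted outliers", {
  set.seed(72)
  X <- matrix(rnorm(80 * 10), 80, 10)
  rep_flagged <- replicate(20, {
    Xi <- matrix(rnorm(80 * 10), 80, 10)
    mean(remove_outlier_controls(Xi, confidence = 0.99)$excluded)
  })
  expect_lt(mean(rep_flagged), 0.05)        # ~1 % expected at 99 %
  # planted gross outlier
  X[1, 3] <- X[1, 3] + 10
  rep <- remove_outlier_controls(X, confidence = 0.99)
  expect_true(rep$excluded[1])
  # degenerate shapes reduce the subspace instead of crashing
  Xs <- matrix(rnorm(5 * 84), 5, 84)
  rep2 <- remove_outlier_controls(Xs)
  expect_lte(attr(rep2, "k"), 3)
  expect_error(remove_outlier_controls(matrix(rnorm(6), 3, 2)), "outlier-detection")
})

test_that("fit_pls separates separable control clouds perfectly", {
  set.seed(73)
  n <- 40
  X <- rbind(matrix(rnorm(n * 10, 0), n, 10), matrix(rnorm(n * 10, 6), n, 10))
  colnames(X) <- paste0("p", 1:10)
  labels <- rep(c("negative_control", "positive_control"), each = n)
  m <- fit_pls(X, labels, fold_seed = 5)
  expect_equal(m$cv_misassignment, 0)
  sc <- predict_scores(m, X)
  # recruitment polarity: negative controls score high
  expect_true(all(sc[1:n] > max(sc[(n + 1):(2 * n)])))
})

test_that("one-component PLS weights match the svd(X'y) oracle", {
  set.seed(74)
  for (i in 1:10) {
    n <- 30; p <- 8
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    fit <- mitoscreen:::nipals_pls1(X, y, 1)
    Xc <- scale(X, center = TRUE, scale = FALSE)
    yc <- y - mean(y)
    w_or <- svd(crossprod(Xc, matrix(yc)))$u[, 1]
    cosine <- abs(sum(fit$W[, 1] * w_or))
    expect_gte(cosine, 0.999)
  }
})

test_that("PLS component scores are mutually orthogonal", {
  set.seed(75)
  X <- matrix(rnorm(60 * 12), 60, 12)
  y <- rnorm(60)
  fit <- mitoscreen:::nipals_pls1(X, y, 4)
  G <- crossprod(fit$T)
  off <- G - diag(diag(G))
  expect_lt(max(abs(off)) / max(diag(G)), 1e-8)
})

test_that("label permutation yields chance-level cross-validation", {
  set.seed(76)
  n <- 40
  X <- rbind(matrix(rnorm(n * 10, 0), n, 10), matrix(rnorm(n * 10, 4), n, 10))
  labels <- sample(rep(c("negative_control", "positive_control"), each = n))
  m <- fit_pls(X, labels, fold_seed = 7)
  expect_gt(min(m$cv_error, na.rm = TRUE), 0.5)
  expect_gt(m$cv_misassignment, 0.25)
})

test_that("predicted scores are invariant to a common affine shift", {
  set.seed(77)
  n <- 30
  X <- rbind(matrix(rnorm(n * 6, 0), n, 6), matrix(rnorm(n * 6, 3), n, 6))
  labels <- rep(c("negative_control", "positive_control"), each = n)
  Xnew <- matrix(rnorm(10 * 6, 1.5), 10, 6)
  m1 <- fit_pls(X, labels, fold_seed = 2)
  shift <- matrix(rep(runif(6, -5, 5), each = nrow(X)), nrow(X))
  m2 <- fit_pls(X + shift, labels, fold_seed = 2)
  s1 <- predict_scores(m1, Xnew)
  s2 <- predict_scores(m2, Xnew + matrix(rep(shift[1, ], each = 10), 10))
  expect_equal(diff(s1), diff(s2), tolerance = 1e-8)
  # a well at the negative-control centroid scores inside the negative cloud
  cen <- matrix(colMeans(X[labels == "negative_control", ]), 1)
  s_cen <- predict_scores(m1, cen)
  neg_scores <- predict_scores(m1, X[labels == "negative_control", ])
  expect_gte(s_cen, min(neg_scores))
  expect_lte(s_cen, max(neg_scores))
})

test_that("fit_pls is deterministic given the fold seed", {
  cm <- make_controls(n_per = 20, n_shift = 10, delta = 2, seed = 78)
  m1 <- fit_pls(cm$X[, 1:20], cm$labels, fold_seed = 3)
  m2 <- fit_pls(cm$X[, 1:20], cm$labels, fold_seed = 3)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$cv_error, m2$cv_error)
  expect_error(fit_pls(cm$X[1:20, 1:5], rep("negative_control", 20)), "label error")
})

test_that("pls_pipeline recovers planted modulators end to end", {
  sim <- simulate_screen(screen_sim_config(
    n_plates = 2, replicates = 3, effect_size_sd_units = 4,
    planted_positive_modulators = c("g0010", "g0011"),
    planted_negative_modulators = c("g0030"), seed = 79))
  corr <- correct_dataset(sim$dataset)
  tab <- pls_pipeline(corr$dataset, fold_seed = 79)
  expect_equal(tab$pls_hit[tab$gene_id == "g0010"], "negative_hit")
  expect_equal(tab$pls_hit[tab$gene_id == "g0030"], "positive_hit")
  # planted genes rank above the null 95th percentile
  null_abs <- abs(tab$ssmd[!tab$gene_id %in% c("g0010", "g0011", "g0030")])
  expect_gt(abs(tab$ssmd[tab$gene_id == "g0010"]), quantile(null_abs, 0.95))
  log <- attr(tab, "log")
  expect_true(all(c("features_selected", "outlier_controls_removed",
                    "plate_replicates_failed_qc") %in% names(log)))
  expect_gte(log$features_selected, 55)
})

test_that("effects confined to unselected parameters are invisible to PLS", {
  sim <- simulate_screen(screen_sim_config(n_plates = 2, replicates = 3, seed = 80))
  d <- sim$dataset
  # plant an effect only on uninformative parameters (never control-separating)
  uninf <- names(sim$truth$informative)[!sim$truth$informative][1:5]
  tgt <- !is.na(d$wells$gene_id) & d$wells$gene_id == "g0050"
  for (p in uninf) d$wells[[p]][tgt] <- d$wells[[p]][tgt] + 6
  tab <- pls_pipeline(correct_dataset(d)$dataset, fold_seed = 80)
  expect_equal(tab$pls_hit[tab$gene_id == "g0050"], "none")
})
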