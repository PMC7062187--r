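test_that("univariate SSMDs are zero (and unflagged) for null genes", {
  # every sample well sits exactly on the negative-control median
  d <- manual_screen(function(role, row, col, rep_) {
    if (role == "negative_control") c(9, 10, 11)[rep_]
    else if (role == "positive_control") c(3, 4, 5)[rep_]
    else c(9.5, 10, 10.5)[rep_]
  })
  tab <- univariate_hits(d, parameters = "pct_cells_gt3_puncta")
  expect_true(all(tab$ssmd.pct_cells_gt3_puncta == 0))
  expect_true(all(tab$hit.pct_cells_gt3_puncta == "none"))
  expect_error(univariate_hits(d, parameters = "nope"), "lookup error")
})

test_that("planted modulators cross the +-3 univariate threshold with the right sign", {
  sim <- simulate_screen(screen_sim_config(
    n_plates = 2, replicates = 3, effect_size_sd_units = 6,
    planted_positive_modulators = c("g0010"),
    planted_negative_modulators = c("g0020"), seed = 51))
  corr <- correct_dataset(sim$dataset, parameters = LEADS)
  qc <- qc_screen(corr$dataset)
  tab <- univariate_hits(qc$dataset)
  expect_equal(tab$hit.pct_cells_gt3_puncta[tab$gene_id == "g0010"], "negative_hit")
  expect_equal(tab$hit.pct_cells_gt3_puncta[tab$gene_id == "g0020"], "positive_hit")
  expect_lt(tab$ssmd.pct_cells_gt3_puncta[tab$gene_id == "g0010"], -3)
})

test_that("select_parameters ranks control-separating candidates first", {
  sim <- tiny_screen(seed = 52)
  # informative leads vs parameters beyond the informative set
  cand <- c(LEADS, "param_070", "param_075", "param_080")
  sel <- select_parameters(sim$dataset, candidates = cand)
  expect_setequal(sel, LEADS)
  # manual override short-circuits
  expect_equal(select_parameters(sim$dataset, override = c("a", "b", "c")),
               c("a", "b", "c"))
  expect_error(select_parameters(sim$dataset, candidates = c("x", "y")),
               "selection error")
})

test_that("pca_score recovers exact rank-1 structure", {
  set.seed(6)
  h <- rnorm(40, sd = 3)
  w <- c(0.6, 0.64, 0.48)           # unit norm, positive anchor
  X <- h %*% t(w)
  colnames(X) <- LEADS
  ps <- pca_score(X)
  expect_equal(ps$scores, h, tolerance = 1e-10)
  expect_equal(unname(ps$model$loadings), w, tolerance = 1e-10)
  expect_equal(ps$model$explained_variance, 1, tolerance = 1e-12)
})

test_that("pca_score matches an independent eigen-decomposition oracle", {
  set.seed(61)
  for (i in 1:10) {
    X <- matrix(rnorm(30 * 3), 30, 3)
    colnames(X) <- LEADS
    ps <- pca_score(X)
    # oracle: leading eigenvector of X'X, scores by projection
    eg <- eigen(crossprod(X), symmetric = TRUE)
    w_or <- eg$vectors[, 1]
    if (w_or[1] < 0) w_or <- -w_or
    h_or <- drop(X %*% w_or)
    cosine <- abs(sum(ps$scores * h_or)) /
      sqrt(sum(ps$scores^2) * sum(h_or^2))
    expect_gte(cosine, 0.999)
    expect_equal(unname(ps$model$loadings), w_or, tolerance = 1e-8)
  }
})

test_that("three identical columns give sqrt(3) times the common column", {
  set.seed(62)
  v <- rnorm(25)
  X <- cbind(v, v, v)
  colnames(X) <- LEADS
  ps <- pca_score(X)
  expect_equal(ps$scores, sqrt(3) * v, tolerance = 1e-10)
})

test_that("pca_score is equivariant under positive scaling", {
  set.seed(63)
  X <- matrix(rnorm(20 * 3), 20, 3); colnames(X) <- LEADS
  s1 <- pca_score(X)$scores
  s2 <- pca_score(3.7 * X)$scores
  expect_equal(s2, 3.7 * s1, tolerance = 1e-10)
})

test_that("explained variance is at least 1/3 and high for coherent screens", {
  set.seed(64)
  for (i in 1:10) {
    X <- matrix(rnorm(50 * 3), 50, 3); colnames(X) <- LEADS
    expect_gte(pca_score(X)$model$explained_variance, 1 / 3)
  }
  # strongly coherent: every gene shifts all three readouts together
  eff <- sample(c(-4, 4), 200, replace = TRUE)
  Xc <- eff %*% t(rep(1, 3)) + matrix(rnorm(600, sd = 0.7), 200, 3)
  colnames(Xc) <- LEADS
  expect_gte(pca_score(Xc)$model$explained_variance, 0.9)
})

test_that("pca_hits applies strict thresholds in both screen modes", {
  expect_equal(pca_hits(c(3, -3.2, 2.9, 3.01), threshold = 3),
               c("none", "negative_hit", "none", "positive_hit"))
  expect_equal(pca_hits(c(1.31, -1.3, 1.3), threshold = 1.3),
               c("positive_hit", "none", "none"))
  expect_error(pca_hits(c(1, NA)), "finite")
})

test_that("degenerate inputs to pca_score are rejected", {
  X0 <- matrix(0, 5, 3); colnames(X0) <- LEADS
  expect_error(pca_score(X0), "degenerate")
  X1 <- matrix(c(1, NA, 2, 3, 4, 5), 2, 3)
  expect_error(pca_score(X1), "missing")
})
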