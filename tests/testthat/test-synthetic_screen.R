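test_that("simulation is reproducible from the seed and varies across seeds", {
  a <- tiny_screen(seed = 99)
  b <- tiny_screen(seed = 99)
  c <- tiny_screen(seed = 100)
  expect_identical(a$dataset$wells, b$dataset$wells)
  expect_false(identical(a$dataset$wells$pct_cells_gt3_puncta,
                         c$dataset$wells$pct_cells_gt3_puncta))
})

test_that("an injected row gradient is recoverable by plain regression", {
  sim <- simulate_screen(screen_sim_config(
    n_plates = 1, replicates = 1, row_slope = 0.5, seed = 41))
  w <- sim$dataset$wells
  fit <- lm(w$pct_cells_gt3_puncta ~ well_row(w$well) + well_col(w$well))
  expect_equal(unname(coef(fit)[2]), 0.5, tolerance = 0.15)
})

test_that("with zero slopes the per-plate robust fits find no gradient", {
  sim <- simulate_screen(screen_sim_config(n_plates = 1, replicates = 1, seed = 42))
  corr <- correct_dataset(sim$dataset)
  # |slope| below 3 standard errors for at least 95 % of parameters;
  # se of a slope over rows 1..8 with unit noise is ~ 0.044
  se_row <- 1 / sqrt(sum((well_row(sim$dataset$wells$well) -
                            mean(well_row(sim$dataset$wells$well)))^2))
  frac_ok <- mean(abs(corr$fits$row_slope) < 3 * se_row)
  expect_gte(frac_ok, 0.95)
})

test_that("planted directions equal the sign of the induced shift", {
  sim <- simulate_screen(screen_sim_config(
    n_plates = 2, replicates = 3, effect_size_sd_units = 4,
    planted_positive_modulators = c("g0005", "g0006"),
    planted_negative_modulators = c("g0007"), seed = 43))
  w <- sim$dataset$wells
  neg_med <- median(w$pct_cells_gt3_puncta[w$role == "negative_control"])
  truth <- sim$truth$genes
  for (g in c("g0005", "g0006", "g0007")) {
    dirn <- truth$direction[truth$gene_id == g]
    gene_med <- median(w$pct_cells_gt3_puncta[!is.na(w$gene_id) & w$gene_id == g])
    expect_equal(sign(gene_med - neg_med), dirn)
  }
  # positive modulators are recorded with direction -1 (knockdown suppresses)
  expect_equal(truth$direction[truth$gene_id == "g0005"], -1)
  expect_equal(truth$modulator[truth$gene_id == "g0007"], "negative")
})

test_that("uninformative parameters never respond to planted effects", {
  sim <- simulate_screen(screen_sim_config(
    n_plates = 2, replicates = 3, effect_size_sd_units = 6,
    planted_positive_modulators = sprintf("g%04d", 1:20), seed = 44))
  w <- sim$dataset$wells
  uninf <- names(sim$truth$informative)[!sim$truth$informative][1]
  planted_rows <- !is.na(w$gene_id) & w$gene_id %in% sprintf("g%04d", 1:20)
  neg_rows <- w$role == "negative_control"
  shift <- mean(w[[uninf]][planted_rows]) - mean(w[[uninf]][neg_rows])
  expect_lt(abs(shift), 0.5)
})

test_that("planted gene ids must exist and capacity is checked", {
  expect_error(
    simulate_screen(screen_sim_config(
      n_plates = 1, replicates = 1,
      planted_positive_modulators = "g9999", seed = 1)),
    "capacity error")
})

test_that("zero-effect screens put sample and control wells on one distribution", {
  sim <- simulate_screen(screen_sim_config(
    n_plates = 2, replicates = 3, control_separation_sd_units = 0, seed = 45))
  w <- sim$dataset$wells
  x <- w$pct_cells_gt3_puncta
  expect_lt(abs(median(x[w$role == "sample"]) -
                  median(x[w$role == "negative_control"])), 0.3)
  expect_lt(abs(median(x[w$role == "positive_control"]) -
                  median(x[w$role == "negative_control"])), 0.5)
})

test_that("simulate_expression returns labelled mixtures of the stated shape", {
  se <- simulate_expression(500, expressed_fraction = 0.4, mu_off = 4, mu_on = 9,
                            n_samples = 11, seed = 3)
  expect_equal(dim(se$matrix), c(500, 11))
  expect_equal(length(se$expressed), 500)
  expect_equal(mean(se$expressed), 0.4, tolerance = 0.08)
  expect_gt(mean(se$gene_mean[se$expressed]), mean(se$gene_mean[!se$expressed]))
  # reproducibility
  se2 <- simulate_expression(500, 0.4, 4, 9, 1, 1, 11, seed = 3)
  expect_identical(se$matrix, se2$matrix)
  expect_warning(simulate_expression(50, 0.5, mu_off = 4, mu_on = 4, seed = 1),
                 "degenerate")
})

test_that("secondary-screen simulation assigns three siRNAs per gene", {
  sim <- simulate_screen(screen_sim_config(
    n_plates = 1, replicates = 2, layout_name = "secondary",
    sirnas_per_gene = 3, seed = 46))
  w <- sim$dataset$wells
  samp <- w[w$role == "sample" & w$replicate == 1, ]
  per_gene <- table(samp$gene_id)
  # 78 sample wells on the secondary layout -> 26 genes x 3 siRNAs
  expect_equal(length(per_gene), 26L)
  expect_true(all(per_gene == 3))
  expect_true(all(grepl("_s[123]$", samp$sirna_id)))
  expect_equal(length(unique(samp$sirna_id)), 78L)
})
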