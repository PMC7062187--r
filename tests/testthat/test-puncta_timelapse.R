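# render a frame with given shapes for controlled geometry tests
blank_frame <- function(d = 96) matrix(0, d, d)

test_that("segment_nuclei finds rendered ellipses with accurate geometry", {
  sim <- simulate_timelapse(n_cells = 5, seed = 21)
  truth <- sim$truth$counts[sim$truth$counts$frame == 1, ]
  nuc <- segment_nuclei(sim$stack$nuclear[[1]])
  expect_equal(nrow(nuc), 5)
  d <- sqrt(outer(nuc$cx, truth$cx, "-")^2 + outer(nuc$cy, truth$cy, "-")^2)
  expect_lt(max(apply(d, 1, min)), 2)
  # a rendered circle of diameter 30 measures 30 +- 2 px on the major axis
  img <- mitoscreen:::render_ellipse(blank_frame(), 48, 48, 15, 15, 0, 1)
  circ <- segment_nuclei(img, threshold = 0.5, min_area = 40)
  expect_equal(circ$major, 30, tolerance = 2)
  expect_equal(circ$minor, 30, tolerance = 2)
})

test_that("blank or saturated frames yield zero nuclei with a warning", {
  expect_warning(out <- segment_nuclei(blank_frame()), "blank")
  expect_equal(nrow(out), 0)
  expect_warning(out2 <- segment_nuclei(matrix(1, 64, 64)), "blank")
  expect_equal(nrow(out2), 0)
})

test_that("detect_puncta applies the strict 5 < area < 2000 rule", {
  img <- blank_frame(48)
  # a plus-shaped plateau of exactly 5 pixels: rejected
  img[10, 10] <- 1; img[9, 10] <- 1; img[11, 10] <- 1
  img[10, 9] <- 1; img[10, 11] <- 1
  expect_equal(nrow(detect_puncta(img)), 0)
  # a 3 x 3 + 1 plateau of 10 pixels: accepted
  img2 <- blank_frame(48)
  img2[20:22, 20:22] <- 1; img2[23, 21] <- 1
  det <- detect_puncta(img2)
  expect_equal(nrow(det), 1)
  expect_equal(det$area, 10)
  expect_equal(det$cx, mean(c(rep(20:22, 3), 23)), tolerance = 0.2)
  # blank image: no puncta
  expect_equal(nrow(detect_puncta(blank_frame(32))), 0)
  # an enormous region (> 2000 px) is rejected
  img3 <- blank_frame(96); img3[10:80, 10:80] <- 1
  expect_equal(nrow(detect_puncta(img3)), 0)
})

test_that("detected puncta counts match rendered truth on generator frames", {
  sim <- simulate_timelapse(n_cells = 4, seed = 22)
  truth <- sim$truth$counts
  f <- unique(truth$frame[truth$count > 0])[1]
  det <- detect_puncta(sim$stack$reporter[[f]])
  expect_equal(nrow(det), sum(truth$count[truth$frame == f]))
  expect_true(all(det$area > 5 & det$area < 2000))
})

test_that("puncta attribution uses the inclusive nucleus-diameter rule", {
  nuclei <- data.frame(cx = c(50, 120), cy = c(50, 50),
                       major = c(30, 30), minor = c(20, 20),
                       theta = 0, area = 400)
  puncta <- data.frame(
    cx = c(80, 50, 95, 86),
    cy = c(50, 85, 50, 50),
    area = 10
  )
  # punctum 1: exactly one diameter (30) from nucleus 1 -> attributed (inclusive)
  # punctum 2: 35 px from nucleus 1, farther from 2 -> unattributed
  # punctum 3: 45 from nucleus 1 (out), 25 from nucleus 2 (in) -> nucleus 2
  # punctum 4: 36 from nucleus 1 and 34 from nucleus 2, both > 30 -> unattributed
  asg <- assign_puncta(puncta, nuclei)
  expect_equal(asg$assignment, c(1L, NA, 2L, NA))
  expect_equal(asg$counts, c(1L, 1L))
  expect_equal(asg$n_unattributed, 2L)
  expect_equal(sum(asg$counts) + asg$n_unattributed, nrow(puncta))
})

test_that("ties between eligible nuclei go to the nearest centre", {
  nuclei <- data.frame(cx = c(40, 80), cy = c(40, 40),
                       major = c(50, 50), minor = c(30, 30), theta = 0, area = 300)
  p <- data.frame(cx = 58, cy = 40, area = 9)      # 18 from n1, 22 from n2
  asg <- assign_puncta(p, nuclei)
  expect_equal(asg$assignment, 1L)
})

test_that("peak windows follow the 0-2 / 2-4 / 4-6 h boundaries", {
  sims <- simulate_timelapse(n_cells = 3,
                             peak_window_assignment = c("h0_2", "h2_4", "h4_6"),
                             seed = 23)
  res <- track_and_group(sims$stack)
  expect_equal(sum(res$tracks$complete), 3)
  got <- res$tracks$peak_window[order(res$tracks$cell_id)]
  # match tracks to truth by first-frame position
  truth1 <- sims$truth$counts[sims$truth$counts$frame == 1, ]
  det1 <- res$counts[res$counts$frame == 1, ]
  near <- apply(outer(det1$cx, truth1$cx, "-")^2 +
                  outer(det1$cy, truth1$cy, "-")^2, 1, which.min)
  expect_equal(got, sims$truth$cells$window[truth1$cell_id[near]])
  # the true peak frames respect the window arithmetic (2 h = 8 frames)
  pk <- sims$truth$cells$peak_frame[sims$truth$cells$window == "h2_4"]
  expect_true(all(pk >= 10 & pk <= 17))
})

test_that("recovered window fractions track the generator assignment", {
  sim <- simulate_timelapse(n_cells = 12,
                            peak_window_assignment = c(0.35, 0.30, 0.31),
                            seed = 24)
  res <- track_and_group(sim$stack)
  truth_frac <- table(factor(sim$truth$cells$window,
                             c("h0_2", "h2_4", "h4_6"))) / 12
  expect_true(all(abs(res$summary - as.numeric(truth_frac)) <= 0.05))
  # attributed + unattributed puncta equal detections, every frame
  for (f in c(1, 13, 25)) {
    det <- detect_puncta(sim$stack$reporter[[f]])
    counted <- sum(res$counts$count[res$counts$frame == f], na.rm = TRUE)
    expect_equal(counted + res$unattributed[f], nrow(det))
  }
  # fold change of some cell reaches its planted peak/baseline ratio
  expect_true(all(res$tracks$max_fold_change >= 1))
})

test_that("empty simulations and stacks behave gracefully", {
  sim0 <- simulate_timelapse(n_cells = 0, seed = 25)
  expect_equal(length(sim0$stack$nuclear), 25)
  expect_equal(nrow(sim0$truth$cells), 0)
  res0 <- track_and_group(sim0$stack)
  expect_equal(nrow(res0$tracks), 0)
  expect_true(all(is.na(res0$summary)))
  expect_error(simulate_timelapse(3, frames = 5, interval_min = 15), "span")
  expect_error(simulate_timelapse(100), "placement error")
})

test_that("TIFF round-trip preserves the stack", {
  sim <- simulate_timelapse(n_cells = 2, frames = 25, seed = 26)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(sim$stack, path)
  back <- read_stack(path, interval_min = 15)
  expect_equal(length(back$nuclear), 25)
  clamp <- function(m) pmin(pmax(m, 0), 1)
  expect_equal(back$nuclear[[1]], clamp(sim$stack$nuclear[[1]]), tolerance = 1e-6)
  expect_equal(back$reporter[[10]], clamp(sim$stack$reporter[[10]]), tolerance = 1e-6)
})
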