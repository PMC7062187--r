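# --- rendering primitives (matrices indexed [x, y]) ---------------------

render_ellipse <- function(img, cx, cy, a, b, theta, value) {
  # a, b are semi-axes; paints value inside the rotated ellipse
  x0 <- max(1L, floor(cx - a - 2)); x1 <- min(nrow(img), ceiling(cx + a + 2))
  y0 <- max(1L, floor(cy - a - 2)); y1 <- min(ncol(img), ceiling(cy + a + 2))
  xs <- x0:x1; ys <- y0:y1
  dx <- outer(xs - cx, rep(1, length(ys)))
  dy <- outer(rep(1, length(xs)), ys - cy)
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  inside <- u^2 + v^2 <= 1
  sub <- img[xs, ys, drop = FALSE]
  sub[inside] <- value
  img[xs, ys] <- sub
  img
}

render_disk <- function(img, cx, cy, r, value) {
  x0 <- max(1L, floor(cx - r - 1)); x1 <- min(nrow(img), ceiling(cx + r + 1))
  y0 <- max(1L, floor(cy - r - 1)); y1 <- min(ncol(img), ceiling(cy + r + 1))
  xs <- x0:x1; ys <- y0:y1
  dx <- outer(xs - cx, rep(1, length(ys)))
  dy <- outer(rep(1, length(xs)), ys - cy)
  inside <- dx^2 + dy^2 <= r^2
  sub <- img[xs, ys, drop = FALSE]
  sub[inside] <- sub[inside] + value
  img[xs, ys] <- sub
  img
}

# integer apportionment of n cells to fractions (largest remainder)
apportion <- function(n, fractions) {
  fractions <- fractions / sum(fractions)
  raw <- n * fractions
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Simulate a two-channel puncta time-lapse with known ground truth
#'
#' Renders a nuclear channel (elliptical nuclei on a dark background) and a
#' reporter channel (bright circular puncta near each nucleus) over a
#' 15-minute-cadence time course, with each cell's per-frame puncta count
#' peaking inside an assigned time window (0-2, 2-4 or 4-6 h). Spots are
#' additive plateaus with Gaussian pixel noise; simplicity over optical
#' realism, since only the segmentation and counting contract is exercised.
#'
#' Cells sit on a jittered grid with gentle frame-to-frame drift. Window
#' assignment is deterministic (largest-remainder apportionment of
#' `peak_window_assignment`), so the generated window fractions are exact.
#'
#' @param n_cells number of cells (0 allowed; at most 64).
#' @param frames number of frames (default 25: t = 0..6 h at 15 min).
#' @param interval_min minutes between frames.
#' @param peak_window_assignment either fractions for the three windows
#'   (normalized internally) or a per-cell vector of window labels
#'   (`"h0_2"`, `"h2_4"`, `"h4_6"`).
#' @param puncta_area_range target punctum area range in pixels.
#' @param noise_sd Gaussian pixel noise S.D. on both channels.
#' @param seed RNG seed.
#' @return list with `stack` (a `TimelapseStack`: lists `nuclear` and
#'   `reporter` of frame matrices, `interval_min`, `dim`) and `truth`
#'   (`cells` data frame with per-cell window/peak/geometry, `counts` long
#'   data frame of per-cell per-frame true counts and positions).
#' @export
simulate_timelapse <- function(n_cells, frames = 25L, interval_min = 15L,
                               peak_window_assignment = c(h0_2 = 0.35, h2_4 = 0.30, h4_6 = 0.31),
                               puncta_area_range = c(8L, 16L),
                               noise_sd = 0.01, seed = 1L) {
  stopifnot(frames >= 2L, interval_min >= 1L)
  if ((frames - 1L) * interval_min < 360) {
    stop("frames x interval must span the 0-6 h grouping windows")
  }
  if (n_cells > 64L) stop("placement error: too many cells to pack (max 64)")
  t_min <- (seq_len(frames) - 1L) * interval_min
  windows <- c("h0_2", "h2_4", "h4_6")
  window_of_time <- function(t) ifelse(t <= 120, "h0_2", ifelse(t <= 240, "h2_4", "h4_6"))

  if (n_cells == 0L) {
    dims <- c(64L, 64L)
    stack <- with_seed(seed, {
      list(
        nuclear = lapply(seq_len(frames), function(f)
          matrix(stats::rnorm(prod(dims), 0.02, noise_sd), dims[1], dims[2])),
        reporter = lapply(seq_len(frames), function(f)
          matrix(stats::rnorm(prod(dims), 0.02, noise_sd), dims[1], dims[2]))
      )
    })
    stack$interval_min <- interval_min
    stack$dim <- dims
    class(stack) <- "TimelapseStack"
    return(list(stack = stack,
                truth = list(cells = data.frame(), counts = data.frame())))
  }

  if (length(peak_window_assignment) == n_cells &&
      all(peak_window_assignment %in% windows)) {
    cell_window <- as.character(peak_window_assignment)
  } else {
    stopifnot(length(peak_window_assignment) == 3L)
    n_per <- apportion(n_cells, as.numeric(peak_window_assignment))
    cell_window <- rep(windows, n_per)
  }

  spacing <- 60; margin <- 32
  nx <- ceiling(sqrt(n_cells)); ny <- ceiling(n_cells / nx)
  dims <- c(as.integer(margin * 2 + (nx - 1) * spacing),
            as.integer(margin * 2 + (ny - 1) * spacing))

  with_seed(seed, {
    gx <- margin + ((seq_len(n_cells) - 1L) %% nx) * spacing +
      stats::runif(n_cells, -4, 4)
    gy <- margin + ((seq_len(n_cells) - 1L) %/% nx) * spacing +
      stats::runif(n_cells, -4, 4)
    a <- stats::runif(n_cells, 11, 14)   # semi-major
    b <- stats::runif(n_cells, 8, 10)    # semi-minor
    th <- stats::runif(n_cells, 0, pi)

    # peak frame: interior of the assigned window so the argmax is unambiguous
    interior <- lapply(windows, function(wd) {
      f <- which(window_of_time(t_min) == wd)
      if (length(f) > 2L) f[-c(1L, length(f))] else f
    })
    names(interior) <- windows
    peak_frame <- vapply(cell_window, function(wd) {
      cand <- interior[[wd]]
      cand[sample.int(length(cand), 1L)]
    }, integer(1))
    baseline <- sample(0:1, n_cells, replace = TRUE)
    peak_n <- sample(6:10, n_cells, replace = TRUE)

    # strict-peak triangular count profile
    count_mat <- matrix(0L, n_cells, frames)
    for (i in seq_len(n_cells)) {
      count_mat[i, ] <- pmax(baseline[i],
                             peak_n[i] - ceiling(1.5 * abs(seq_len(frames) - peak_frame[i])))
    }

    # gentle drift, shared per cell
    drift_x <- t(apply(matrix(stats::rnorm(n_cells * frames, 0, 0.6), n_cells), 1, cumsum))
    drift_y <- t(apply(matrix(stats::rnorm(n_cells * frames, 0, 0.6), n_cells), 1, cumsum))
    drift_x <- pmin(pmax(drift_x, -8), 8); drift_y <- pmin(pmax(drift_y, -8), 8)

    r_range <- sqrt(puncta_area_range / pi)
    nuclear <- vector("list", frames); reporter <- vector("list", frames)
    counts_rows <- vector("list", n_cells * frames); ci <- 0L
    for (f in seq_len(frames)) {
      nuc <- matrix(0.02, dims[1], dims[2])
      rep_ch <- matrix(0.02, dims[1], dims[2])
      for (i in seq_len(n_cells)) {
        cx <- gx[i] + drift_x[i, f]; cy <- gy[i] + drift_y[i, f]
        nuc <- render_ellipse(nuc, cx, cy, a[i], b[i], th[i], 0.9)
        k <- count_mat[i, f]
        if (k > 0L) {
          # rejection-sample well-separated puncta positions around the nucleus
          px <- numeric(0); py <- numeric(0); tries <- 0L
          while (length(px) < k && tries < 400L) {
            tries <- tries + 1L
            rr <- stats::runif(1, 4, 22); ang <- stats::runif(1, 0, 2 * pi)
            qx <- cx + rr * cos(ang); qy <- cy + rr * sin(ang)
            if (length(px) == 0 ||
                min((px - qx)^2 + (py - qy)^2) > (2 * max(r_range) + 2)^2) {
              px <- c(px, qx); py <- c(py, qy)
            }
          }
          rs <- sqrt(stats::runif(length(px), puncta_area_range[1], puncta_area_range[2]) / pi)
          for (j in seq_along(px)) {
            rep_ch <- render_disk(rep_ch, px[j], py[j], rs[j], 1.0)
          }
          k <- length(px)  # actually rendered
        }
        ci <- ci + 1L
        counts_rows[[ci]] <- data.frame(cell_id = i, frame = f, t_min = t_min[f],
                                        cx = cx, cy = cy, count = k)
      }
      nuclear[[f]] <- nuc + matrix(stats::rnorm(prod(dims), 0, noise_sd), dims[1], dims[2])
      reporter[[f]] <- rep_ch + matrix(stats::rnorm(prod(dims), 0, noise_sd), dims[1], dims[2])
    }
    counts <- do.call(rbind, counts_rows)
    # true peak from the rendered counts (placement can drop a punctum)
    true_peak <- vapply(seq_len(n_cells), function(i) {
      cc <- counts$count[counts$cell_id == i]
      which.max(cc)
    }, integer(1))
    cells <- data.frame(
      cell_id = seq_len(n_cells), window = cell_window,
      peak_frame = true_peak, x = gx, y = gy,
      major_axis = 2 * a, minor_axis = 2 * b,
      baseline = baseline, peak_count = peak_n,
      max_fold_change = peak_n / pmax(1, baseline)
    )
    stack <- structure(
      list(nuclear = nuclear, reporter = reporter,
           interval_min = interval_min, dim = dims),
      class = "TimelapseStack"
    )
    list(stack = stack, truth = list(cells = cells, counts = counts))
  })
}

#' @export
print.TimelapseStack <- function(x, ...) {
  cat("TimelapseStack: ", length(x$nuclear), " frames, ",
      x$dim[1], " x ", x$dim[2], " px, every ", x$interval_min, " min\n", sep = "")
  invisible(x)
}

#' Write / read a two-channel stack as multi-page TIFF
#'
#' Pages are interleaved (nuclear, reporter, nuclear, ...), 32-bit float.
#'
#' @param stack a `TimelapseStack`.
#' @param path TIFF file path.
#' @param interval_min frame interval to attach on read.
#' @return `path` / a `TimelapseStack`.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "TimelapseStack"))
  pages <- vector("list", 2L * length(stack$nuclear))
  pages[seq(1, length(pages), 2)] <- stack$nuclear
  pages[seq(2, length(pages), 2)] <- stack$reporter
  # TIFF float samples are stored in [0, 1]; clamp the (rare) noise excursions
  pages <- lapply(pages, function(m) pmin(pmax(m, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path, interval_min = 15L) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) %% 2L != 0L) stop("format error: odd page count in stack")
  structure(
    list(nuclear = pages[seq(1, length(pages), 2)],
         reporter = pages[seq(2, length(pages), 2)],
         interval_min = interval_min,
         dim = dim(pages[[1]])),
    class = "TimelapseStack"
  )
}
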