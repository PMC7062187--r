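# greyscale morphological reconstruction of `marker` under `mask`
# (geodesic dilation to stability), implemented as repeated directional
# raster sweeps: each sweep propagates values down, up, left and right with
# vectorized per-line updates, which converges in a handful of sweeps
# instead of one pixel per dilation step
grey_reconstruct <- function(marker, mask, tol = 1e-9, max_sweeps = 400L) {
  m <- pmin(marker, mask)
  nr <- nrow(m); nc <- ncol(m)
  for (s in seq_len(max_sweeps)) {
    before <- m
    if (nr > 1L) {
      for (i in 2:nr)        m[i, ] <- pmin(mask[i, ], pmax(m[i, ], m[i - 1L, ]))
      for (i in (nr - 1L):1) m[i, ] <- pmin(mask[i, ], pmax(m[i, ], m[i + 1L, ]))
    }
    if (nc > 1L) {
      for (j in 2:nc)        m[, j] <- pmin(mask[, j], pmax(m[, j], m[, j - 1L]))
      for (j in (nc - 1L):1) m[, j] <- pmin(mask[, j], pmax(m[, j], m[, j + 1L]))
    }
    if (max(abs(m - before)) < tol) return(m)
  }
  warning("greyscale reconstruction did not fully converge")
  m
}

#' Segment nuclei as ellipses from the nuclear channel
#'
#' Thresholds the nuclear (Hoechst) channel, labels connected components and
#' summarizes each by its fitted ellipse (intensity moments): centroid,
#' major/minor axis lengths and orientation. Components below `min_area`
#' are discarded. The major-axis length is what downstream puncta
#' attribution treats as the nucleus "diameter".
#'
#' @param frame single-channel image matrix.
#' @param threshold intensity threshold; `NULL` picks Otsu's threshold.
#' @param min_area minimum component area in pixels.
#' @return data frame with columns `cx`, `cy`, `major`, `minor`, `theta`,
#'   `area` (zero rows, with a warning, for blank/saturated frames).
#' @export
segment_nuclei <- function(frame, threshold = NULL, min_area = 40) {
  stopifnot(is.matrix(frame))
  empty <- data.frame(cx = numeric(0), cy = numeric(0), major = numeric(0),
                      minor = numeric(0), theta = numeric(0), area = numeric(0))
  rng <- range(frame)
  # blank/saturated guard: no structure beyond the noise floor
  if (diff(rng) < 1e-6 ||
      diff(rng) < 10 * stats::mad(frame, constant = 1.4826)) {
    warning("blank or saturated frame: no nuclei")
    return(empty)
  }
  if (is.null(threshold)) {
    scaled <- (frame - rng[1]) / diff(rng)
    threshold <- rng[1] + diff(rng) * EBImage::otsu(EBImage::Image(scaled))
  }
  bw <- frame > threshold
  if (!any(bw) || all(bw)) {
    warning("blank or saturated frame: no nuclei")
    return(empty)
  }
  lab <- EBImage::bwlabel(bw)
  mom <- EBImage::computeFeatures.moment(lab)
  shp <- EBImage::computeFeatures.shape(lab)
  if (is.null(mom) || nrow(mom) == 0) {
    warning("no nuclei detected")
    return(empty)
  }
  keep <- shp[, "s.area"] >= min_area
  mom <- mom[keep, , drop = FALSE]; shp <- shp[keep, , drop = FALSE]
  data.frame(
    cx = mom[, "m.cx"], cy = mom[, "m.cy"],
    major = mom[, "m.majoraxis"],
    minor = mom[, "m.majoraxis"] * sqrt(1 - mom[, "m.eccentricity"]^2),
    theta = mom[, "m.theta"],
    area = shp[, "s.area"],
    row.names = NULL
  )
}

#' Detect puncta by the extended-maxima transform
#'
#' Computes the h-maxima transform of the reporter channel (greyscale
#' reconstruction of `frame - h` under `frame`); the residue
#' `frame - reconstruction` is `h` on plateaus that stand at least `h`
#' above their surroundings and decays to 0 over the background. Candidate
#' puncta are the connected regions where the residue exceeds `h / 2` (the
#' half-depth rule keeps whole plateaus together under pixel noise), whose
#' peak rises at least `h` above the frame's diffuse background (its
#' median — this discards the degenerate whole-frame plateau of a blank
#' frame), and whose pixel area satisfies `area_min < area < area_max`
#' (strict inequalities, so a region of exactly `area_min` pixels is
#' rejected).
#'
#' @param frame single-channel image matrix.
#' @param area_min,area_max strict area bounds in pixels (defaults 5 and
#'   2000).
#' @param h contrast depth of the extended-maxima transform, in intensity
#'   units of `frame`.
#' @return data frame with columns `cx`, `cy`, `area`.
#' @export
detect_puncta <- function(frame, area_min = 5, area_max = 2000, h = 0.3) {
  stopifnot(is.matrix(frame), h > 0)
  rec <- grey_reconstruct(frame - h, frame)
  rmax <- (frame - rec) >= h / 2
  # a flat (blank or saturated) frame is one global plateau; genuine puncta
  # must also rise at least h above the diffuse background level
  bg <- stats::median(frame)
  if (!any(rmax)) {
    return(data.frame(cx = numeric(0), cy = numeric(0), area = numeric(0)))
  }
  lab <- EBImage::bwlabel(rmax)
  n <- max(lab)
  idx <- which(lab > 0, arr.ind = TRUE)
  lab_v <- lab[lab > 0]
  area <- tabulate(lab_v, nbins = n)
  cx <- tapply(idx[, 1], lab_v, mean)
  cy <- tapply(idx[, 2], lab_v, mean)
  peak <- tapply(frame[lab > 0], lab_v, max)
  keep <- area > area_min & area < area_max & peak >= bg + h
  data.frame(cx = as.numeric(cx[keep]), cy = as.numeric(cy[keep]),
             area = area[keep], row.names = NULL)
}

#' Attribute puncta to nuclei
#'
#' A punctum is eligible for a nucleus when its centroid lies within that
#' nucleus's diameter (major-axis length) of the nucleus centre; among
#' eligible nuclei the nearest wins. Ineligible puncta are reported as
#' unattributed, never reassigned.
#'
#' @param puncta data frame from [detect_puncta()].
#' @param nuclei data frame from [segment_nuclei()].
#' @return list with `counts` (integer per nucleus row), `assignment`
#'   (nucleus row index per punctum, NA if unattributed), `n_unattributed`.
#' @export
assign_puncta <- function(puncta, nuclei) {
  n_nuc <- nrow(nuclei); n_p <- nrow(puncta)
  counts <- integer(n_nuc)
  assignment <- rep(NA_integer_, n_p)
  if (n_nuc > 0 && n_p > 0) {
    d <- sqrt(outer(puncta$cx, nuclei$cx, "-")^2 +
              outer(puncta$cy, nuclei$cy, "-")^2)
    eligible <- d <= matrix(nuclei$major, n_p, n_nuc, byrow = TRUE)
    d[!eligible] <- Inf
    best <- apply(d, 1, which.min)
    ok <- is.finite(d[cbind(seq_len(n_p), best)])
    assignment[ok] <- best[ok]
    counts <- tabulate(assignment[ok], nbins = n_nuc)
  }
  list(counts = counts, assignment = assignment,
       n_unattributed = sum(is.na(assignment)))
}

#' Track cells and group them by puncta peak window
#'
#' Runs [segment_nuclei()], [detect_puncta()] and [assign_puncta()] on every
#' frame, links nuclei across frames by greedy nearest-centroid matching
#' under a maximum-displacement gate, and assembles per-cell puncta-count
#' trajectories. Each complete track is labelled with the window (0-2,
#' 2-4 or 4-6 h) containing its maximum count; argmax ties take the
#' earliest frame. A track that misses a detection is terminated and
#' flagged, never bridged.
#'
#' @param stack a `TimelapseStack`.
#' @param h,area_min,area_max puncta-detection settings (see
#'   [detect_puncta()]).
#' @param nucleus_threshold,min_nucleus_area nucleus-segmentation settings.
#' @param max_displacement tracking gate in pixels per frame; `NULL` uses
#'   the median first-frame nucleus major axis.
#' @return list with `tracks` (per-cell summary: peak frame/count, baseline
#'   count, `max_fold_change`, `peak_window`, `complete` flag), `counts`
#'   (long per-cell per-frame table), `summary` (fraction of complete cells
#'   per window), and `unattributed` (per-frame counts of orphan puncta).
#' @export
track_and_group <- function(stack, h = 0.3, area_min = 5, area_max = 2000,
                            nucleus_threshold = NULL, min_nucleus_area = 40,
                            max_displacement = NULL) {
  stopifnot(inherits(stack, "TimelapseStack"))
  n_frames <- length(stack$nuclear)
  if (n_frames < 2L) stop("need >= 2 frames to track")
  interval <- stack$interval_min
  window_of_time <- function(t) ifelse(t <= 120, "h0_2", ifelse(t <= 240, "h2_4", "h4_6"))

  per_frame <- vector("list", n_frames)
  unattributed <- integer(n_frames)
  for (f in seq_len(n_frames)) {
    nuc <- suppressWarnings(
      segment_nuclei(stack$nuclear[[f]], threshold = nucleus_threshold,
                     min_area = min_nucleus_area))
    pts <- detect_puncta(stack$reporter[[f]], area_min = area_min,
                         area_max = area_max, h = h)
    asg <- assign_puncta(pts, nuc)
    nuc$count <- asg$counts
    unattributed[f] <- asg$n_unattributed
    per_frame[[f]] <- nuc
  }

  first <- per_frame[[1]]
  if (is.null(max_displacement)) {
    max_displacement <- if (nrow(first) > 0) stats::median(first$major) else 30
  }
  # track state: current position, per-frame row index (NA once lost)
  n_tracks <- nrow(first)
  pos_x <- first$cx; pos_y <- first$cy
  active <- rep(TRUE, n_tracks)
  hit <- matrix(NA_integer_, nrow = n_tracks, ncol = n_frames)
  if (n_tracks > 0) hit[, 1] <- seq_len(n_tracks)
  started <- rep(1L, n_tracks)

  for (f in seq_len(n_frames)[-1]) {
    det <- per_frame[[f]]
    n_det <- nrow(det)
    matched_det <- rep(FALSE, n_det)
    matched_trk <- rep(FALSE, n_tracks)
    if (n_det > 0 && any(active)) {
      idx_act <- which(active)
      d <- sqrt(outer(pos_x[idx_act], det$cx, "-")^2 +
                outer(pos_y[idx_act], det$cy, "-")^2)
      ord <- order(d)
      for (k in ord) {
        if (d[k] > max_displacement) break
        ti <- idx_act[(k - 1) %% length(idx_act) + 1]
        dj <- (k - 1) %/% length(idx_act) + 1
        if (matched_trk[ti] || matched_det[dj]) next
        matched_trk[ti] <- TRUE; matched_det[dj] <- TRUE
        hit[ti, f] <- dj
        pos_x[ti] <- det$cx[dj]; pos_y[ti] <- det$cy[dj]
      }
    }
    active[active & !matched_trk[seq_len(n_tracks)]] <- FALSE
    if (any(!matched_det)) {
      # unmatched detections start new (necessarily incomplete) tracks
      for (dj in which(!matched_det)) {
        n_tracks <- n_tracks + 1L
        pos_x <- c(pos_x, det$cx[dj]); pos_y <- c(pos_y, det$cy[dj])
        active <- c(active, TRUE)
        matched_trk <- c(matched_trk, TRUE)
        hit <- rbind(hit, NA_integer_)
        hit[n_tracks, f] <- dj
        started <- c(started, f)
      }
    }
  }

  t_min <- (seq_len(n_frames) - 1L) * interval
  counts_rows <- vector("list", n_tracks)
  track_rows <- vector("list", n_tracks)
  for (ti in seq_len(n_tracks)) {
    fr <- which(!is.na(hit[ti, ]))
    cnt <- rep(NA_integer_, n_frames)
    cxs <- rep(NA_real_, n_frames); cys <- rep(NA_real_, n_frames)
    for (f in fr) {
      row <- per_frame[[f]][hit[ti, f], ]
      cnt[f] <- row$count; cxs[f] <- row$cx; cys[f] <- row$cy
    }
    complete <- length(fr) == n_frames
    peak <- fr[which.max(cnt[fr])]          # earliest argmax among observed
    baseline <- cnt[fr[1]]
    counts_rows[[ti]] <- data.frame(cell_id = ti, frame = seq_len(n_frames),
                                    t_min = t_min, cx = cxs, cy = cys, count = cnt)
    track_rows[[ti]] <- data.frame(
      cell_id = ti, start_frame = started[ti], n_observed = length(fr),
      complete = complete, broken = !complete,
      peak_frame = peak, peak_count = cnt[peak],
      baseline_count = baseline,
      max_fold_change = cnt[peak] / max(1, baseline),
      peak_window = window_of_time(t_min[peak])
    )
  }
  tracks <- if (n_tracks > 0) do.call(rbind, track_rows) else
    data.frame(cell_id = integer(0))
  counts <- if (n_tracks > 0) do.call(rbind, counts_rows) else
    data.frame(cell_id = integer(0))
  comp <- tracks[isTRUE(nrow(tracks) > 0) & tracks$complete, , drop = FALSE]
  summary <- vapply(c("h0_2", "h2_4", "h4_6"), function(wd)
    if (nrow(comp) > 0) mean(comp$peak_window == wd) else NA_real_, numeric(1))
  list(tracks = tracks, counts = counts, summary = summary,
       unattributed = unattributed)
}
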