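#' Centroid pupil-tracker configuration
#'
#' Parameters of the threshold-based pupil tracker.  In practice these are
#' tuned per participant (camera distance, iris darkness and lighting all
#' move them); the defaults suit the synthetic renderer at 192 px frames.
#'
#' @param roi Region of interest `c(row_min, row_max, col_min, col_max)`,
#'   1-based inclusive; `NULL` for the full frame.
#' @param intensity_threshold Grayscale level in `[0, 255]`; pixels strictly
#'   darker are pupil candidates.
#' @param diameter_range Admissible equivalent diameter (px) of a candidate,
#'   `c(min, max)`.
#' @param circularity_min Minimum circularity `4*pi*area/perimeter^2`
#'   (1 for an ideal circle; rasterized disks score about 0.9).
#' @param consistency_radius Maximum jump (px) from the last valid pupil
#'   center for a candidate to count as consistent.
#' @return A list of class `tracker_config`.
#' @export
tracker_config <- function(roi = NULL, intensity_threshold = 80,
                           diameter_range = c(10, 80),
                           circularity_min = 0.65,
                           consistency_radius = 15) {
  stopifnot(
    intensity_threshold >= 0, intensity_threshold <= 255,
    length(diameter_range) == 2, diameter_range[1] < diameter_range[2],
    circularity_min >= 0, circularity_min <= 1,
    consistency_radius > 0
  )
  if (!is.null(roi)) {
    stopifnot(length(roi) == 4, roi[1] <= roi[2], roi[3] <= roi[4])
  }
  structure(
    list(
      roi = roi, intensity_threshold = intensity_threshold,
      diameter_range = diameter_range, circularity_min = circularity_min,
      consistency_radius = consistency_radius
    ),
    class = "tracker_config"
  )
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so merge labels
# that touch diagonally.
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n < 2) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nr <- nrow(lab); nc <- ncol(lab)
  for (dd in list(c(1, 1), c(1, -1))) {
    a <- lab[1:(nr - 1), if (dd[2] == 1) 1:(nc - 1) else 2:nc]
    b <- lab[2:nr, if (dd[2] == 1) 2:nc else 1:(nc - 1)]
    touch <- a > 0 & b > 0 & a != b
    if (any(touch)) {
      pairs <- unique(cbind(a[touch], b[touch]))
      for (i in seq_len(nrow(pairs))) {
        ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

# Even-odd point-in-polygon, vectorized over points.
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Closed polygon chain length of an ocontour coordinate matrix.
chain_perimeter <- function(xy) {
  d <- xy - xy[c(2:nrow(xy), 1), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

#' Segment pupil candidates in one frame
#'
#' Thresholds the grayscale frame inside the region of interest to a binary
#' image, labels connected dark blobs (8-connected), closes each blob by its
#' convex hull (which also fills holes), and measures area, binary center of
#' mass, equivalent diameter `sqrt(4*area/pi)` and circularity
#' `4*pi*area/perimeter^2` (perimeter traced along the outer contour).
#' Candidates outside the configured diameter range or below the minimum
#' circularity are dropped; an empty result is a valid outcome.
#'
#' @param frame Grayscale matrix (0-255).
#' @param config A [tracker_config()].
#' @return Tibble with one row per surviving candidate: `cx` (column), `cy`
#'   (row) at sub-pixel precision, `area`, `eq_diameter`, `circularity`.
#' @export
segment_pupil_candidates <- function(frame, config) {
  stopifnot(is.matrix(frame), inherits(config, "tracker_config"))
  roi <- config$roi %||% c(1, nrow(frame), 1, ncol(frame))
  if (roi[2] > nrow(frame) || roi[4] > ncol(frame) || any(roi < 1)) {
    stop("roi exceeds frame bounds")
  }
  sub <- frame[roi[1]:roi[2], roi[3]:roi[4], drop = FALSE]
  mask <- (sub < config$intensity_threshold) * 1
  if (!any(mask > 0)) return(empty_candidates())
  lab <- label8(mask)
  n <- max(lab)
  sizes <- tabulate(lab[lab > 0], nbins = n)
  # raw blobs far below the minimum admissible area cannot pass the
  # diameter filter even after hull closing of a thin ring; skip them early
  min_area <- pi * (config$diameter_range[1] / 2)^2
  keep <- which(sizes >= max(4, 0.2 * min_area))
  if (length(keep) == 0) return(empty_candidates())

  all_idx <- which(lab > 0, arr.ind = TRUE)
  all_lab <- lab[lab > 0]
  out <- lapply(keep, function(i) {
    idx <- all_idx[all_lab == i, , drop = FALSE]
    rows <- idx[, 1]; cols <- idx[, 2]
    r0 <- min(rows); c0 <- min(cols)
    hgt <- max(rows) - r0 + 1L
    wdt <- max(cols) - c0 + 1L
    blob <- matrix(0L, hgt, wdt)
    blob[cbind(rows - r0 + 1L, cols - c0 + 1L)] <- 1L
    if (nrow(idx) >= 3 && length(unique(rows)) > 1 &&
        length(unique(cols)) > 1) {
      hl <- grDevices::chull(cols, rows)
      bb <- expand.grid(row = seq_len(hgt) + r0 - 1L,
                        col = seq_len(wdt) + c0 - 1L)
      inside <- points_in_polygon(bb$col, bb$row, cols[hl], rows[hl])
      blob[cbind(bb$row[inside] - r0 + 1L, bb$col[inside] - c0 + 1L)] <- 1L
    }
    fidx <- which(blob == 1L, arr.ind = TRUE)
    area <- nrow(fidx)
    oc <- EBImage::ocontour(blob)[[1]]
    per <- if (is.null(oc) || nrow(oc) < 3) NA_real_ else chain_perimeter(oc)
    c(
      cx = mean(fidx[, 2]) + c0 - 1 + roi[3] - 1,
      cy = mean(fidx[, 1]) + r0 - 1 + roi[1] - 1,
      area = area,
      eq_diameter = sqrt(4 * area / pi),
      circularity = if (is.na(per) || per == 0) NA_real_ else
        4 * pi * area / per^2
    )
  })
  m <- do.call(rbind, out)
  cand <- tibble::as_tibble(as.data.frame(m))
  keep <- cand$eq_diameter >= config$diameter_range[1] &
    cand$eq_diameter <= config$diameter_range[2] &
    !is.na(cand$circularity) &
    cand$circularity >= config$circularity_min
  cand[keep, , drop = FALSE]
}

empty_candidates <- function() {
  tibble::tibble(
    cx = numeric(), cy = numeric(), area = numeric(),
    eq_diameter = numeric(), circularity = numeric()
  )
}

#' Choose the pupil estimate among candidates
#'
#' Keeps the candidates within `consistency_radius` of the previous valid
#' center (all of them when there is no history, e.g. on the first frame)
#' and returns the largest by area.  With no consistent candidate the frame
#' is labeled missing.
#'
#' @param candidates Tibble from [segment_pupil_candidates()].
#' @param previous One-row tibble (or list) with the last valid `cx`, `cy`,
#'   or `NULL`.
#' @param config A [tracker_config()].
#' @return One-row tibble: `cx`, `cy`, `area`, `eq_diameter`,
#'   `circularity`, `valid`.  Geometry is `NA` when invalid.
#' @export
select_pupil <- function(candidates, previous = NULL, config) {
  stopifnot(inherits(config, "tracker_config"))
  cand <- candidates
  if (!is.null(previous) && nrow(cand) > 0) {
    d <- sqrt((cand$cx - previous$cx)^2 + (cand$cy - previous$cy)^2)
    cand <- cand[d <= config$consistency_radius, , drop = FALSE]
  }
  if (nrow(cand) == 0) {
    return(tibble::tibble(
      cx = NA_real_, cy = NA_real_, area = NA_real_,
      eq_diameter = NA_real_, circularity = NA_real_, valid = FALSE
    ))
  }
  best <- cand[which.max(cand$area), , drop = FALSE]
  best$valid <- TRUE
  best
}

#' Track the pupil through a video
#'
#' Runs segmentation and selection over every frame and converts the pupil
#' center to a displacement trace relative to the first valid frame.
#' Frames without a consistent pupil are marked missing; a video losing
#' strictly more than 30% of its frames is classified "low data".
#'
#' @param video An [okn_video()] or 3-D array.
#' @param config A [tracker_config()].
#' @param fps Frame rate if `video` is a plain array.
#' @return A list of class `pupil_track`: `trace` (an [okn_trace()], units
#'   `"px"`, source `"centroid"`), `estimates` (per-frame tibble),
#'   `loss_fraction` and `low_data`.
#' @export
track_pupil <- function(video, config, fps = NULL) {
  a <- as_video_array(video)
  fps <- video_fps(video, fps)
  nt <- dim(a)[3]
  if (nt < 2) stop("video must have at least 2 frames")
  prev <- NULL
  rows <- vector("list", nt)
  for (t in seq_len(nt)) {
    cand <- segment_pupil_candidates(a[, , t], config)
    est <- select_pupil(cand, prev, config)
    if (est$valid) prev <- est
    est$frame <- t
    rows[[t]] <- est
  }
  est <- dplyr::bind_rows(rows)
  loss <- mean(!est$valid)
  first_valid <- which(est$valid)[1]
  if (is.na(first_valid)) {
    dx <- dy <- rep(NA_real_, nt)
  } else {
    dx <- est$cx - est$cx[first_valid]
    dy <- est$cy - est$cy[first_valid]
  }
  trace <- okn_trace((seq_len(nt) - 1) / fps, dx, dy,
                     valid = est$valid, units = "px", source = "centroid",
                     fps = fps)
  structure(
    list(trace = trace, estimates = est,
         loss_fraction = loss, low_data = loss > 0.30),
    class = "pupil_track"
  )
}

#' @export
print.pupil_track <- function(x, ...) {
  cat(sprintf(
    "<pupil_track> %d frames, loss %.1f%%%s\n",
    nrow(x$trace), 100 * x$loss_fraction,
    if (x$low_data) " (low data)" else ""
  ))
  invisible(x)
}
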