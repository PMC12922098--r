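#' Temporal phase unwrapping
#'
#' Removes 2*pi jump artifacts from a time series of wrapped phases at one
#' pixel and level.  The output differs from the input by integer multiples
#' of 2*pi per sample, consecutive differences lie in `(-pi, pi]`, and the
#' first sample is unchanged.
#'
#' @param x Numeric vector of wrapped phases in `(-pi, pi]`.
#' @return Numeric vector of unwrapped phases, same length.
#' @examples
#' temporal_unwrap(c(3, -3))   # second sample becomes 3 + (2*pi - 6)
#' @export
temporal_unwrap <- function(x) {
  if (length(x) == 0) stop("empty phase series")
  if (length(x) == 1) return(x)
  x[1] + c(0, cumsum(wrap_pm_pi(diff(x))))
}

# Wrap into (-pi, pi].
wrap_pm_pi <- function(d) {
  d - 2 * pi * ceiling((d - pi) / (2 * pi))
}

#' Build a phase stack over a pixel window
#'
#' Decomposes every video frame with the filter bank and collects, over a
#' square window of pixels, the per-level wrapped phase, amplitude and the
#' spatial phase gradients (the local instantaneous frequency, computed
#' spectrally as `Im(conj(R) * dR/dx) / |R|^2`, which is free of
#' finite-difference attenuation).  Phase is then unwrapped in time per
#' pixel and level.  The stack is the input to the weighted least-squares
#' displacement solve.
#'
#' Only the frequency-domain samples inside each mask's support are summed
#' (a direct inverse DFT at the window pixels), so the cost scales with the
#' window, not the frame.
#'
#' @param video An [okn_video()] (array `rows x cols x frames` with a frame
#'   rate) or a plain 3-D array.
#' @param bank A [csp_filter_bank()] matching the frame size.
#' @param center Window center, `c(row, col)`, 1-based.
#' @param radius Window half-width in px: the window is
#'   `(2*radius + 1)^2` pixels.  Must leave the window inside the frame.
#' @param fps Frame rate, required if `video` is a plain array.
#'
#' @return An object of class `phase_stack`: list with arrays `phi_wrapped`,
#'   `phi` (unwrapped), `amp`, `gx`, `gy`, each
#'   `frames x win x win x levels`, the time axis `t_s`, window coordinates
#'   `rows`/`cols`, and the bank's level metadata.
#' @export
csp_phase_stack <- function(video, bank, center, radius = 2L, fps = NULL) {
  stopifnot(inherits(bank, "csp_bank"))
  v <- as_video_array(video)
  fps <- fps %||% attr(video, "fps") %||% stop("`fps` required")
  if (!all(dim(v)[1:2] == bank$image_shape)) {
    stop("video frame size does not match bank$image_shape")
  }
  nt <- dim(v)[3]
  if (nt < 2) stop("video must have at least 2 frames")
  rows <- (center[1] - radius):(center[1] + radius)
  cols <- (center[2] - radius):(center[2] + radius)
  if (min(rows) < 1 || min(cols) < 1 ||
      max(rows) > dim(v)[1] || max(cols) > dim(v)[2]) {
    stop("window extends past the frame border")
  }
  vals <- csp_point_subbands(v, bank, rows, cols)
  w <- 2L * radius + 1L
  L <- length(bank$masks)
  dims <- c(nt, w, w, L)
  phi_w <- Arg(vals$V)
  amp <- Mod(vals$V)
  a2 <- amp^2
  a2[a2 == 0] <- NA_real_
  gx <- Im(Conj(vals$V) * vals$Vx) / a2
  gy <- Im(Conj(vals$V) * vals$Vy) / a2
  dim(phi_w) <- dim(amp) <- dim(gx) <- dim(gy) <- dims

  # unwrap along time, per pixel and level
  m <- matrix(phi_w, nrow = nt)
  dm <- wrap_pm_pi(m[-1, , drop = FALSE] - m[-nt, , drop = FALSE])
  dm <- if (nt > 2) apply(dm, 2, cumsum) else dm
  phi <- m[rep(1, nt), , drop = FALSE] + rbind(0, dm)
  dim(phi) <- dims

  structure(
    list(
      phi_wrapped = phi_w, phi = phi, amp = amp, gx = gx, gy = gy,
      t_s = (seq_len(nt) - 1) / fps, fps = fps,
      rows = rows, cols = cols, center = center,
      levels = bank$levels
    ),
    class = "phase_stack"
  )
}

# Complex sub-band values and their spatial derivatives at selected pixels
# for every frame and level.  Returns list of arrays
# [frames, pixels (row-major over rows x cols grid), levels].
csp_point_subbands <- function(v, bank, rows, cols) {
  nr <- dim(v)[1]; nc <- dim(v)[2]; nt <- dim(v)[3]
  npix <- nr * nc
  L <- length(bank$masks)
  grid <- expand.grid(row = rows, col = cols)
  npts <- nrow(grid)

  FF <- matrix(0i, npix, nt)
  for (t in seq_len(nt)) FF[, t] <- as.vector(stats::fft(v[, , t]))

  ky <- rep(fft_freqs(nr), nc)
  kx <- rep(fft_freqs(nc), each = nr)
  iy <- rep(0:(nr - 1), nc)
  ix <- rep(0:(nc - 1), each = nr)
  V <- array(0i, c(nt, npts, L))
  Vx <- V; Vy <- V
  for (l in seq_len(L)) {
    idx <- which(bank$masks[[l]] > 1e-10)
    # inverse-DFT kernel restricted to the mask support, mask folded in
    ph <- outer(grid$row - 1, iy[idx] / nr) + outer(grid$col - 1, ix[idx] / nc)
    E <- exp(2i * pi * ph) * matrix(bank$masks[[l]][idx] / npix,
                                    npts, length(idx), byrow = TRUE)
    Fi <- FF[idx, , drop = FALSE]
    V[, , l] <- t(E %*% Fi)
    Vx[, , l] <- t((E * matrix(1i * kx[idx], npts, length(idx),
                               byrow = TRUE)) %*% Fi)
    Vy[, , l] <- t((E * matrix(1i * ky[idx], npts, length(idx),
                               byrow = TRUE)) %*% Fi)
  }
  list(V = V, Vx = Vx, Vy = Vy)
}

#' Temporal median filtering of a phase stack
#'
#' Applies a running median of odd length `window` along time to the
#' unwrapped phase of every pixel and level; `window = 1` is the identity.
#' Suppresses isolated phase spikes before the displacement solve.  The
#' reference sample (t = 0) is kept exactly as unwrapped so that phase
#' deltas - and hence displacement - remain relative to the true first
#' frame.
#'
#' @param stack A [csp_phase_stack()].
#' @param window Odd window length in samples.
#' @return The stack with `phi` filtered.
#' @export
median_filter_phase <- function(stack, window = 3L) {
  stopifnot(inherits(stack, "phase_stack"))
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("`window` must be odd and >= 1")
  if (window == 1L) return(stack)
  d <- dim(stack$phi)
  nt <- d[1]
  if (window > nt) stop("`window` longer than the series")
  m <- matrix(stack$phi, nrow = nt)
  ref <- m[1, ]
  m <- apply(m, 2, stats::runmed, k = window, endrule = "median")
  m[1, ] <- ref # keep the reference frame exact
  dim(m) <- d
  stack$phi <- m
  stack
}

#' Phase change relative to the reference frame
#'
#' Returns the per-level unwrapped phase difference
#' `delta_phi_l(x, t) = phi_l(x, t) - phi_l(x, 0)` over the stack window.
#' At the reference frame it is exactly zero.
#'
#' @param stack A [csp_phase_stack()].
#' @param t Frame index (1-based; 1 is the reference).
#' @return Array `win x win x levels`.
#' @export
phase_delta <- function(stack, t) {
  stopifnot(inherits(stack, "phase_stack"))
  d <- dim(stack$phi)
  if (t < 1 || t > d[1]) stop("frame index out of range")
  array(stack$phi[t, , , ] - stack$phi[1, , , ], d[2:4])
}

#' Weighted least-squares displacement at one pixel and frame
#'
#' Solves the phase-constancy system across levels at a single pixel: the
#' design matrix stacks the spatial phase gradients `(dphi/dx, dphi/dy)` of
#' every level, the observations are the temporal phase changes relative to
#' the reference frame, and the weights couple the local amplitude at both
#' times (`A_l(x, t) * A_l(x, 0)` by default).  Displacement is reported for
#' the image content: positive `dx` means the content moved toward larger
#' column index.  A rank-deficient system (fewer than two independent
#' gradient orientations with nonzero weight) is an error, never a silent
#' pseudo-solution.
#'
#' @param stack A [csp_phase_stack()] (median-filter first if desired).
#' @param pixel `c(row, col)` index within the stack window.
#' @param t Frame index, 1-based.
#' @param weight `"coupled"` for `A(t) * A(0)` weights (default) or
#'   `"squared"` for `A(t)^2`.
#' @param levels Optional integer vector restricting which levels enter the
#'   solve (default: all).
#' @return Named numeric `c(dx, dy)` in pixels.
#' @export
solve_displacement <- function(stack, pixel, t,
                               weight = c("coupled", "squared"),
                               levels = NULL) {
  stopifnot(inherits(stack, "phase_stack"))
  weight <- match.arg(weight)
  w <- dim(stack$phi)[2]
  if (any(pixel < 1) || any(pixel > w)) stop("`pixel` outside the window")
  L <- dim(stack$phi)[4]
  sel <- levels %||% seq_len(L)
  # trapezoidal gradient: average of reference- and current-frame local
  # frequency, second-order accurate for a pure shift
  gx <- (stack$gx[t, pixel[1], pixel[2], sel] +
           stack$gx[1, pixel[1], pixel[2], sel]) / 2
  gy <- (stack$gy[t, pixel[1], pixel[2], sel] +
           stack$gy[1, pixel[1], pixel[2], sel]) / 2
  dp <- stack$phi[t, pixel[1], pixel[2], sel] -
    stack$phi[1, pixel[1], pixel[2], sel]
  a_t <- stack$amp[t, pixel[1], pixel[2], sel]
  a_0 <- stack$amp[1, pixel[1], pixel[2], sel]
  w2 <- if (weight == "coupled") a_t * a_0 else a_t^2
  d <- wls_solve(gx, gy, dp, w2)
  if (anyNA(d)) {
    stop(sprintf(
      "singular phase-flow system at pixel (%d, %d), frame %d",
      pixel[1], pixel[2], t
    ))
  }
  c(dx = d[1], dy = d[2])
}

# 2x2 weighted normal equations; NA on rank deficiency.
# Sign: content shifted by d gives dphi = -grad . d.
wls_solve <- function(gx, gy, dp, w2) {
  ok <- is.finite(gx) & is.finite(gy) & is.finite(dp) & is.finite(w2)
  gx <- gx[ok]; gy <- gy[ok]; dp <- dp[ok]; w2 <- w2[ok]
  sxx <- sum(w2 * gx * gx)
  sxy <- sum(w2 * gx * gy)
  syy <- sum(w2 * gy * gy)
  bx <- -sum(w2 * gx * dp)
  by <- -sum(w2 * gy * dp)
  det <- sxx * syy - sxy * sxy
  if (!is.finite(det) || det <= 1e-9 * (sxx + syy)^2 || (sxx + syy) == 0) {
    return(c(NA_real_, NA_real_))
  }
  c((syy * bx - sxy * by) / det, (sxx * by - sxy * bx) / det)
}

#' Extract a displacement trace at a measurement point
#'
#' The motion-microscope measurement: builds a phase stack around `point`,
#' median-filters the unwrapped phase in time, solves the amplitude-weighted
#' least-squares phase-flow system at every pixel of the
#' `neighborhood x neighborhood` grid centered on the point, for every
#' frame, and averages the per-pixel displacements into a single trace.
#' The trace starts at exactly `(0, 0)`; frames where most pixels' systems
#' are singular are marked invalid rather than failing.
#'
#' The intended measurement point sits on high-contrast structure such as
#' the limbal edge (nasal to the pupil), but any point far enough from the
#' borders is accepted.
#'
#' @inheritParams csp_phase_stack
#' @param point `c(row, col)` measurement point, 1-based.
#' @param neighborhood Odd grid width averaged over (default 5).
#' @param median_window Odd temporal median window applied to unwrapped
#'   phase (default 3; 1 disables).
#' @param weight,levels Passed to the per-pixel solve; see
#'   [solve_displacement()].
#' @return An [okn_trace] tibble with columns `t_s`, `dx`, `dy`, `valid`;
#'   units `"px"`, source `"mmic"`.
#' @export
extract_point_trace <- function(video, bank, point, neighborhood = 5L,
                                median_window = 3L,
                                weight = c("coupled", "squared"),
                                levels = NULL, fps = NULL) {
  weight <- match.arg(weight)
  neighborhood <- as.integer(neighborhood)
  if (neighborhood %% 2L == 0L) stop("`neighborhood` must be odd")
  radius <- neighborhood %/% 2L
  stack <- csp_phase_stack(video, bank, center = point, radius = radius,
                           fps = fps)
  if (median_window > 1L) stack <- median_filter_phase(stack, median_window)

  nt <- dim(stack$phi)[1]
  w <- dim(stack$phi)[2]
  L <- dim(stack$phi)[4]
  sel <- levels %||% seq_len(L)
  npts <- w * w

  flat <- function(a) {
    m <- a[, , , sel, drop = FALSE]
    dim(m) <- c(nt * npts, length(sel))
    m
  }
  # trapezoidal gradients (see solve_displacement)
  gx_m <- (flat(stack$gx) + flat(stack$gx[rep(1, nt), , , , drop = FALSE])) / 2
  gy_m <- (flat(stack$gy) + flat(stack$gy[rep(1, nt), , , , drop = FALSE])) / 2
  dp_m <- flat(stack$phi) - flat(stack$phi[rep(1, nt), , , , drop = FALSE])
  w2_m <- if (weight == "coupled") {
    flat(stack$amp) * flat(stack$amp[rep(1, nt), , , , drop = FALSE])
  } else {
    flat(stack$amp)^2
  }
  bad_lvl <- !is.finite(gx_m) | !is.finite(gy_m) | !is.finite(dp_m)
  w2_m[bad_lvl] <- 0
  gx_m[bad_lvl] <- 0; gy_m[bad_lvl] <- 0; dp_m[bad_lvl] <- 0

  sxx <- rowSums(w2_m * gx_m^2)
  sxy <- rowSums(w2_m * gx_m * gy_m)
  syy <- rowSums(w2_m * gy_m^2)
  bx <- -rowSums(w2_m * gx_m * dp_m)
  by <- -rowSums(w2_m * gy_m * dp_m)
  det <- sxx * syy - sxy^2
  bad <- !is.finite(det) | det <= 1e-9 * (sxx + syy)^2 | (sxx + syy) == 0
  dx <- (syy * bx - sxy * by) / det
  dy <- (sxx * by - sxy * bx) / det
  dx[bad] <- NA_real_; dy[bad] <- NA_real_
  dim(dx) <- dim(dy) <- c(nt, npts)

  n_ok <- rowSums(!is.na(dx))
  valid <- n_ok >= max(1, ceiling(npts / 2))
  dx_t <- ifelse(valid, rowMeans(dx, na.rm = TRUE), NA_real_)
  dy_t <- ifelse(valid, rowMeans(dy, na.rm = TRUE), NA_real_)

  okn_trace(stack$t_s, dx_t, dy_t, valid = valid,
            units = "px", source = "mmic", fps = stack$fps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
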