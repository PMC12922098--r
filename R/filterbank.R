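#' Complex steerable pyramid filter bank
#'
#' Constructs the frequency-domain masks of a complex steerable pyramid
#' (CSP): a self-inverting set of oriented band-pass windows plus high- and
#' low-pass residuals.  Each band-pass mask selects a polar region of
#' frequency space (one radial octave times one orientation window) on a
#' single half-plane; the conjugate half-plane is zeroed, which is what makes
#' the spatial sub-bands complex and gives access to local amplitude and
#' phase.
#'
#' Radial windows are raised-cosine transitions in `log2` radial frequency
#' (one octave wide, full-octave spacing); angular windows are
#' `cos^(n_orientations - 1)` in orientation, normalised so that the squared
#' masks tile: at every non-DC frequency sample of the covered half-plane,
#' `hipass^2 + lopass^2 + sum_l mask_l^2 == 1` to floating precision.
#' Orientation is treated with period pi and all oriented masks share the
#' half-plane `wy > 0 | (wy == 0 & wx > 0)`.  DC and the Nyquist ring belong
#' entirely to the residual masks.
#'
#' @param image_shape Integer vector `c(rows, cols)` of the frames the bank
#'   will be applied to; both dimensions must be at least 16.
#' @param n_scales Number of radial octaves (spatial scales), >= 1.  Limited
#'   by the grid: `min(image_shape)` must be at least `2^(n_scales + 2)` so
#'   the smallest annulus still contains frequency samples.
#' @param n_orientations Number of orientation bands, >= 1.
#'
#' @return An object of class `csp_bank`: a list with `image_shape`,
#'   `n_scales`, `n_orientations`, `masks` (list of `n_scales *
#'   n_orientations` real non-negative matrices, scale-major order),
#'   `hipass`/`lopass` residual masks, `halfplane` (logical matrix of covered
#'   samples) and `levels`, a tibble of per-level metadata (scale,
#'   orientation index, orientation angle in radians, radial pass-band).
#'
#' @examples
#' bank <- csp_filter_bank(c(64, 64), n_scales = 2, n_orientations = 4)
#' length(bank$masks)   # 8 band-pass levels
#' bank$levels
#' @seealso [csp_decompose()], [extract_point_trace()]
#' @export
csp_filter_bank <- function(image_shape, n_scales = 5, n_orientations = 4) {
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2L || any(image_shape < 16L)) {
    stop("`image_shape` must be two dimensions, each >= 16")
  }
  if (n_scales < 1L || n_orientations < 1L) {
    stop("`n_scales` and `n_orientations` must be >= 1")
  }
  max_scales <- floor(log2(min(image_shape))) - 2L
  if (n_scales > max_scales) {
    stop(sprintf(
      "frame %d x %d supports at most %d scales (requested %d)",
      image_shape[1], image_shape[2], max_scales, n_scales
    ))
  }

  nr <- image_shape[1]
  nc <- image_shape[2]
  wy <- fft_freqs(nr)
  wx <- fft_freqs(nc)
  WY <- matrix(wy, nr, nc)
  WX <- matrix(wx, nr, nc, byrow = TRUE)
  r <- sqrt(WX^2 + WY^2)
  theta <- atan2(WY, WX)
  halfplane <- WY > 0 | (WY == 0 & WX > 0)

  hipass <- radial_hi(r, pi)
  lopass <- radial_lo(r, pi / 2^n_scales)

  K <- n_orientations
  alpha <- 2^(K - 1) * factorial(K - 1) / sqrt(K * factorial(2 * K - 2))
  thetas <- (seq_len(K) - 1) * pi / K

  masks <- vector("list", n_scales * K)
  meta <- vector("list", n_scales * K)
  for (s in seq_len(n_scales)) {
    c_out <- pi / 2^(s - 1)
    c_in <- pi / 2^s
    radial <- radial_lo(r, c_out) * radial_hi(r, c_in)
    for (k in seq_len(K)) {
      ang <- alpha * abs(cos(theta - thetas[k]))^(K - 1)
      l <- (s - 1L) * K + k
      masks[[l]] <- radial * ang * halfplane
      meta[[l]] <- tibble::tibble(
        level = l, scale = s, orientation = k, theta = thetas[k],
        r_lo = c_in / 2, r_hi = c_out
      )
    }
  }

  structure(
    list(
      image_shape = image_shape,
      n_scales = as.integer(n_scales),
      n_orientations = as.integer(K),
      masks = masks,
      hipass = hipass,
      lopass = lopass,
      halfplane = halfplane,
      levels = dplyr::bind_rows(meta)
    ),
    class = "csp_bank"
  )
}

#' @export
print.csp_bank <- function(x, ...) {
  cat(sprintf(
    "<csp_bank> %d x %d px, %d scales x %d orientations = %d band-pass levels\n",
    x$image_shape[1], x$image_shape[2], x$n_scales, x$n_orientations,
    length(x$masks)
  ))
  invisible(x)
}

# Signed DFT angular frequencies (radians/sample); Nyquist mapped to +pi.
fft_freqs <- function(n) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  if (n %% 2 == 0) k[n / 2 + 1] <- n / 2
  2 * pi * k / n
}

# Raised-cosine (in log2 r) low-pass window with cutoff c: 1 below c/2,
# 0 above c.  Self-inverting pair with radial_hi: lo^2 + hi^2 == 1.
radial_lo <- function(r, c) {
  out <- matrix(0, nrow(r), ncol(r))
  out[r <= c / 2] <- 1
  tr <- r > c / 2 & r < c
  out[tr] <- cos(pi / 2 * log2(2 * r[tr] / c))
  out
}

radial_hi <- function(r, c) {
  sqrt(pmax(1 - radial_lo(r, c)^2, 0))
}

#' Decompose a frame into complex oriented sub-bands
#'
#' Multiplies the frame's discrete Fourier transform by each band-pass mask
#' of the bank and inverse-transforms, yielding one complex spatial image per
#' level whose modulus is the local amplitude and whose argument is the local
#' phase (wrapped to `(-pi, pi]`).
#'
#' @param frame Real-valued grayscale matrix matching `bank$image_shape`.
#' @param bank A [csp_filter_bank()] object.
#' @param residuals If `TRUE`, also return the (real) high- and low-pass
#'   residual images; these carry no orientation and are never used for
#'   displacement estimation.
#'
#' @return An object of class `csp_subbands`: list with `subbands` (list of
#'   complex matrices, one per level), `levels` (the bank's level metadata)
#'   and optionally `hipass`/`lopass` real images.
#'
#' @examples
#' bank <- csp_filter_bank(c(64, 64), 2, 4)
#' frame <- matrix(rnorm(64 * 64), 64)
#' sb <- csp_decompose(frame, bank)
#' amp <- Mod(sb$subbands[[1]])
#' phase <- Arg(sb$subbands[[1]])
#' @export
csp_decompose <- function(frame, bank, residuals = FALSE) {
  stopifnot(inherits(bank, "csp_bank"))
  if (!is.matrix(frame) || !all(dim(frame) == bank$image_shape)) {
    stop("`frame` must be a matrix matching bank$image_shape")
  }
  if (is.complex(frame)) stop("`frame` must be real-valued")
  n <- length(frame)
  F <- stats::fft(frame)
  sub <- lapply(bank$masks, function(m) stats::fft(F * m, inverse = TRUE) / n)
  out <- list(subbands = sub, levels = bank$levels)
  if (residuals) {
    out$hipass <- Re(stats::fft(F * bank$hipass, inverse = TRUE) / n)
    out$lopass <- Re(stats::fft(F * bank$lopass, inverse = TRUE) / n)
  }
  structure(out, class = "csp_subbands")
}

#' Numerical tiling check of a filter bank
#'
#' Computes `hipass^2 + lopass^2 + sum_l mask_l^2` over the half-plane the
#' oriented masks cover and returns the maximum absolute deviation from 1
#' over all covered non-DC samples.  By the self-inverting window design the
#' deviation is at floating precision.
#'
#' @param bank A `csp_bank`.
#' @return Maximum absolute deviation from unity (a single number).
#' @export
csp_tiling_deviation <- function(bank) {
  total <- bank$hipass^2 + bank$lopass^2
  for (m in bank$masks) total <- total + m^2
  sel <- bank$halfplane
  sel[1, 1] <- FALSE # DC
  max(abs(total[sel] - 1))
}
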