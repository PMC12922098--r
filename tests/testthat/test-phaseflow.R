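test_that("temporal unwrapping removes 2*pi jumps and keeps the first sample", {
  expect_equal(temporal_unwrap(c(0.1, 0.2, 0.3)), c(0.1, 0.2, 0.3))
  expect_equal(temporal_unwrap(c(3.0, -3.0)), c(3.0, 3.0 + (2 * pi - 6)))
  expect_equal(temporal_unwrap(rep(1.5, 10)), rep(1.5, 10))
  expect_error(temporal_unwrap(numeric()), "empty")
  # property: output - input is a multiple of 2*pi; diffs wrapped
  set.seed(1)
  for (i in 1:20) {
    x <- oknflow:::wrap_pm_pi(cumsum(stats::rnorm(50, sd = 2)))
    u <- temporal_unwrap(x)
    expect_equal((u - x) / (2 * pi), round((u - x) / (2 * pi)),
                 tolerance = 1e-9)
    expect_true(all(diff(u) > -pi & diff(u) <= pi + 1e-12))
    expect_equal(u[1], x[1])
  }
})

test_that("median filtering is the identity at window 1, removes spikes, keeps monotone series", {
  vid <- shifted_texture_video(0.2, n_frames = 9)
  stack <- csp_phase_stack(vid, test_bank_64(), c(32, 32), radius = 2)
  expect_identical(median_filter_phase(stack, 1)$phi, stack$phi)
  expect_error(median_filter_phase(stack, 4), "odd")

  # spike in a linear series at one pixel/level is removed (window 3)
  spiked <- stack
  spiked$phi[, , , ] <- 0
  lin <- seq(0, 2, length.out = 9)
  for (t in 1:9) spiked$phi[t, , , ] <- lin[t]
  spiked$phi[5, 3, 3, 1] <- lin[5] + 3
  filt <- median_filter_phase(spiked, 3)
  # sliding-median oracle: med(lin[4], spike, lin[6]) = lin[6] = 1.25
  expect_equal(filt$phi[5, 3, 3, 1], 1.25, tolerance = 1e-9)
  # monotone series stay monotone
  expect_true(all(diff(filt$phi[, 2, 2, 2]) >= 0))
})

test_that("phase deltas vanish at the reference frame and track pure shifts", {
  vid <- shifted_texture_video(0.3, n_frames = 5)
  stack <- csp_phase_stack(vid, test_bank_64(), c(32, 32), radius = 2)
  expect_true(all(phase_delta(stack, 1) == 0))
  expect_error(phase_delta(stack, 99), "out of range")
  # delta approx -gx * delta at well-weighted pixels (FFT shift oracle)
  d3 <- phase_delta(stack, 3)
  pred <- -stack$gx[3, , , ] * 0.3
  amp <- stack$amp[1, , , ]
  strong <- amp > stats::quantile(amp, 0.75)
  expect_lt(stats::median(abs(d3[strong] - pred[strong])), 0.02)
})

test_that("the per-pixel solve reproduces constructed systems exactly", {
  # synthetic stack: 3 levels with known gradients, consistent deltas
  gx <- c(2, 1, 0); gy <- c(0, 0, 1.5)
  d_true <- c(0.3, 0)
  phi <- array(0, c(2, 3, 3, 3))
  for (l in 1:3) phi[2, , , l] <- -(gx[l] * d_true[1] + gy[l] * d_true[2])
  stack <- structure(list(
    phi_wrapped = array(0, c(2, 3, 3, 3)),
    phi = phi,
    amp = array(1, c(2, 3, 3, 3)),
    gx = array(rep(gx, each = 2 * 9), c(2, 3, 3, 3)),
    gy = array(rep(gy, each = 2 * 9), c(2, 3, 3, 3)),
    t_s = c(0, 1), fps = 1, rows = 1:3, cols = 1:3,
    levels = NULL
  ), class = "phase_stack")
  d <- solve_displacement(stack, c(2, 2), 2)
  expect_equal(unname(d), d_true, tolerance = 1e-12)
  # two orthogonal levels: equals the hand-computed 2x2 inverse
  d2 <- solve_displacement(stack, c(2, 2), 2, levels = c(1, 3))
  expect_equal(unname(d2), c(0.3, 0), tolerance = 1e-12)
  # one orientation only: rank 1 < 2 -> singularity error naming the pixel
  expect_error(solve_displacement(stack, c(2, 2), 2, levels = c(1, 2)),
               "singular.*\\(2, 2\\)")
})

test_that("point traces recover known sub-pixel shifts within oracle bands", {
  bank <- test_bank_64()
  for (delta in c(0.3, 0.05)) {
    tr <- extract_point_trace(shifted_texture_video(delta), bank, c(32, 32))
    expect_equal(tr$dx[1], 0)
    expect_equal(tr$dy[1], 0)
    est <- mean(tr$dx[-1])
    expect_lt(abs(est - delta) / delta, 0.1)
    expect_lt(max(abs(tr$dy[-1])), 0.05)
  }
  # sinusoidal translation, amplitude 0.01 px, 40 frames
  tex <- synth_texture(c(64, 64), seed = 7) * 30 + 128
  wfm <- 0.01 * sin(2 * pi * (0:39) / 10)
  v <- array(0, c(64, 64, 40))
  for (t in 1:40) v[, , t] <- oknflow:::fft_shift_image(tex, wfm[t])
  tr <- extract_point_trace(okn_video(v, 25), bank, c(32, 32))
  expect_lt(abs(max(abs(tr$dx)) - 0.01) / 0.01, 0.25)
})

test_that("a static video yields an identically zero trace", {
  tex <- synth_texture(c(64, 64), seed = 2) * 30 + 128
  v <- array(rep(tex, 4), c(64, 64, 4))
  tr <- extract_point_trace(okn_video(v, 25), test_bank_64(), c(32, 32))
  expect_true(all(tr$dx == 0))
  expect_true(all(tr$dy == 0))
  expect_true(all(tr$valid))
})

test_that("small-amplitude estimates are linear in the true shift", {
  bank <- test_bank_64()
  est <- vapply(c(0.1, 0.2), function(d) {
    mean(extract_point_trace(shifted_texture_video(d), bank, c(32, 32))$dx[-1])
  }, numeric(1))
  expect_lt(abs(est[2] / est[1] - 2), 0.05 * 2)
})

test_that("no temporal differencing: dropping an interior frame only changes that sample", {
  # constant shift, no median filter: displacement at each frame depends
  # only on that frame and the reference
  bank <- test_bank_64()
  vid <- shifted_texture_video(0.2, n_frames = 6)
  a <- oknflow:::as_video_array(vid)
  tr_full <- extract_point_trace(okn_video(a, 25), bank, c(32, 32),
                                 median_window = 1)
  a_drop <- a[, , -4]
  tr_drop <- extract_point_trace(okn_video(a_drop, 25), bank, c(32, 32),
                                 median_window = 1)
  expect_equal(tr_drop$dx, tr_full$dx[-4], tolerance = 1e-10)
})

test_that("borders and inputs are validated", {
  bank <- test_bank_64()
  vid <- shifted_texture_video(0.1, n_frames = 3)
  expect_error(extract_point_trace(vid, bank, c(2, 2)), "border")
  expect_error(extract_point_trace(vid, bank, c(32, 32), neighborhood = 4),
               "odd")
  one <- okn_video(array(0, c(64, 64, 1)), 25)
  expect_error(csp_phase_stack(one, bank, c(32, 32)), "2 frames")
})

test_that("traces survive a CSV round trip", {
  tr <- extract_point_trace(shifted_texture_video(0.3), test_bank_64(),
                            c(32, 32))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, path, notes = c(point = "32,32"))
  tr2 <- read_trace_csv(path)
  expect_equal(tr2$dx, tr$dx, tolerance = 1e-12)
  expect_equal(attr(tr2, "units"), "px")
  expect_equal(attr(tr2, "source"), "mmic")
})
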