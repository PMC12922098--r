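test_that("a dark disk yields one near-circular candidate at its center", {
  frame <- disk_frame(center = c(96, 96), radius = 20)
  cand <- segment_pupil_candidates(frame, disk_config())
  expect_equal(nrow(cand), 1)
  expect_lt(abs(cand$cx - 96), 0.5)
  expect_lt(abs(cand$cy - 96), 0.5)
  expect_gt(cand$circularity, 0.9)
  expect_equal(cand$eq_diameter, 40, tolerance = 0.05)
})

test_that("convex-hull closing restores a notched disk", {
  frame <- disk_frame(center = c(96, 96), radius = 20)
  # bite a notch out of the disk
  notch <- (row(frame) - 96)^2 + (col(frame) - 110)^2 <= 100
  frame[notch] <- 220
  cand <- segment_pupil_candidates(frame, disk_config())
  expect_equal(nrow(cand), 1)
  expect_gt(cand$circularity, 0.85)
  # hull area close to the full disk's
  expect_gt(cand$area, 0.9 * pi * 20^2)
})

test_that("uniform or hole-punctured frames behave", {
  cfg <- disk_config()
  expect_equal(nrow(segment_pupil_candidates(matrix(220, 192, 192), cfg)), 0)
  # bright hole inside the pupil is filled by the hull
  frame <- disk_frame()
  frame[(row(frame) - 96)^2 + (col(frame) - 96)^2 <= 16] <- 220
  cand <- segment_pupil_candidates(frame, cfg)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$area, 1257, tolerance = 0.03)
})

test_that("selection takes the largest consistent candidate", {
  cfg <- disk_config()
  two <- tibble::tibble(
    cx = c(50, 120), cy = c(50, 120), area = c(900, 400),
    eq_diameter = sqrt(4 * c(900, 400) / pi), circularity = c(0.95, 0.95)
  )
  prev <- list(cx = 60, cy = 60)
  # both within a huge radius: larger area wins
  big_cfg <- tracker_config(intensity_threshold = 50,
                            diameter_range = c(10, 80),
                            consistency_radius = 500)
  est <- select_pupil(two, prev, big_cfg)
  expect_true(est$valid)
  expect_equal(est$area, 900)
  # candidate 50 px away with radius 15 -> missing
  one <- two[2, ]
  est2 <- select_pupil(one, list(cx = 85, cy = 120), cfg)
  expect_false(est2$valid)
  expect_true(is.na(est2$cx))
  # empty set -> invalid
  est3 <- select_pupil(two[0, ], NULL, cfg)
  expect_false(est3$valid)
})

test_that("clean eye video tracking recovers the commanded sawtooth", {
  # 192 px study geometry; 2 deg at 6 px/deg = 12 px peak-to-peak sawtooth
  r <- rendered_eye(amplitude = 2, beat = 1.3, seed = 11, size = 192)
  pt <- track_pupil(r$video, small_tracker(192))
  expect_equal(pt$loss_fraction, 0)
  expect_false(pt$low_data)
  err <- abs(pt$trace$dx - (r$truth_px - r$truth_px[1]))
  expect_lt(max(err, na.rm = TRUE), 0.5)
})

test_that("occluders produce missing frames and the low-data classification", {
  r <- rendered_eye(occluder = "shadow", occluder_fraction = 0.4, seed = 12)
  pt <- track_pupil(r$video, small_tracker())
  expect_equal(pt$loss_fraction, 0.4, tolerance = 0.02)
  expect_true(pt$low_data)
  # the missing frames are the occluded ones
  expect_true(all(!pt$estimates$valid[r$occluded]))
})

test_that("the low-data rule is a strict 30% inequality", {
  # 20-frame video, exactly 6 occluded -> loss exactly 0.30
  spec <- okn_trial_spec(fps = 30, seed = 13, occluder = "shadow",
                         occluder_fraction = 0.3)
  r <- render_eye_video(spec, waveform_px = rep(0, 20), size = 64,
                        camera_noise_sd = 0)
  expect_equal(sum(r$occluded), 6)
  pt <- track_pupil(r$video, small_tracker())
  expect_equal(pt$loss_fraction, 0.3)
  expect_false(pt$low_data)
})

test_that("tracking is translation-equivariant for integer shifts", {
  r <- rendered_eye(amplitude = 1, beat = 1, seed = 14, camera_noise_sd = 0)
  a <- oknflow:::as_video_array(r$video)[, , 1:20]
  roll <- function(m, by, dim) {
    idx <- ((seq_len(dim(m)[dim]) - by - 1) %% dim(m)[dim]) + 1
    if (dim == 1) m[idx, , , drop = FALSE] else m[, idx, , drop = FALSE]
  }
  shifted <- roll(roll(a, 3, 1), 5, 2)
  cfg <- small_tracker()
  e1 <- track_pupil(okn_video(a, 30), cfg)$estimates
  e2 <- track_pupil(okn_video(shifted, 30), cfg)$estimates
  expect_equal(e2$cx, e1$cx + 5, tolerance = 1e-9)
  expect_equal(e2$cy, e1$cy + 3, tolerance = 1e-9)
})

test_that("raising the intensity threshold never shrinks the thresholded set", {
  r <- rendered_eye(seed = 15)
  fr <- oknflow:::as_video_array(r$video)[, , 1]
  for (th in c(40, 60, 80)) {
    low <- fr < th
    high <- fr < th + 20
    expect_true(all(high[low]))
  }
  # and the pupil candidate's area is non-decreasing on the disk fixture
  areas <- vapply(c(40, 50, 60), function(th) {
    cfg <- tracker_config(intensity_threshold = th,
                          diameter_range = c(10, 80))
    segment_pupil_candidates(disk_frame(), cfg)$area[1]
  }, numeric(1))
  expect_true(all(diff(areas) >= 0))
})

test_that("tracking is deterministic", {
  r <- rendered_eye(seed = 16)
  cfg <- small_tracker()
  t1 <- track_pupil(r$video, cfg)
  t2 <- track_pupil(r$video, cfg)
  expect_identical(t1$trace$dx, t2$trace$dx)
  expect_identical(t1$loss_fraction, t2$loss_fraction)
})

test_that("a video with no detectable pupil is fully lost", {
  v <- okn_video(array(220, c(64, 64, 10)), 30)
  pt <- track_pupil(v, small_tracker())
  expect_equal(pt$loss_fraction, 1)
  expect_true(pt$low_data)
  expect_true(all(!pt$trace$valid))
})
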