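test_that("a clean rightward sawtooth train is detected in full", {
  p <- okn_params("gaze")
  tr <- sawtooth_trace(onsets = seq(0, 7, by = 0.8), dir = +1, fs = 200,
                       noise_sd = 0.02)
  ev <- detect_sawteeth(tr, +1, p)
  expect_equal(nrow(ev), 9)
  expect_true(all(ev$direction == 1))
  expect_true(all(diff(ev$onset_s) > 0))
  expect_true(all(ev$onset_s < ev$peak_s & ev$peak_s < ev$end_s))
  expect_true(all(sign(ev$sp_velocity) == ev$direction))
  expect_equal(ev$sp_duration, ev$peak_s - ev$onset_s, tolerance = 1e-9)
  expect_true(okn_trial_decision(ev, p))
  # the same trace tested against the wrong direction yields nothing
  expect_equal(nrow(detect_sawteeth(tr, -1, p)), 0)
})

test_that("sub-threshold noise is rejected", {
  p <- okn_params("gaze")
  set.seed(5)
  flat <- okn_trace(seq(0, 8, by = 1 / 200), rnorm(1601, sd = 0.05),
                    units = "deg", fps = 200)
  expect_equal(nrow(detect_sawteeth(flat, +1, p)), 0)
  expect_false(detect_okn(flat, "none", p))
})

test_that("trial criteria: 2 consecutive or 3 isolated sawteeth", {
  p <- okn_params("gaze")
  ev <- function(onsets, width = 0.65) {
    tibble::tibble(onset_s = onsets, peak_s = onsets + 0.5,
                   end_s = onsets + width)
  }
  expect_true(okn_trial_decision(ev(c(1.0, 1.7)), p))       # gap 0.05
  expect_true(okn_trial_decision(ev(c(0.5, 3, 6)), p))      # 3 isolated
  expect_false(okn_trial_decision(ev(c(1, 5)), p))          # 2 isolated
  expect_false(okn_trial_decision(ev(numeric(0)), p))
  # boundary: gap exactly at consecutive_gap_max counts as consecutive
  expect_true(okn_trial_decision(ev(c(1, 1 + 0.65 + p$consecutive_gap_max)),
                                 p))
})

test_that("detected sawteeth satisfy the trial criteria end to end", {
  p <- okn_params("gaze")
  # two consecutive sawteeth, then silence
  two <- sawtooth_trace(onsets = c(1, 1.65), fs = 200, noise_sd = 0.02)
  ev2 <- detect_sawteeth(two, +1, p)
  expect_equal(nrow(ev2), 2)
  expect_true(okn_trial_decision(ev2, p))
  # three isolated
  three <- sawtooth_trace(onsets = c(0.5, 3, 6), fs = 200, noise_sd = 0.02)
  ev3 <- detect_sawteeth(three, +1, p)
  expect_equal(nrow(ev3), 3)
  expect_true(okn_trial_decision(ev3, p))
  # two isolated
  iso <- sawtooth_trace(onsets = c(1, 5), fs = 200, noise_sd = 0.02)
  evi <- detect_sawteeth(iso, +1, p)
  expect_equal(nrow(evi), 2)
  expect_false(okn_trial_decision(evi, p))
})

test_that("no-stimulus trials are tested in both directions", {
  p <- okn_params("gaze")
  left <- sawtooth_trace(onsets = seq(0, 7, by = 0.8), dir = -1, fs = 200,
                         noise_sd = 0.02)
  right <- sawtooth_trace(onsets = seq(0, 7, by = 0.8), dir = +1, fs = 200,
                          noise_sd = 0.02)
  expect_true(detect_both_directions(left, p))
  expect_true(detect_both_directions(right, p))
  expect_true(detect_okn(left, "none", p))
  expect_error(detect_sawteeth(left, "none", p), "both")
})

test_that("reversing the trace swaps the detecting direction", {
  p <- okn_params("gaze")
  tr <- sawtooth_trace(onsets = seq(0, 7, by = 0.8), dir = +1, fs = 200,
                       noise_sd = 0.02)
  rev_tr <- okn_trace(tr$t_s, -tr$dx, units = "deg", fps = 200)
  expect_gt(nrow(detect_sawteeth(tr, +1, p)), 0)
  expect_equal(nrow(detect_sawteeth(rev_tr, +1, p)), 0)
  expect_equal(nrow(detect_sawteeth(rev_tr, -1, p)),
               nrow(detect_sawteeth(tr, +1, p)))
})

test_that("scaling a detected trace up never reduces the event count", {
  p <- okn_params("gaze")
  tr <- sawtooth_trace(onsets = seq(0, 7, by = 1), amp = 1, fs = 200,
                       noise_sd = 0.02)
  n0 <- nrow(detect_sawteeth(tr, +1, p))
  expect_gt(n0, 0)
  for (k in c(1.5, 3, 8)) {
    scaled <- okn_trace(tr$t_s, tr$dx * k, units = "deg", fps = 200)
    expect_gte(nrow(detect_sawteeth(scaled, +1, p)), n0)
  }
})

test_that("gaps inside a quick phase do not create spurious slow-phase events", {
  p <- okn_params("gaze")
  tr <- sawtooth_trace(onsets = seq(0, 7, by = 0.8), fs = 200,
                       noise_sd = 0.02)
  n0 <- nrow(detect_sawteeth(tr, +1, p))
  # invalidate samples inside the third quick phase (t in [2.1, 2.17])
  bad <- tr$t_s >= 2.1 & tr$t_s <= 2.17
  tr$valid[bad] <- FALSE
  tr$dx[bad] <- NA
  n1 <- nrow(detect_sawteeth(tr, +1, p))
  expect_lte(n1, n0)
  expect_true(okn_trial_decision(detect_sawteeth(tr, +1, p), p))
})

test_that("eye combination is an OR with single-eye fallback", {
  expect_true(combine_eyes(FALSE, TRUE))
  expect_true(combine_eyes(TRUE, FALSE))
  expect_false(combine_eyes(FALSE, FALSE))
  expect_false(combine_eyes(FALSE, NA))
  expect_true(combine_eyes(NA, TRUE))
  expect_error(combine_eyes(NA, NA), "both eyes")
})

test_that("the STEP multiplexer follows the gaze flag", {
  expect_true(step_combine(TRUE, FALSE))
  expect_true(step_combine(TRUE, TRUE))
  expect_true(step_combine(FALSE, TRUE))
  expect_false(step_combine(FALSE, FALSE))
  # dominance: STEP output is exactly gaze OR video
  for (g in c(TRUE, FALSE)) for (v in c(TRUE, FALSE)) {
    expect_equal(step_combine(g, v), g || v)
    expect_gte(step_combine(g, v), g)
  }
})

test_that("detector parameters are validated and presets are distinct", {
  expect_error(okn_params("gaze", nonsense = 1), "unknown")
  expect_error(okn_params("gaze", min_sp_amplitude = -1))
  pg <- okn_params("gaze")
  pv <- okn_params("video")
  expect_false(identical(pg, pv))
  expect_equal(pg$preset, "gaze")
  over <- okn_params("video", min_sp_amplitude = 2.5)
  expect_equal(over$min_sp_amplitude, 2.5)
})
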