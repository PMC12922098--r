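# Shared fixtures: everything is generated in code at test time.

# Standard noiseless texture video: frame 1 unshifted, later frames shifted
# by a constant sub-pixel amount (FFT shift theorem = ground truth).
shifted_texture_video <- function(delta, n_frames = 4, size = 64, seed = 7,
                                  fps = 25) {
  tex <- synth_texture(c(size, size), seed = seed) * 30 + 128
  v <- array(0, c(size, size, n_frames))
  v[, , 1] <- tex
  for (t in 2:n_frames) v[, , t] <- oknflow:::fft_shift_image(tex, delta)
  okn_video(v, fps)
}

test_bank_64 <- local({
  bank <- NULL
  function() {
    if (is.null(bank)) bank <<- csp_filter_bank(c(64, 64), 3, 4)
    bank
  }
})

# Bright frame with a dark disk (sub-pixel center via soft edge).
disk_frame <- function(size = 192, center = c(96, 96), radius = 20,
                       dark = 30, bright = 220, edge = 0.8) {
  r <- sqrt((row(matrix(0, size, size)) - center[1])^2 +
              (col(matrix(0, size, size)) - center[2])^2)
  bright + (dark - bright) / (1 + exp((r - radius) / edge))
}

# Threshold at the disk's half-intensity (125 between 30 and 220) so the
# binary boundary sits at the nominal radius.
disk_config <- function() {
  tracker_config(intensity_threshold = 125, diameter_range = c(10, 80),
                 circularity_min = 0.65, consistency_radius = 15)
}

# Ideal sawtooth displacement trace with events at given onsets.
# Each sawtooth: ramp of `amp` over sp_dur in `dir`, reset over qp_dur.
sawtooth_trace <- function(onsets, amp = 2, sp_dur = 0.5, qp_dur = 0.15,
                           dir = +1, fs = 50, duration = 8, noise_sd = 0,
                           seed = 1) {
  set.seed(seed)
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  x <- numeric(length(t))
  for (on in onsets) {
    sp <- t >= on & t < on + sp_dur
    x[sp] <- x[sp] + dir * amp * (t[sp] - on) / sp_dur
    qp <- t >= on + sp_dur & t < on + sp_dur + qp_dur
    x[qp] <- x[qp] + dir * amp * (1 - (t[qp] - on - sp_dur) / qp_dur)
  }
  okn_trace(t, x + stats::rnorm(length(t), sd = noise_sd),
            units = "deg", source = "gaze", fps = fs)
}

# Small clean rendered eye video plus its commanded waveform (px).
rendered_eye <- function(amplitude = 2, beat = 1.3, seed = 11, size = 64,
                         fps = 30, occluder = "none", occluder_fraction = 0,
                         direction = "right", camera_noise_sd = 1.5) {
  spec <- okn_trial_spec(
    stimulus_direction = direction, amplitude = amplitude,
    beat_frequency = beat, fps = fps, seed = seed,
    occluder = occluder, occluder_fraction = occluder_fraction
  )
  wf <- okn_waveform(spec, fs = fps)
  px_per_deg <- 6 * size / 192
  r <- render_eye_video(spec, waveform_px = wf$trace$dx * px_per_deg,
                        size = size, px_per_deg = px_per_deg,
                        camera_noise_sd = camera_noise_sd)
  r$spec <- spec
  r
}

small_tracker <- function(size = 64) {
  tracker_config(intensity_threshold = 50,
                 diameter_range = c(0.08 * size, 0.45 * size),
                 consistency_radius = max(8, 0.08 * size))
}
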