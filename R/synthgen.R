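#' Band-limited random texture
#'
#' Seeded noise texture whose spectrum is confined to an annulus of radial
#' frequencies, guaranteeing band-pass spectral content at every orientation
#' (used as the standard phase-flow test fixture and as iris texture).
#' The texture is periodic, so FFT-based sub-pixel shifting wraps seamlessly.
#'
#' @param shape `c(rows, cols)`.
#' @param seed Integer seed.
#' @param r_range Radial pass-band in radians/sample.
#' @return Matrix with zero mean and unit variance.
#' @export
synth_texture <- function(shape, seed = 1L, r_range = c(pi / 8, pi / 2)) {
  set.seed(seed)
  nr <- shape[1]; nc <- shape[2]
  wy <- matrix(fft_freqs(nr), nr, nc)
  wx <- matrix(fft_freqs(nc), nr, nc, byrow = TRUE)
  r <- sqrt(wx^2 + wy^2)
  keep <- r >= r_range[1] & r <= r_range[2]
  spec <- stats::fft(matrix(stats::rnorm(nr * nc), nr, nc)) * keep
  tex <- Re(stats::fft(spec, inverse = TRUE)) / (nr * nc)
  (tex - mean(tex)) / stats::sd(tex)
}

# Sub-pixel circular shift of a matrix via the FFT shift theorem; content
# moves by +dx columns (rightward) and +dy rows (downward).
fft_shift_image <- function(img, dx, dy = 0) {
  nr <- nrow(img); nc <- ncol(img)
  wy <- matrix(fft_freqs(nr), nr, nc)
  wx <- matrix(fft_freqs(nc), nr, nc, byrow = TRUE)
  Re(stats::fft(stats::fft(img) * exp(-1i * (wx * dx + wy * dy)),
                inverse = TRUE)) / (nr * nc)
}

#' Specification of one synthetic trial
#'
#' Collects the ground-truth parameters of a simulated 8 s OKN trial:
#' stimulus direction, whether an OKN response is present, its sawtooth
#' shape (amplitude, beat frequency, quick-phase duration), noise levels
#' and an occluder schedule for the rendered eye video.
#'
#' @param duration Trial length in seconds (default 8, the stimulus
#'   presentation time).
#' @param stimulus_direction `"left"`, `"right"` or `"none"`.
#' @param okn_present Ground-truth response flag; must be `FALSE` when
#'   `stimulus_direction == "none"` is combined with `okn_present = TRUE`
#'   only through `response_direction`.
#' @param amplitude Slow-phase amplitude (degrees for gaze, converted to px
#'   at render time).
#' @param beat_frequency Sawtooth repetition rate in Hz.
#' @param qp_duration Quick-phase duration in seconds.
#' @param noise_sd Additive Gaussian noise on the ground-truth waveform
#'   (trace units).
#' @param gaze_noise_sd Extra noise on the simulated eye-tracker gaze.
#' @param gaze_gain Multiplier applied to the gaze rendering of the
#'   waveform; values well below 1 emulate the poorly resolved small-OKN
#'   regime in which the tracker under-reports the eye movement.
#' @param occluder `"none"`, `"eyelash"` or `"shadow"`.
#' @param occluder_fraction Fraction of frames occluded (contiguous block in
#'   the middle of the trial).
#' @param fps Video frame rate (Hz); gaze is always sampled at 200 Hz.
#' @param seed Integer seed for this trial's randomness.
#' @return A list of class `okn_trial_spec`.
#' @export
okn_trial_spec <- function(duration = 8, stimulus_direction = "right",
                           okn_present = TRUE, amplitude = 2,
                           beat_frequency = 1.2, qp_duration = 0.15,
                           noise_sd = 0.05, gaze_noise_sd = 0.1,
                           gaze_gain = 1, occluder = "none",
                           occluder_fraction = 0, fps = 200, seed = 1L) {
  stopifnot(duration > 0, beat_frequency > 0, qp_duration > 0,
            qp_duration < 1 / beat_frequency)
  stimulus_direction <- match.arg(stimulus_direction,
                                  c("left", "right", "none"))
  occluder <- match.arg(occluder, c("none", "eyelash", "shadow"))
  structure(
    list(
      duration = duration, stimulus_direction = stimulus_direction,
      okn_present = okn_present, amplitude = amplitude,
      beat_frequency = beat_frequency, qp_duration = qp_duration,
      noise_sd = noise_sd, gaze_noise_sd = gaze_noise_sd,
      gaze_gain = gaze_gain, occluder = occluder,
      occluder_fraction = occluder_fraction, fps = fps,
      seed = as.integer(seed)
    ),
    class = "okn_trial_spec"
  )
}

dir_sign <- function(direction) {
  switch(direction, right = 1, left = -1,
         stop("direction must be 'left' or 'right'"))
}

#' Ground-truth sawtooth waveform for a trial
#'
#' Generates the ideal eye-displacement waveform of an OKN response: slow
#' ramps of the given amplitude in the stimulus direction followed by quick
#' resets in the opposite direction, repeated at the beat frequency, plus
#' additive Gaussian noise.  When `okn_present` is `FALSE` the trace is
#' drift-free noise.  The true sawtooth event times are returned alongside.
#'
#' @param spec An [okn_trial_spec()].
#' @param fs Sampling rate of the generated trace (defaults to `spec$fps`).
#' @return List with `trace` (an [okn_trace()], units `"deg"`, source
#'   `"truth"`) and `events` (tibble of true `onset_s`, `peak_s`, `end_s`,
#'   `direction` for each complete sawtooth; empty when absent).
#' @examples
#' wf <- okn_waveform(okn_trial_spec(amplitude = 1, beat_frequency = 1.8))
#' nrow(wf$events)   # floor(1.8 * 8) complete sawteeth
#' @export
okn_waveform <- function(spec, fs = NULL) {
  stopifnot(inherits(spec, "okn_trial_spec"))
  fs <- fs %||% spec$fps
  set.seed(spec$seed)
  t <- seq(0, spec$duration, by = 1 / fs)
  t <- t[t < spec$duration]
  noise <- stats::rnorm(length(t), sd = spec$noise_sd)

  if (!spec$okn_present) {
    tr <- okn_trace(t, noise, 0, units = "deg", source = "truth", fps = fs)
    return(list(trace = tr, events = empty_events()))
  }
  if (spec$stimulus_direction == "none") {
    stop("okn_present requires a stimulus direction (left or right)")
  }
  s <- dir_sign(spec$stimulus_direction)
  P <- 1 / spec$beat_frequency
  sp_dur <- P - spec$qp_duration
  ph <- t %% P
  x <- ifelse(ph < sp_dur,
              spec$amplitude * ph / sp_dur,
              spec$amplitude * (1 - (ph - sp_dur) / spec$qp_duration))
  x <- s * (x - spec$amplitude / 2)
  n_complete <- floor(spec$duration / P)
  onsets <- (seq_len(n_complete) - 1) * P
  events <- tibble::tibble(
    onset_s = onsets, peak_s = onsets + sp_dur, end_s = onsets + P,
    direction = s
  )
  tr <- okn_trace(t, x + noise, 0, units = "deg", source = "truth", fps = fs)
  list(trace = tr, events = events)
}

empty_events <- function() {
  tibble::tibble(onset_s = numeric(), peak_s = numeric(), end_s = numeric(),
                 direction = numeric())
}

#' Simulated eye-tracker gaze trace
#'
#' The ground-truth waveform as the eye tracker would report it: sampled at
#' 200 Hz in degrees, scaled by `gaze_gain` (small gains emulate the
#' under-resolved small-OKN failure mode of the tracker) and carrying the
#' tracker's own measurement noise.
#'
#' @param spec An [okn_trial_spec()].
#' @return An [okn_trace()], units `"deg"`, source `"gaze"`.
#' @export
simulate_gaze <- function(spec) {
  wf <- okn_waveform(spec, fs = 200)
  set.seed(spec$seed + 1L)
  noise <- stats::rnorm(nrow(wf$trace), sd = spec$gaze_noise_sd)
  okn_trace(wf$trace$t_s, wf$trace$dx * spec$gaze_gain + noise, 0,
            units = "deg", source = "gaze", fps = 200)
}

#' Render a synthetic single-eye video
#'
#' Draws a schematic infrared eye image - bright sclera, band-limited
#' textured iris, dark pupil, all with smooth edges - and translates it
#' horizontally per the waveform with exact FFT sub-pixel interpolation.
#' Optional occluders reproduce the documented centroid-tracking failure
#' modes: `"eyelash"` bars covering the pupil, and a `"shadow"` channel of
#' dark pixels linking the pupil to the frame border so that threshold
#' segmentation merges it with the background.
#'
#' The degree-to-pixel scale defaults to `6 * size / 192` px/deg, the
#' nominal eye-camera geometry scaled with the rendered frame.
#'
#' @param spec An [okn_trial_spec()].
#' @param waveform_px Optional displacement vector in px (one per frame);
#'   derived from [okn_waveform()] via `px_per_deg` when omitted.
#' @param size Frame side in px (default 192).
#' @param px_per_deg Degree-to-pixel conversion.
#' @param pupil_radius,iris_radius Geometry in px (defaults scale with
#'   `size`).
#' @param camera_noise_sd Per-frame sensor noise (grayscale units).
#' @return List with `video` (an [okn_video()]), `truth_px` (commanded
#'   per-frame displacement), `occluded` (logical per frame) and the
#'   geometry (`center`, `pupil_radius`, `iris_radius`, `px_per_deg`).
#' @export
render_eye_video <- function(spec, waveform_px = NULL, size = 192,
                             px_per_deg = 6 * size / 192,
                             pupil_radius = round(0.12 * size),
                             iris_radius = round(0.36 * size),
                             camera_noise_sd = 1.5) {
  stopifnot(inherits(spec, "okn_trial_spec"))
  if (is.null(waveform_px)) {
    wf <- okn_waveform(spec, fs = spec$fps)
    waveform_px <- wf$trace$dx * px_per_deg
  }
  margin <- size / 2 - iris_radius - 4
  if (max(abs(waveform_px)) > margin) {
    stop("waveform exceeds frame bounds for this eye geometry")
  }
  nt <- length(waveform_px)

  # static eye image, periodic iris texture, smooth (logistic) edges
  set.seed(spec$seed + 2L)
  ctr <- (size + 1) / 2
  xs <- matrix(seq_len(size), size, size, byrow = TRUE) - ctr
  ys <- matrix(seq_len(size), size, size) - ctr
  r <- sqrt(xs^2 + ys^2)
  soft <- function(r0, w = 1.5) 1 / (1 + exp((r - r0) / w))
  tex <- synth_texture(c(size, size), seed = spec$seed + 3L)
  img <- 220 +
    (140 + 35 * tex - 220) * soft(iris_radius) +
    (30 - 140 - 35 * tex) * soft(pupil_radius)

  occluded <- rep(FALSE, nt)
  if (spec$occluder != "none" && spec$occluder_fraction > 0) {
    n_occ <- min(nt, ceiling(spec$occluder_fraction * nt))
    start <- max(2L, floor((nt - n_occ) / 2) + 1L)
    occluded[start:(start + n_occ - 1L)] <- TRUE
  }

  F0 <- stats::fft(img)
  wx <- matrix(fft_freqs(size), size, size, byrow = TRUE)
  set.seed(spec$seed + 4L)
  frames <- array(0, c(size, size, nt))
  ri <- round(ctr); ci <- round(ctr)
  for (t in seq_len(nt)) {
    fr <- Re(stats::fft(F0 * exp(-1i * wx * waveform_px[t]),
                        inverse = TRUE)) / size^2
    if (occluded[t]) {
      if (spec$occluder == "eyelash") {
        # dark lash bars sweeping down over the pupil
        for (off in c(-8, 0, 8)) {
          cols <- pmax(1, pmin(size, ci + off + (-1:1)))
          fr[1:(ri + pupil_radius), cols] <- 25
        }
      } else {
        # dark channel from the pupil to the frame border
        rows <- pmax(1, pmin(size, ri + (-2:2)))
        fr[rows, 1:ci] <- pmin(fr[rows, 1:ci], 40)
      }
    }
    if (camera_noise_sd > 0) {
      fr <- fr + stats::rnorm(size^2, sd = camera_noise_sd)
    }
    frames[, , t] <- fr
  }
  list(
    video = okn_video(frames, spec$fps),
    truth_px = waveform_px, occluded = occluded,
    center = c(ctr, ctr), pupil_radius = pupil_radius,
    iris_radius = iris_radius, px_per_deg = px_per_deg
  )
}

#' Generate a seeded trial set with ground truth
#'
#' Builds the per-trial specifications of a simulated study: each
#' participant views trials at decreasing stimulus visibility (logMAR 0.5,
#' 0.3, 0.1 and a no-stimulus condition, three repeats each by default) with
#' the stimulus direction randomized left/right per trial.  Visibility maps
#' to the synthetic response: full responses at 0.5/0.3, partial (smaller,
#' faster, sometimes absent) responses at 0.1, and no response for
#' no-stimulus trials.  A fraction of the present trials has the gaze
#' rendering attenuated, emulating the under-resolved-OKN failure mode that
#' video-based methods are meant to remediate; selected participants'
#' videos carry occluders.  The mapping from visibility to response is
#' synthetic by construction and makes no claim of modeling human
#' psychometrics.
#'
#' @param n_participants,trials_per_participant Study size; trials cycle
#'   through the visibility levels in blocks.
#' @param seed Master seed; all per-trial seeds derive from it.
#' @param fps Video frame rate for rendering.
#' @param p_attenuated_gaze Fraction of OKN-present trials whose gaze
#'   rendering is attenuated (gain `attenuated_gain`).
#' @param attenuated_gain Gaze gain of attenuated trials.
#' @param occluded_participants Integer ids whose videos get a `"shadow"`
#'   occluder over 40% of frames.
#' @param p_present_low Probability that a lowest-visibility (logMAR 0.1)
#'   trial evokes a response.
#' @return A tibble, one row per trial: `participant`, `trial`, `logmar`
#'   (`NA` for no-stimulus), `stimulus_direction`, `okn_present` (truth
#'   label), waveform parameters, `gaze_gain`, occluder columns and `seed`.
#' @export
okn_trial_set <- function(n_participants, trials_per_participant = 12,
                          seed = 1L, fps = 200,
                          p_attenuated_gaze = 0.2, attenuated_gain = 0.1,
                          occluded_participants = integer(),
                          p_present_low = 0.6) {
  stopifnot(n_participants >= 1, trials_per_participant >= 1)
  set.seed(seed)
  levels <- c(0.5, 0.3, 0.1, NA)
  amp_map <- c(`0.5` = 3, `0.3` = 2, `0.1` = 1)
  freq_map <- list(`0.5` = c(0.8, 1.2), `0.3` = c(1.0, 1.5),
                   `0.1` = c(1.4, 1.8))

  grid <- tidyr::expand_grid(
    participant = seq_len(n_participants),
    trial = seq_len(trials_per_participant)
  )
  n <- nrow(grid)
  logmar <- levels[((grid$trial - 1) %/% 3) %% 4 + 1]
  direction <- ifelse(is.na(logmar), "none",
                      sample(c("left", "right"), n, replace = TRUE))
  present <- !is.na(logmar) &
    (logmar > 0.1 | stats::runif(n) < p_present_low)
  amplitude <- ifelse(present, amp_map[as.character(logmar)], 0)
  beat <- vapply(seq_len(n), function(i) {
    if (!present[i]) return(1.2)
    rng <- freq_map[[as.character(logmar[i])]]
    stats::runif(1, rng[1], rng[2])
  }, numeric(1))
  gaze_gain <- ifelse(present & stats::runif(n) < p_attenuated_gaze,
                      attenuated_gain, 1)
  occluded <- grid$participant %in% occluded_participants
  tibble::tibble(
    participant = grid$participant, trial = grid$trial,
    logmar = logmar, stimulus_direction = direction,
    okn_present = present, amplitude = amplitude, beat_frequency = beat,
    gaze_gain = gaze_gain,
    occluder = ifelse(occluded, "shadow", "none"),
    occluder_fraction = ifelse(occluded, 0.4, 0),
    fps = fps,
    seed = (as.integer(seed) * 10007L + seq_len(n)) %% .Machine$integer.max
  )
}

# One trial-set row -> okn_trial_spec
trial_row_spec <- function(row) {
  okn_trial_spec(
    duration = 8, stimulus_direction = row$stimulus_direction,
    okn_present = row$okn_present,
    amplitude = if (row$okn_present) row$amplitude else 0,
    beat_frequency = row$beat_frequency,
    gaze_gain = row$gaze_gain, occluder = row$occluder,
    occluder_fraction = row$occluder_fraction,
    fps = row$fps, seed = row$seed
  )
}
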