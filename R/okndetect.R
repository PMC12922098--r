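#' OKN detector parameters
#'
#' Thresholds and smoothing settings of the sawtooth detector.  Two named
#' presets mirror the two signal families: `"gaze"` (angular units, 200 Hz
#' eye-tracker traces) and `"video"` (pixel units, camera-frame-rate traces
#' from centroid tracking or phase flow).  The preset values were fixed
#' empirically on the synthetic generator and are deliberately exposed:
#' real recordings may need retuning, particularly the video preset, whose
#' pixel units depend on camera distance and eye geometry.
#'
#' @param preset `"gaze"` or `"video"`.
#' @param ... Named overrides of individual fields: `min_sp_amplitude`
#'   (trace units), `sp_duration` (`c(min, max)` seconds),
#'   `sp_velocity` (`c(min, max)` units/s, magnitudes),
#'   `qp_velocity_min` (units/s), `smooth_window_s` (Savitzky-Golay window,
#'   seconds), `min_run_s` (velocity sign-runs shorter than this merge into
#'   their neighbor), `consecutive_gap_max` (max end-to-onset gap in
#'   seconds for two sawteeth to count as consecutive).
#' @return A list of class `okn_params`.
#' @export
okn_params <- function(preset = c("gaze", "video"), ...) {
  preset <- match.arg(preset)
  p <- switch(preset,
    gaze = list(
      min_sp_amplitude = 0.3, sp_duration = c(0.15, 2),
      sp_velocity = c(1, 20), qp_velocity_min = 2.5,
      smooth_window_s = 0.125, min_run_s = 0.05,
      consecutive_gap_max = 0.2
    ),
    video = list(
      min_sp_amplitude = 0.8, sp_duration = c(0.15, 2),
      sp_velocity = c(1.5, 60), qp_velocity_min = 3,
      smooth_window_s = 0.15, min_run_s = 0.05,
      consecutive_gap_max = 0.2
    )
  )
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p[names(over)] <- over
  stopifnot(
    p$min_sp_amplitude > 0, all(p$sp_duration > 0),
    p$sp_duration[1] < p$sp_duration[2],
    p$sp_velocity[1] < p$sp_velocity[2], p$qp_velocity_min > 0,
    p$smooth_window_s > 0, p$consecutive_gap_max >= 0
  )
  structure(c(p, list(preset = preset)), class = "okn_params")
}

# Savitzky-Golay smoothed position and velocity of one gap-free segment.
sg_smooth_velocity <- function(x, fs, window_s) {
  n <- max(5L, round(window_s * fs))
  if (n %% 2 == 0) n <- n + 1L
  n <- min(n, if (length(x) %% 2 == 0) length(x) - 1 else length(x))
  if (n < 5 || length(x) <= n) {
    return(list(xs = x, v = c(diff(x), NA) * fs))
  }
  xs <- signal::sgolayfilt(x, p = 2, n = n)
  v <- signal::sgolayfilt(x, p = 2, n = n, m = 1, ts = 1 / fs)
  list(xs = xs, v = v)
}

# Merge velocity sign-runs shorter than min_len into the preceding run.
merged_sign_runs <- function(sgn, min_len) {
  r <- rle(sgn)
  if (length(r$lengths) > 1) {
    repeat {
      short <- which(r$lengths < min_len)
      short <- short[short > 1]
      if (length(short) == 0) break
      i <- short[1]
      r$values[i] <- r$values[i - 1]
      r <- rle(inverse.rle(r))
    }
  }
  ends <- cumsum(r$lengths)
  tibble::tibble(
    value = r$values,
    start = ends - r$lengths + 1L,
    end = ends
  )
}

#' Detect sawtooth OKN events in a displacement trace
#'
#' Looks for the defining OKN signature: a slow ramp in the known stimulus
#' direction immediately followed by a quick reset in the opposite
#' direction.  The trace is smoothed (Savitzky-Golay), velocity-sign runs
#' are segmented (gaps in the trace break runs), slow/quick run pairs become
#' candidate sawteeth with onset, peak and end points, and each candidate is
#' tested for consistency (slow phase longer than quick phase, quick phase
#' faster than slow phase) and thresholded on amplitude, duration and
#' velocity.
#'
#' @param trace An [okn_trace()] (or tibble with `t_s`, `dx`, `valid`).
#' @param stimulus_direction `+1`/"right" or `-1`/"left"; for no-stimulus
#'   trials use [detect_both_directions()].
#' @param params An [okn_params()].
#' @return Tibble of time-ordered, non-overlapping events: `onset_s`,
#'   `peak_s`, `end_s`, `sp_amplitude`, `sp_duration`, `sp_velocity`
#'   (signed), `qp_duration`, `qp_velocity`, `direction`.
#' @export
detect_sawteeth <- function(trace, stimulus_direction, params = okn_params()) {
  stopifnot(inherits(params, "okn_params"))
  s <- if (is.character(stimulus_direction)) {
    switch(stimulus_direction, right = 1, left = -1, 0)
  } else {
    stimulus_direction
  }
  if (!isTRUE(s %in% c(-1, 1))) {
    stop("stimulus_direction must be left/right; use detect_both_directions() ",
         "for no-stimulus trials")
  }
  x <- trace$dx
  tt <- trace$t_s
  ok <- (trace$valid %||% TRUE) & !is.na(x)
  if (sum(ok) < 2) stop("trace has fewer than 2 valid samples")
  fs <- trace_fps(trace)
  min_run <- max(2L, round(params$min_run_s * fs))

  segs <- split(which(ok), cumsum(!ok)[ok])
  events <- lapply(segs, function(idx) {
    if (length(idx) < 2 * min_run) return(NULL)
    sv <- sg_smooth_velocity(x[idx], fs, params$smooth_window_s)
    runs <- merged_sign_runs(sign(sv$v), min_run)
    runs <- runs[runs$value %in% c(-1, 1), , drop = FALSE]
    if (nrow(runs) < 2) return(NULL)
    out <- list()
    for (i in seq_len(nrow(runs) - 1)) {
      if (runs$value[i] != s || runs$value[i + 1] != -s) next
      onset <- idx[runs$start[i]]
      peak <- idx[runs$end[i]]
      # the reset ends at its displacement extremum: a slow wander of the
      # velocity sign after the quick phase must not stretch it
      qspan <- runs$start[i + 1]:runs$end[i + 1]
      qrel <- if (s > 0) which.min(sv$xs[qspan]) else which.max(sv$xs[qspan])
      qend <- idx[qspan[qrel]]
      sp_dur <- tt[peak] - tt[onset]
      qp_dur <- tt[qend] - tt[peak]
      if (sp_dur <= 0 || qp_dur <= 0) next
      sp_amp <- abs(sv$xs[runs$end[i]] - sv$xs[runs$start[i]])
      qp_amp <- abs(sv$xs[qspan[qrel]] - sv$xs[runs$end[i]])
      sp_vel <- sp_amp / sp_dur
      qp_vel <- qp_amp / qp_dur
      consistent <- sp_dur > qp_dur && qp_vel > sp_vel
      valid <- consistent &&
        sp_amp >= params$min_sp_amplitude &&
        sp_dur >= params$sp_duration[1] && sp_dur <= params$sp_duration[2] &&
        sp_vel >= params$sp_velocity[1] && sp_vel <= params$sp_velocity[2] &&
        qp_vel >= params$qp_velocity_min
      if (valid) {
        out[[length(out) + 1]] <- tibble::tibble(
          onset_s = tt[onset], peak_s = tt[peak], end_s = tt[qend],
          sp_amplitude = sp_amp, sp_duration = sp_dur,
          sp_velocity = s * sp_vel, qp_duration = qp_dur,
          qp_velocity = qp_vel, direction = s
        )
      }
    }
    dplyr::bind_rows(out)
  })
  ev <- dplyr::bind_rows(events)
  if (nrow(ev) == 0) {
    return(tibble::tibble(
      onset_s = numeric(), peak_s = numeric(), end_s = numeric(),
      sp_amplitude = numeric(), sp_duration = numeric(),
      sp_velocity = numeric(), qp_duration = numeric(),
      qp_velocity = numeric(), direction = numeric()
    ))
  }
  dplyr::arrange(ev, .data$onset_s)
}

#' Per-trial OKN decision from detected events
#'
#' OKN is signaled in a trial if two or more sawteeth are consecutive (the
#' end of one within `consecutive_gap_max` of the onset of the next -
#' repeating OKN), or if three or more isolated sawteeth occur anywhere in
#' the trial.
#'
#' @param events Time-ordered events from [detect_sawteeth()].
#' @param params An [okn_params()].
#' @return `TRUE` (present) or `FALSE` (absent).
#' @export
okn_trial_decision <- function(events, params = okn_params()) {
  n <- nrow(events)
  if (n == 0) return(FALSE)
  if (n >= 3) return(TRUE)
  if (n >= 2) {
    gaps <- events$onset_s[-1] - events$end_s[-n]
    if (any(gaps <= params$consecutive_gap_max)) return(TRUE)
  }
  FALSE
}

#' OKN decision when the stimulus direction is unknown
#'
#' No-stimulus trials have no defined OKN direction, so the detector runs
#' for both directions; the trial is positive if either direction yields a
#' positive decision.
#'
#' @inheritParams detect_sawteeth
#' @return `TRUE`/`FALSE`; the per-direction events are attached as
#'   attribute `"events"`.
#' @export
detect_both_directions <- function(trace, params = okn_params()) {
  ev_r <- detect_sawteeth(trace, +1, params)
  ev_l <- detect_sawteeth(trace, -1, params)
  res <- okn_trial_decision(ev_r, params) || okn_trial_decision(ev_l, params)
  structure(res, events = dplyr::bind_rows(ev_r, ev_l))
}

#' One-call trial detection
#'
#' Dispatches to [detect_sawteeth()] plus [okn_trial_decision()] for trials
#' with a known stimulus direction and to [detect_both_directions()] for
#' no-stimulus trials.
#'
#' @inheritParams detect_sawteeth
#' @param stimulus_direction `"left"`, `"right"` or `"none"`.
#' @return `TRUE`/`FALSE`.
#' @export
detect_okn <- function(trace, stimulus_direction, params = okn_params()) {
  if (identical(stimulus_direction, "none")) {
    as.logical(detect_both_directions(trace, params))
  } else {
    okn_trial_decision(
      detect_sawteeth(trace, stimulus_direction, params), params
    )
  }
}

#' Combine per-eye decisions into a trial decision
#'
#' Logical OR over the available eyes; if only one eye yielded data
#' (`NA` marks an unavailable eye), that eye alone decides.
#'
#' @param left,right Per-eye flags: `TRUE`, `FALSE` or `NA` (unavailable).
#' @return `TRUE`/`FALSE`.
#' @export
combine_eyes <- function(left, right) {
  if (is.na(left) && is.na(right)) {
    stop("both eyes unavailable; trial must be excluded upstream")
  }
  isTRUE(left) || isTRUE(right)
}

#' Two-stage (STEP) decision
#'
#' The serial remediation scheme: the gaze decision stands if positive;
#' only a negative gaze decision falls through to the video-derived
#' decision (a multiplexer driven by the gaze flag).
#'
#' @param gaze_flag,video_flag Logical decisions.
#' @return `TRUE`/`FALSE`.
#' @export
step_combine <- function(gaze_flag, video_flag) {
  stopifnot(!is.na(gaze_flag), !is.na(video_flag))
  if (gaze_flag) TRUE else video_flag
}
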