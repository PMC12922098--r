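#' Pipeline configuration
#'
#' Collects every knob of the end-to-end simulated study: rendering size
#' and rate, filter-bank geometry, tracker thresholds, detector presets and
#' the eyes to simulate.  Defaults follow the recorded study conditions
#' (192 px eye frames, 5 x 4 pyramid); smaller sizes scale the tracker and
#' renderer geometry proportionally.
#'
#' @param video_size Rendered eye frame side in px.
#' @param fps Video frame rate (Hz).
#' @param n_eyes 1 or 2 eyes per trial.
#' @param n_scales,n_orientations Filter-bank geometry.
#' @param tracker A [tracker_config()]; default scales with `video_size`.
#' @param params_gaze,params_video Detector presets ([okn_params()]).
#' @param neighborhood,median_window Phase-flow measurement settings.
#' @return A list of class `okn_pipeline_config`.
#' @export
okn_pipeline_config <- function(video_size = 192, fps = 30, n_eyes = 2,
                                n_scales = NULL, n_orientations = 4,
                                tracker = NULL,
                                params_gaze = okn_params("gaze"),
                                params_video = okn_params("video"),
                                neighborhood = 5, median_window = 3) {
  n_scales <- n_scales %||% min(5L, floor(log2(video_size)) - 2L)
  tracker <- tracker %||% tracker_config(
    intensity_threshold = 50,
    diameter_range = c(0.08 * video_size, 0.45 * video_size),
    consistency_radius = max(8, 0.08 * video_size)
  )
  structure(
    list(
      video_size = video_size, fps = fps, n_eyes = n_eyes,
      n_scales = n_scales, n_orientations = n_orientations,
      tracker = tracker, params_gaze = params_gaze,
      params_video = params_video, neighborhood = neighborhood,
      median_window = median_window
    ),
    class = "okn_pipeline_config"
  )
}

#' Process one eye video with both video methods
#'
#' Runs centroid tracking and the phase-flow measurement on a single-eye
#' video.  The phase-flow measurement point sits at the limbal edge nasal
#' to the pupil: the mean tracked pupil center offset horizontally by the
#' iris radius when centroid tracking produced data, else the frame center
#' with the same offset.
#'
#' @param video An [okn_video()].
#' @param bank A [csp_filter_bank()] matching the frames.
#' @param config An [okn_pipeline_config()].
#' @param limbal_offset_px Horizontal offset (px) from the pupil center to
#'   the measurement point; default 0.36 x frame size (the nominal iris
#'   radius).
#' @return List: `centroid` (a [track_pupil()] result), `mmic` (an
#'   [okn_trace()]), `point` used for the phase measurement.
#' @export
process_eye_video <- function(video, bank, config = okn_pipeline_config(),
                              limbal_offset_px = NULL) {
  a <- as_video_array(video)
  size <- dim(a)[1:2]
  limbal_offset_px <- limbal_offset_px %||% round(0.36 * size[2])
  ct <- track_pupil(video, config$tracker)
  ctr <- if (any(ct$estimates$valid)) {
    c(round(mean(ct$estimates$cy, na.rm = TRUE)),
      round(mean(ct$estimates$cx, na.rm = TRUE)))
  } else {
    round(size / 2)
  }
  margin <- config$neighborhood %/% 2 + 1
  point <- c(
    min(max(ctr[1], 1 + margin), size[1] - margin),
    min(max(ctr[2] - limbal_offset_px, 1 + margin), size[2] - margin)
  )
  mmic <- extract_point_trace(
    video, bank, point,
    neighborhood = config$neighborhood,
    median_window = config$median_window
  )
  list(centroid = ct, mmic = mmic, point = point)
}

#' Run the full simulated OKN study
#'
#' For every trial of a trial set (see [okn_trial_set()]): simulates the
#' eye-tracker gaze trace, renders the eye video(s), extracts centroid and
#' phase-flow displacement traces per eye, applies OKN detection (gaze
#' preset for the gaze signal, video preset for both video methods; trials
#' without a stimulus are tested in both directions), combines eyes by
#' logical OR (single available eye decides alone), and forms the two-stage
#' decisions C-STEP and MMIC-STEP.  Videos whose centroid tracking loses
#' more than 30% of frames are "low data": their trials form the retest
#' partition, where only the gaze and phase methods report.
#'
#' @param trials Tibble from [okn_trial_set()].
#' @param config An [okn_pipeline_config()].
#' @param verbose Print progress every 20 trials.
#' @return An object of class `okn_run`: list with `manifest` (one row per
#'   eye video: loss fraction, low-data flag, per-method eye decisions),
#'   `decisions` (one row per trial and method with the combined flag,
#'   truth and partition), `metrics` (per method and partition) and
#'   `errors` (per-trial failures; a failing trial is recorded and the run
#'   continues).
#' @export
run_okn_pipeline <- function(trials, config = okn_pipeline_config(),
                             verbose = FALSE) {
  stopifnot(inherits(config, "okn_pipeline_config"))
  size <- config$video_size
  bank <- csp_filter_bank(c(size, size), config$n_scales,
                          config$n_orientations)
  px_per_deg <- 6 * size / 192

  manifest <- list()
  decisions <- list()
  errors <- list()
  for (i in seq_len(nrow(trials))) {
    row <- trials[i, ]
    ok <- tryCatch({
      spec <- trial_row_spec(row)

      gaze <- simulate_gaze(spec)
    g_flag <- detect_okn(gaze, row$stimulus_direction, config$params_gaze)

    eye_c <- rep(NA, config$n_eyes)
    eye_m <- rep(NA, config$n_eyes)
    low <- rep(NA, config$n_eyes)
    loss <- rep(NA_real_, config$n_eyes)
    for (e in seq_len(config$n_eyes)) {
      espec <- spec
      espec$seed <- spec$seed + 101L * (e - 1L)
      wf <- okn_waveform(espec, fs = espec$fps)
      r <- render_eye_video(espec, waveform_px = wf$trace$dx * px_per_deg,
                            size = size, px_per_deg = px_per_deg)
      pe <- process_eye_video(r$video, bank, config)
      loss[e] <- pe$centroid$loss_fraction
      low[e] <- pe$centroid$low_data
      eye_c[e] <- if (pe$centroid$low_data) NA else {
        detect_okn(pe$centroid$trace, row$stimulus_direction,
                   config$params_video)
      }
      eye_m[e] <- detect_okn(pe$mmic, row$stimulus_direction,
                             config$params_video)
      manifest[[length(manifest) + 1]] <- tibble::tibble(
        participant = row$participant, trial = row$trial,
        eye = c("left", "right")[e],
        loss_fraction = loss[e], low_data = low[e],
        centroid_flag = eye_c[e], mmic_flag = eye_m[e]
      )
    }

    c_flag <- if (all(is.na(eye_c))) NA else combine_eyes(
      eye_c[1], if (config$n_eyes > 1) eye_c[2] else NA
    )
    m_flag <- combine_eyes(eye_m[1], if (config$n_eyes > 1) eye_m[2] else NA)
    partition <- if (any(low)) "retest" else "main"
    dec <- tibble::tibble(
      participant = row$participant, trial = row$trial,
      truth = row$okn_present, partition = partition,
      method = c("G", "C", "MMIC", "C-STEP", "MMIC-STEP"),
      flag = c(
        g_flag, c_flag, m_flag,
        if (is.na(c_flag)) NA else step_combine(g_flag, c_flag),
        step_combine(g_flag, m_flag)
      )
    )
      decisions[[i]] <- dec
      TRUE
    }, error = function(e) {
      errors[[length(errors) + 1]] <<- tibble::tibble(
        participant = row$participant, trial = row$trial,
        message = conditionMessage(e)
      )
      FALSE
    })
    if (verbose && i %% 20 == 0) {
      message(sprintf("trial %d / %d", i, nrow(trials)))
    }
  }
  manifest <- dplyr::bind_rows(manifest)
  decisions <- dplyr::bind_rows(decisions)
  structure(
    list(
      manifest = manifest, decisions = decisions,
      metrics = summarize_run_metrics(decisions),
      errors = dplyr::bind_rows(errors),
      config = config
    ),
    class = "okn_run"
  )
}

summarize_run_metrics <- function(decisions) {
  parts <- list(
    main = dplyr::filter(decisions, .data$partition == "main"),
    retest = dplyr::filter(decisions, .data$partition == "retest"),
    all = decisions
  )
  out <- purrr::imap(parts, function(d, part) {
    d <- dplyr::filter(d, !is.na(.data$flag))
    if (nrow(d) == 0) return(NULL)
    d |>
      dplyr::group_by(.data$method) |>
      dplyr::group_modify(~ okn_metrics(.x$flag, .x$truth)) |>
      dplyr::ungroup() |>
      dplyr::mutate(partition = part, .before = 1)
  })
  dplyr::bind_rows(out)
}

#' @export
print.okn_run <- function(x, ...) {
  cat(sprintf("<okn_run> %d trials (%d main, %d retest)\n",
              length(unique(paste(x$decisions$participant,
                                  x$decisions$trial))),
              sum(x$decisions$partition == "main") / 5,
              sum(x$decisions$partition == "retest") / 5))
  print(dplyr::filter(x$metrics, .data$partition == "main"))
  invisible(x)
}

#' @method tidy okn_run
#' @export
tidy.okn_run <- function(x, ...) x$decisions

#' @method glance okn_run
#' @export
glance.okn_run <- function(x, ...) {
  dplyr::filter(x$metrics, .data$partition == "main")
}
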