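#' Read and write pipeline configuration as YAML
#'
#' Serializes an [okn_pipeline_config()] (including the tracker
#' configuration and both detector presets) so that a study configuration
#' travels with its results.
#'
#' @param config An [okn_pipeline_config()].
#' @param path File path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "okn_pipeline_config"))
  x <- unclass(config)
  x$tracker <- unclass(x$tracker)
  x$params_gaze <- unclass(x$params_gaze)
  x$params_video <- unclass(x$params_video)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  tr <- x$tracker
  pg <- x$params_gaze
  pv <- x$params_video
  okn_pipeline_config(
    video_size = x$video_size, fps = x$fps, n_eyes = x$n_eyes,
    n_scales = x$n_scales, n_orientations = x$n_orientations,
    tracker = tracker_config(
      roi = unlist(tr$roi), intensity_threshold = tr$intensity_threshold,
      diameter_range = unlist(tr$diameter_range),
      circularity_min = tr$circularity_min,
      consistency_radius = tr$consistency_radius
    ),
    params_gaze = do.call(okn_params, c(
      list(preset = pg$preset),
      purrr::map(pg[setdiff(names(pg), "preset")], unlist)
    )),
    params_video = do.call(okn_params, c(
      list(preset = pv$preset),
      purrr::map(pv[setdiff(names(pv), "preset")], unlist)
    )),
    neighborhood = x$neighborhood, median_window = x$median_window
  )
}
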