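#' Displacement trace
#'
#' The common 1-D eye-displacement format shared by the gaze signal and both
#' video-derived methods: a tibble with time `t_s` (seconds, strictly
#' increasing), horizontal and vertical displacement `dx`/`dy` relative to
#' the start of the trace, and a `valid` flag marking usable samples
#' (missing samples keep their row with `NA` displacement).  Units (`"px"`
#' or `"deg"`), source (`"gaze"`, `"centroid"`, `"mmic"`, `"truth"`) and the
#' sampling rate travel as attributes.
#'
#' @param t_s Time axis in seconds.
#' @param dx,dy Displacement; `dy` defaults to zero.
#' @param valid Logical; defaults to `!is.na(dx)`.
#' @param units `"px"` or `"deg"`.
#' @param source Short tag naming the extraction method.
#' @param fps Sampling rate in Hz.
#' @return A tibble of class `okn_trace`.
#' @export
okn_trace <- function(t_s, dx, dy = 0, valid = NULL, units = "px",
                      source = "gaze", fps = NULL) {
  if (is.unsorted(t_s, strictly = TRUE)) stop("`t_s` must be strictly increasing")
  tr <- tibble::tibble(
    t_s = as.numeric(t_s),
    dx = as.numeric(dx),
    dy = rep_len(as.numeric(dy), length(t_s)),
    valid = valid %||% !is.na(dx)
  )
  fps <- fps %||% (1 / stats::median(diff(t_s)))
  structure(tr,
    units = units, source = source, fps = fps,
    class = c("okn_trace", class(tr))
  )
}

trace_fps <- function(trace) {
  attr(trace, "fps") %||% (1 / stats::median(diff(trace$t_s)))
}

#' Write or read a displacement trace as CSV
#'
#' Columns `t_s, dx_px, dy_px, valid` (or `_deg` for angular traces) plus
#' `source`; metadata (units, source, sampling rate, free-form notes such as
#' bank parameters and measurement point) is kept in `#`-prefixed header
#' comment lines.
#'
#' @param trace An [okn_trace()].
#' @param path File path.
#' @param notes Optional named character vector added to the header.
#' @export
write_trace_csv <- function(trace, path, notes = NULL) {
  units <- attr(trace, "units") %||% "px"
  hdr <- c(
    sprintf("# units: %s", units),
    sprintf("# source: %s", attr(trace, "source") %||% "unknown"),
    sprintf("# fps: %g", trace_fps(trace)),
    if (!is.null(notes)) sprintf("# %s: %s", names(notes), notes)
  )
  df <- data.frame(
    t_s = trace$t_s, dx = trace$dx, dy = trace$dy,
    valid = as.integer(trace$valid),
    source = attr(trace, "source") %||% "unknown"
  )
  names(df)[2:3] <- paste0(c("dx_", "dy_"), units)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    if (length(m)) trimws(sub(sprintf("^# %s:", key), "", m[1])) else NA
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  units <- get("units"); if (is.na(units)) units <- "px"
  okn_trace(df$t_s, df[[paste0("dx_", units)]], df[[paste0("dy_", units)]],
            valid = df$valid == 1, units = units,
            source = get("source"),
            fps = suppressWarnings(as.numeric(get("fps"))))
}
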