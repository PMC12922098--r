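#' Grayscale video container
#'
#' A minimal in-memory video: a numeric array `rows x cols x frames` with a
#' frame rate.  Pixel values are grayscale intensities on a 0-255 scale.
#'
#' @param frames Numeric 3-D array `rows x cols x frames`.
#' @param fps Frame rate in Hz.
#' @return An `okn_video` object.
#' @export
okn_video <- function(frames, fps) {
  stopifnot(is.array(frames), length(dim(frames)) == 3, fps > 0)
  structure(frames, fps = as.numeric(fps), class = "okn_video")
}

#' @export
print.okn_video <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<okn_video> %d x %d px, %d frames @ %g fps (%.2f s)\n",
              d[1], d[2], d[3], attr(x, "fps"), d[3] / attr(x, "fps")))
  invisible(x)
}

as_video_array <- function(v) {
  if (inherits(v, "okn_video")) {
    a <- unclass(v)
    attr(a, "fps") <- NULL
    a
  } else if (is.array(v) && length(dim(v)) == 3) {
    v
  } else {
    stop("expected an okn_video or a 3-D array")
  }
}

video_fps <- function(v, fps = NULL) {
  fps %||% attr(v, "fps") %||% stop("frame rate unknown; supply `fps`")
}

#' Join and split side-by-side two-eye frames
#'
#' Eye-camera recordings carry both eyes in one frame, left and right halves.
#' `side_by_side()` joins two single-eye videos into that layout;
#' `split_side_by_side()` cuts a two-eye video back into per-eye videos.
#' By convention (configurable) the left half of the frame is the left eye.
#'
#' @param left,right Single-eye [okn_video()]s with equal dimensions.
#' @return `side_by_side()`: one video of doubled width.
#' @export
side_by_side <- function(left, right) {
  la <- as_video_array(left); ra <- as_video_array(right)
  stopifnot(all(dim(la) == dim(ra)))
  d <- dim(la)
  out <- array(0, c(d[1], 2 * d[2], d[3]))
  out[, 1:d[2], ] <- la
  out[, (d[2] + 1):(2 * d[2]), ] <- ra
  okn_video(out, video_fps(left))
}

#' @rdname side_by_side
#' @param video A two-eye video with even frame width.
#' @param left_first If `TRUE` (default) the left half of the frame is the
#'   left eye.
#' @return `split_side_by_side()`: named list `left`, `right` of videos of
#'   half width.
#' @export
split_side_by_side <- function(video, left_first = TRUE) {
  a <- as_video_array(video)
  nc <- dim(a)[2]
  if (nc %% 2 != 0) stop("frame width must be even to split")
  fps <- video_fps(video)
  h1 <- okn_video(a[, 1:(nc / 2), , drop = FALSE], fps)
  h2 <- okn_video(a[, (nc / 2 + 1):nc, , drop = FALSE], fps)
  if (left_first) list(left = h1, right = h2) else list(left = h2, right = h1)
}

#' Read and write videos as multi-frame TIFF stacks
#'
#' Frame-stack TIFF is used as the on-disk container (grayscale, one TIFF
#' directory per frame).  The frame rate is not stored by TIFF and must be
#' given again on read.
#'
#' @param video An [okn_video()].
#' @param path File path.
#' @export
write_video_tiff <- function(video, path) {
  a <- as_video_array(video)
  img <- EBImage::Image(aperm(a, c(2, 1, 3)) / 255)
  EBImage::writeImage(img, path, type = "tiff")
  invisible(path)
}

#' @rdname write_video_tiff
#' @param fps Frame rate of the stored video.
#' @export
read_video_tiff <- function(path, fps) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2) dim(a) <- c(dim(a), 1)
  okn_video(aperm(a, c(2, 1, 3)) * 255, fps)
}
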