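#' Video sequence container
#'
#' A stack of RGB frames with a frame rate. Intensities live in [0, 1].
#'
#' @param frames numeric array `[T, H, W, 3]` (a `[T, H, W]` array is
#'   promoted to gray RGB).
#' @param fps frame rate in Hz.
#' @return An object of class `"video_sequence"`.
#' @export
video_sequence <- function(frames, fps) {
  d <- dim(frames)
  if (length(d) == 3L) {
    frames <- array(rep(frames, 3L), c(d, 3L))
    d <- dim(frames)
  }
  if (length(d) != 4L || d[4L] != 3L)
    stop("`frames` must be [T, H, W, 3] (or [T, H, W] grayscale)")
  if (d[1L] < 2L) stop("a video needs at least 2 frames")
  if (!all(is.finite(frames))) stop("frame intensities must be finite")
  stopifnot(fps > 0)
  structure(list(frames = frames, fps = as.numeric(fps)),
            class = "video_sequence")
}

#' @export
print.video_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<video_sequence> %d frames of %dx%d @ %g fps\n",
              d[1L], d[2L], d[3L], x$fps))
  invisible(x)
}

# NTSC YIQ transform; the inverse is the numeric inverse of the forward
# matrix so the round trip is exact to machine precision.
.yiq_fwd <- matrix(c(0.299,  0.587,  0.114,
                     0.596, -0.274, -0.322,
                     0.211, -0.523,  0.312), 3L, 3L, byrow = TRUE)
.yiq_inv <- solve(.yiq_fwd)

#' RGB / YIQ color conversion
#'
#' Standard NTSC luminance-chrominance transform; motion processing is
#' applied on the Y channel. The inverse uses the exact numeric inverse of
#' the forward matrix, so a round trip is identity to better than 1e-6.
#'
#' @param video a [video_sequence()] (either color space).
#' @param direction `"to_yiq"` or `"to_rgb"`.
#' @return a [video_sequence()] in the target space (YIQ values are stored
#'   in the same array slots; I and Q may be negative).
#' @export
color_convert <- function(video, direction = c("to_yiq", "to_rgb")) {
  stopifnot(inherits(video, "video_sequence"))
  direction <- match.arg(direction)
  M <- if (direction == "to_yiq") .yiq_fwd else .yiq_inv
  d <- dim(video$frames)
  flat <- matrix(video$frames, ncol = 3L)      # [T*H*W, 3]
  out <- array(flat %*% t(M), d)
  v <- video
  v$frames <- out
  v
}

#' Read / write a video as a directory of numbered PNG frames
#'
#' Deterministic interchange format used throughout: frames are written as
#' `frame_000001.png` etc. (8-bit; quantization is 1/255 of full scale, well
#' below the motion amplitudes of interest).
#'
#' @param dir directory path.
#' @param video a [video_sequence()] (values clipped to [0, 1] on write).
#' @param fps frame rate to attach on read.
#' @return `read_video_png` returns a [video_sequence()];
#'   `write_video_png` returns `dir` invisibly.
#' @export
read_video_png <- function(dir, fps) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) < 2L) stop("no frame PNGs found in ", dir)
  first <- png::readPNG(files[1L])
  if (length(dim(first)) == 2L) dim(first) <- c(dim(first), 1L)
  H <- dim(first)[1L]; W <- dim(first)[2L]
  frames <- array(0, c(length(files), H, W, 3L))
  for (t in seq_along(files)) {
    im <- png::readPNG(files[t])
    if (length(dim(im)) == 2L) im <- array(rep(im, 3L), c(H, W, 3L))
    frames[t, , , ] <- im[, , 1:3]
  }
  video_sequence(frames, fps)
}

#' @rdname read_video_png
#' @export
write_video_png <- function(video, dir) {
  stopifnot(inherits(video, "video_sequence"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  T_ <- dim(video$frames)[1L]
  for (t in seq_len(T_)) {
    fr <- video$frames[t, , , ]
    fr <- pmin(pmax(fr, 0), 1)
    png::writePNG(fr, file.path(dir, sprintf("frame_%06d.png", t)),
                  dpi = NULL)
  }
  invisible(dir)
}
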