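#' Spatial signature of a frame
#'
#' Realizes a frame as a pair of one-dimensional mass distributions: the
#' intensity-weighted column marginal and row marginal, each normalized to
#' unit mass. Unlike an intensity histogram this signature is
#' translation-sensitive, so transporting mass between two frames'
#' signatures measures spatial motion, and the 1-D transport problems are
#' linear-time in the frame dimensions.
#'
#' @param frame numeric matrix of nonnegative intensities (a grayscale or
#'   luminance image), not all zero.
#' @return list of class `"frame_signature"` with `col` and `row`, each a
#'   list of `pos` (pixel positions) and `mass` (nonnegative, summing
#'   to 1).
#' @export
frame_signature <- function(frame) {
  frame <- as.matrix(frame)
  if (any(frame < 0)) stop("frame intensities must be nonnegative")
  tot <- sum(frame)
  if (tot == 0) stop("all-zero frame has no signature")
  structure(list(
    col = list(pos = seq_len(ncol(frame)), mass = colSums(frame) / tot),
    row = list(pos = seq_len(nrow(frame)), mass = rowSums(frame) / tot)),
    class = "frame_signature")
}

#' Exact one-dimensional earth mover's distance
#'
#' For two distributions on a common ordered support the optimal transport
#' cost under |x - y| ground distance has the closed form
#' `sum |CDF_p - CDF_q| * binwidth`; this equals the linear-programming
#' transportation optimum and is a metric.
#'
#' @param p,q lists with `pos` (common, increasing) and `mass` (nonnegative,
#'   equal totals within 1e-6).
#' @return transport distance in position units (pixels).
#' @export
emd_1d <- function(p, q) {
  if (length(p$pos) != length(q$pos) || any(p$pos != q$pos))
    stop("`p` and `q` must share a common support")
  if (abs(sum(p$mass) - sum(q$mass)) > 1e-6)
    stop("mass mismatch between the two distributions")
  n <- length(p$pos)
  if (n < 2L) return(0)
  dcdf <- cumsum(p$mass - q$mass)[-n]
  sum(abs(dcdf) * diff(p$pos))
}

#' Temporal earth mover's distance motion series
#'
#' Global-motion metric of a clip: per frame, the 1-D earth mover's
#' distances of its column and row luminance marginals to those of the
#' first frame are summed, giving a displacement-like scalar in pixels.
#' The series starts at exactly 0 and feeds directly into [besct()] /
#' [analyze_signal()] as an ordinary sampled signal.
#'
#' @param video a [video_sequence()], or a numeric array `[T, H, W]` of
#'   luminance frames.
#' @param fps frame rate in Hz when `video` is a bare array.
#' @return a [time_series()] (`fs` = frame rate) of EMOD values in pixels.
#' @export
emod_series <- function(video, fps = NULL) {
  lum <- video_luminance(video)
  if (inherits(video, "video_sequence")) fps <- video$fps
  if (is.null(fps)) stop("`fps` required for a bare frame array")
  T_ <- dim(lum)[1L]
  if (T_ < 2L) stop("need at least 2 frames")
  ref <- frame_signature(lum[1L, , ])
  d <- vapply(seq_len(T_), function(t) {
    sig <- frame_signature(lum[t, , ])
    emd_1d(sig$col, ref$col) + emd_1d(sig$row, ref$row)
  }, numeric(1))
  d[1L] <- 0
  time_series(d, fs = fps, start_time = 0)
}

# luminance [T, H, W] from a video_sequence or pass-through array
video_luminance <- function(video) {
  if (inherits(video, "video_sequence")) {
    yiq <- color_convert(video, "to_yiq")
    yiq$frames[, , , 1L]
  } else {
    v <- unclass(video)
    stopifnot(length(dim(v)) == 3L)
    v
  }
}
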