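#' Frequency-domain complex steerable pyramid filters
#'
#' Builds the polar-separable frequency masks of an undecimated complex
#' steerable pyramid with octave-bandwidth radial filters and `K` angular
#' bands: a high-pass residual, per-level oriented band masks supported on
#' a half-plane wedge (their image-domain responses are complex, with phase
#' encoding local translation), and a low-pass residual. The squared masks,
#' with each oriented wedge counted together with its mirrored conjugate
#' partner, tile the frequency plane exactly, so reconstruction is exact to
#' machine precision for real frames.
#'
#' @param H,W frame size in pixels.
#' @param levels number of octave levels, or `NULL` to choose
#'   `floor(log2(min(H, W))) - 3` (at least 1), which keeps the coarsest
#'   band's support comfortably away from the DC bin.
#' @param orientations number of angular bands K (default 4).
#' @return list of class `"pyr_filters"` with `hi` and `lo` real masks,
#'   `bands` (list of `levels` lists of `K` masks), and the geometry.
#' @export
pyr_filters <- function(H, W, levels = NULL, orientations = 4) {
  if (is.null(levels)) levels <- max(1L, floor(log2(min(H, W))) - 3L)
  levels <- as.integer(levels)
  min_side <- 2^(levels + 2L)
  if (min(H, W) < min_side)
    stop(sprintf("frame too small for %d pyramid levels: need at least %dx%d",
                 levels, min_side, min_side))
  wx <- 2 * pi * ifelse(seq_len(W) - 1 <= W %/% 2, seq_len(W) - 1,
                        seq_len(W) - 1 - W) / W
  wy <- 2 * pi * ifelse(seq_len(H) - 1 <= H %/% 2, seq_len(H) - 1,
                        seq_len(H) - 1 - H) / H
  r <- sqrt(outer(wy^2, wx^2, `+`))
  theta <- atan2(outer(wy, rep(1, W)), outer(rep(1, H), wx))
  lr <- log2(pmax(r, 1e-12) / pi)        # 0 at Nyquist, -1 one octave down
  himask <- function(cut) cos(pi / 2 * pmin(pmax(lr - cut, -1), 0))
  n <- orientations - 1L
  aconst <- 4^n * factorial(n)^2 / (orientations * factorial(2 * n))
  hi <- himask(0)
  lo_acc <- sqrt(pmax(1 - hi^2, 0))
  bands <- vector("list", levels)
  for (l in seq_len(levels)) {
    h <- himask(-l)
    b_rad <- h * lo_acc
    lo_acc <- sqrt(pmax(lo_acc^2 - b_rad^2, 0))
    bands[[l]] <- lapply(seq_len(orientations), function(k) {
      delta <- (theta - (k - 1) * pi / orientations + pi) %% (2 * pi) - pi
      ang <- sqrt(aconst) * abs(cos(delta))^n * (abs(delta) < pi / 2)
      b_rad * ang
    })
  }
  structure(list(hi = hi, lo = lo_acc, bands = bands, H = H, W = W,
                 levels = levels, orientations = orientations),
            class = "pyr_filters")
}

#' Build / collapse a complex steerable pyramid
#'
#' `build_pyramid` decomposes a real frame into a real high-pass residual,
#' complex oriented band coefficients per level, and a real low-pass
#' residual; `collapse_pyramid` reassembles the frame. The decomposition is
#' linear and the round trip is exact up to floating-point error.
#'
#' @param frame real numeric matrix (H x W).
#' @param filters a [pyr_filters()] matching the frame size (built on the
#'   fly if omitted).
#' @param pyr a pyramid as returned by `build_pyramid`.
#' @param levels,orientations passed to [pyr_filters()] when `filters` is
#'   missing.
#' @return `build_pyramid`: list of class `"pyramid"` with `hi`, `lo`
#'   (real matrices), `bands` (list of lists of complex matrices) and
#'   `filters`. `collapse_pyramid`: the reconstructed real matrix.
#' @export
build_pyramid <- function(frame, filters = NULL, levels = NULL,
                          orientations = 4) {
  frame <- as.matrix(frame)
  if (is.null(filters))
    filters <- pyr_filters(nrow(frame), ncol(frame), levels, orientations)
  stopifnot(nrow(frame) == filters$H, ncol(frame) == filters$W)
  X <- stats::fft(frame)
  npix <- filters$H * filters$W
  structure(list(
    hi = Re(stats::fft(X * filters$hi, inverse = TRUE)) / npix,
    lo = Re(stats::fft(X * filters$lo, inverse = TRUE)) / npix,
    bands = lapply(filters$bands, function(lev)
      lapply(lev, function(D) stats::fft(X * D, inverse = TRUE) / npix)),
    filters = filters),
    class = "pyramid")
}

#' @rdname build_pyramid
#' @export
collapse_pyramid <- function(pyr) {
  f <- pyr$filters
  npix <- f$H * f$W
  acc <- stats::fft(pyr$hi) * f$hi + stats::fft(pyr$lo) * f$lo
  out <- Re(stats::fft(acc, inverse = TRUE)) / npix
  for (l in seq_len(f$levels)) for (k in seq_len(f$orientations)) {
    g <- stats::fft(pyr$bands[[l]][[k]]) * f$bands[[l]][[k]]
    out <- out + 2 * Re(stats::fft(g, inverse = TRUE)) / npix
  }
  out
}
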