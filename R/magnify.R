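#' Phase-based Eulerian motion magnification
#'
#' Amplifies motions in selected temporal frequency bands. Each frame's
#' luminance (Y of YIQ) is decomposed by an undecimated complex steerable
#' pyramid; per pixel, level and orientation, the coefficient phase is
#' unwrapped over time, ideally band-passed (hard frequency-domain gate)
#' to the schedule's passbands, scaled by `alpha` and added back, so
#' in-band motion is magnified by a total factor of `1 + alpha` while
#' out-of-band motion (e.g. large drift) passes through unchanged. The
#' high- and low-pass residuals are never amplified, and chrominance passes
#' through untouched.
#'
#' Phase carries the motion of each band's oscillatory carrier; with
#' octave-bandwidth filters the band envelopes (coefficient magnitudes) are
#' spatially comparable to the carrier wavelength and hold a substantial
#' share of the apparent motion, so phase-only amplification underdelivers
#' the nominal `1 + alpha` gain on broadband structures. By default the
#' band-passed log-magnitude is therefore amplified by the same factor
#' (`amplify_magnitude = TRUE`), which transports the envelopes as well and
#' restores the nominal gain to first order; set it to `FALSE` for
#' classical phase-only processing.
#'
#' When the schedule's bands differ across time intervals the phase is
#' filtered by windowed overlap-add (50%-overlap Hann windows, one per
#' schedule interval); when they are constant (or `global_band = TRUE`) a
#' single full-clip gate over the union of bands is used.
#'
#' @param video a [video_sequence()] (RGB, [0, 1]).
#' @param schedule a [passbands_from_mask()] data frame, or a numeric
#'   vector `c(f_low, f_high)` in Hz for a single fixed band.
#' @param alpha amplification factor (>= 0); 0 returns the input up to
#'   reconstruction error (which is machine precision here).
#' @param levels pyramid levels (`NULL` = automatic).
#' @param orientations angular bands (default 4).
#' @param global_band force a single time-invariant gate over the union of
#'   scheduled bands (default: automatic, used when the schedule does not
#'   vary).
#' @param amplify_magnitude also amplify the band-passed log-magnitude of
#'   the pyramid coefficients (default `TRUE`; see Details).
#' @return a [video_sequence()] of the same shape (values clipped to
#'   [0, 1]).
#' @export
magnify <- function(video, schedule, alpha, levels = NULL, orientations = 4,
                    global_band = FALSE, amplify_magnitude = TRUE) {
  stopifnot(inherits(video, "video_sequence"), alpha >= 0)
  fps <- video$fps
  sch <- normalize_schedule(schedule, fps)
  d <- dim(video$frames)
  T_ <- d[1L]; H <- d[2L]; W <- d[3L]
  yiq <- color_convert(video, "to_yiq")
  Y <- yiq$frames[, , , 1L]
  if (nrow(sch) == 0L) {
    warning("empty passband schedule: nothing to amplify, returning input")
    return(video)
  }
  filters <- pyr_filters(H, W, levels, orientations)
  Xf <- vector("list", T_)
  for (t in seq_len(T_)) Xf[[t]] <- stats::fft(Y[t, , ])
  npix <- H * W
  # residual pass-through
  out <- array(0, c(T_, H, W))
  res_mask <- filters$hi^2 + filters$lo^2
  for (t in seq_len(T_))
    out[t, , ] <- Re(stats::fft(Xf[[t]] * res_mask, inverse = TRUE)) / npix
  varying <- !global_band && length(unique(sch$interval)) > 1L &&
    schedule_varies(sch)
  for (l in seq_len(filters$levels)) for (k in seq_len(orientations)) {
    D <- filters$bands[[l]][[k]]
    C <- matrix(0i, npix, T_)
    for (t in seq_len(T_))
      C[, t] <- stats::fft(Xf[[t]] * D, inverse = TRUE) / npix
    if (alpha > 0) {
      phi <- unwrap_rows(Arg(C))
      phf <- if (varying) filter_phase_wola(phi, sch, fps)
             else filter_phase_global(phi, band_union(sch), fps)
      fac <- exp(1i * alpha * phf)
      if (amplify_magnitude) {
        lmag <- log(pmax(Mod(C), 1e-10))
        lmf <- if (varying) filter_phase_wola(lmag, sch, fps)
               else filter_phase_global(lmag, band_union(sch), fps)
        fac <- fac * exp(alpha * lmf)
      }
      C <- C * fac
    }
    for (t in seq_len(T_)) {
      g <- stats::fft(matrix(C[, t], H, W)) * D
      out[t, , ] <- out[t, , ] + 2 * Re(stats::fft(g, inverse = TRUE)) / npix
    }
  }
  yiq$frames[, , , 1L] <- out
  res <- color_convert(yiq, "to_rgb")
  res$frames <- pmin(pmax(res$frames, 0), 1)   # argument order keeps dims
  res
}

# accept c(lo, hi) shorthand; validate against Nyquist
normalize_schedule <- function(schedule, fps) {
  if (is.numeric(schedule) && length(schedule) == 2L) {
    schedule <- data.frame(interval = 1L, time_s = 0,
                           f_low_hz = schedule[1L], f_high_hz = schedule[2L])
  }
  stopifnot(is.data.frame(schedule))
  if (nrow(schedule) && any(schedule$f_low_hz >= fps / 2))
    stop("schedule passband beyond the Nyquist frequency fps/2")
  if (nrow(schedule)) {
    schedule$f_high_hz <- pmin(schedule$f_high_hz, fps / 2)
    schedule <- schedule[schedule$f_high_hz > schedule$f_low_hz, ]
  }
  schedule
}

schedule_varies <- function(sch) {
  key <- vapply(split(sch, sch$interval), function(d)
    paste(sprintf("%.6g-%.6g", d$f_low_hz, d$f_high_hz), collapse = ";"),
    character(1))
  length(unique(key)) > 1L
}

# merge all scheduled ranges into a disjoint union
band_union <- function(sch) {
  b <- sch[order(sch$f_low_hz), c("f_low_hz", "f_high_hz")]
  if (!nrow(b)) return(b)
  merged <- b[1L, , drop = FALSE]
  if (nrow(b) > 1L) for (j in 2:nrow(b)) {
    last <- nrow(merged)
    if (b$f_low_hz[j] <= merged$f_high_hz[last]) {
      merged$f_high_hz[last] <- max(merged$f_high_hz[last], b$f_high_hz[j])
    } else merged <- rbind(merged, b[j, ])
  }
  merged
}

# unwrap phase along rows (time axis) of a [npix, T] matrix
unwrap_rows <- function(ph) {
  T_ <- ncol(ph)
  if (T_ < 2L) return(ph)
  dp <- ph[, -1L, drop = FALSE] - ph[, -T_, drop = FALSE]
  dp <- (dp + pi) %% (2 * pi) - pi
  out <- ph
  acc <- ph[, 1L]
  for (t in 2:T_) {                 # cumulative sum along time, vectorized
    acc <- acc + dp[, t - 1L]       # over pixels
    out[, t] <- acc
  }
  out
}

# 0/1 gate over DFT bins of a length-T clip for a set of bands
dft_gate <- function(T_, fps, bands) {
  f <- (seq_len(T_) - 1L) * fps / T_
  f <- pmin(f, fps - f)                      # two-sided spectrum
  keep <- rep(FALSE, T_)
  for (j in seq_len(nrow(bands)))
    keep <- keep | (f >= bands$f_low_hz[j] & f <= bands$f_high_hz[j])
  keep
}

# ideal band-pass along time of a [npix, T] real matrix, full-clip DFT.
# A per-pixel linear trend is removed first: at pixels traversed by a large
# motion the unwrapped phase is a steep non-periodic ramp whose DFT leaks
# into every bin; detrending confines the gate to genuine oscillations.
filter_phase_global <- function(phi, bands, fps) {
  T_ <- ncol(phi)
  gate <- dft_gate(T_, fps, bands)
  if (!any(gate)) return(phi * 0)
  tt <- seq_len(T_) - (T_ + 1) / 2
  beta <- (phi %*% tt) / sum(tt^2)
  phi <- phi - outer(as.vector(beta), tt) - rowMeans(phi)
  F <- stats::mvfft(t(phi))
  F[!gate, ] <- 0i
  t(Re(stats::mvfft(F, inverse = TRUE))) / T_
}

# windowed overlap-add band-pass: one Hann window per schedule interval,
# each segment gated by its interval's bands
filter_phase_wola <- function(phi, sch, fps) {
  T_ <- ncol(phi)
  ivs <- sort(unique(sch$interval))
  centers <- round(seq(1, T_, length.out = length(ivs)))
  seg <- max(8L, 2L * as.integer(ceiling(T_ / length(ivs))))
  half <- seg %/% 2L
  outp <- phi * 0
  wsum <- numeric(T_)
  for (j in seq_along(ivs)) {
    idx <- (centers[j] - half):(centers[j] + half)
    keep <- idx >= 1L & idx <= T_
    idx <- idx[keep]
    w <- 0.5 * (1 - cos(2 * pi * (seq_len(seg + 1L) - 1L) / seg))[keep]
    bands <- sch[sch$interval == ivs[j], , drop = FALSE]
    gate <- dft_gate(length(idx), fps, bands)
    Fs <- stats::mvfft(t(phi[, idx, drop = FALSE] *
                           rep(w, each = nrow(phi))))
    Fs[!gate, ] <- 0i
    seg_f <- t(Re(stats::mvfft(Fs, inverse = TRUE))) / length(idx)
    outp[, idx] <- outp[, idx] + seg_f
    wsum[idx] <- wsum[idx] + w
  }
  sweep(outp, 2L, pmax(wsum, 1e-6), `/`)
}
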