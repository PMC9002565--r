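#' Amplitude thresholds for spectrum-aware filtering
#'
#' @param rho_l minimum amplitude bound (>= 0); cells quieter than this are
#'   treated as negligible noise. Not critical in practice; default 0.
#' @param rho_h maximum amplitude bound; cells louder than this are treated
#'   as large motion and excluded from amplification. `Inf` disables the
#'   bound.
#' @return list of class `"thresholds"`.
#' @export
thresholds <- function(rho_l = 0, rho_h = Inf) {
  if (!(rho_l >= 0)) stop("`rho_l` must be >= 0")
  if (!(rho_l < rho_h)) stop("`rho_l` must be strictly below `rho_h`")
  structure(list(rho_l = rho_l, rho_h = rho_h), class = "thresholds")
}

#' Default large-motion threshold for a motion spectrum
#'
#' Half the maximum magnitude of the surface: large motions dominate the
#' spectrogram, so anything within a factor 2 of the peak is treated as
#' large motion. Experience-modifiable.
#'
#' @param x a [tfr()].
#' @return a numeric rho_h value.
#' @export
auto_rho_h <- function(x) {
  stopifnot(inherits(x, "tfr"))
  0.5 * max(Mod(x$coeffs))
}

#' Binary weighting mask of the spectrum-aware filter
#'
#' `W(s, i) = 1` iff the coefficient magnitude lies in `[rho_l, rho_h]`,
#' else 0: the time-domain dynamic weighting function applied on the
#' denoised motion spectrogram.
#'
#' @param x a [tfr()].
#' @param th a [thresholds()].
#' @return integer 0/1 matrix of the TFR shape.
#' @export
build_weight <- function(x, th) {
  stopifnot(inherits(x, "tfr"), inherits(th, "thresholds"))
  A <- Mod(x$coeffs)
  m <- (A >= th$rho_l & A <= th$rho_h) * 1L
  storage.mode(m) <- "integer"
  m
}

#' Split a surface into large- and subtle-motion components
#'
#' Cells with magnitude above `rho_h` go to `above`, the rest to `below`;
#' the two components sum cellwise to the input exactly.
#'
#' @param x a [tfr()].
#' @param th a [thresholds()].
#' @return list of two [tfr()]s, `above` and `below`.
#' @export
split_components <- function(x, th) {
  stopifnot(inherits(x, "tfr"), inherits(th, "thresholds"))
  big <- Mod(x$coeffs) > th$rho_h
  above <- x$coeffs * big
  list(above = tfr(x$times, x$freqs, above),
       below = tfr(x$times, x$freqs, x$coeffs - above))
}

#' Per-interval passband schedule from a weight mask
#'
#' Per time column, maximal runs of consecutive selected frequency bins
#' become frequency passbands (band edges extend half a bin beyond the
#' outermost selected bins); runs shorter than `min_band_bins` are dropped.
#' This bridges the global time-frequency mask to the per-pixel temporal
#' filtering of [magnify()].
#'
#' @param mask 0/1 matrix from [build_weight()].
#' @param freqs frequency lines in Hz (length `nrow(mask)`).
#' @param times column times in seconds (length `ncol(mask)`), kept in the
#'   schedule for time-varying filtering.
#' @param min_band_bins minimum run length to keep (default 2).
#' @return An object of class `"passband_schedule"`: a data frame with
#'   columns `interval`, `time_s`, `f_low_hz`, `f_high_hz` (zero rows when
#'   nothing is selected).
#' @export
passbands_from_mask <- function(mask, freqs, times = seq_len(ncol(mask)),
                                min_band_bins = 2) {
  stopifnot(nrow(mask) == length(freqs), ncol(mask) == length(times))
  half <- if (length(freqs) > 1) diff(freqs[1:2]) / 2 else 0.5
  rows <- list()
  for (i in seq_len(ncol(mask))) {
    r <- rle(mask[, i] != 0L)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- which(r$values & r$lengths >= min_band_bins)
    for (k in sel) {
      rows[[length(rows) + 1L]] <- data.frame(
        interval = i, time_s = times[i],
        f_low_hz = max(0, freqs[starts[k]] - half),
        f_high_hz = freqs[ends[k]] + half)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(interval = integer(0), time_s = numeric(0),
               f_low_hz = numeric(0), f_high_hz = numeric(0))
  class(out) <- c("passband_schedule", "data.frame")
  out
}

#' @export
print.passband_schedule <- function(x, ...) {
  cat(sprintf("<passband_schedule> %d bands over %d intervals\n",
              nrow(x), length(unique(x$interval))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Read / write a passband schedule as CSV
#' @param schedule a [passbands_from_mask()] result.
#' @param path file path.
#' @return `write_schedule_csv` returns `path` invisibly;
#'   `read_schedule_csv` returns a `passband_schedule`.
#' @export
write_schedule_csv <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("passband_schedule", "data.frame")
  out
}
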