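#' Time-frequency representation
#'
#' Complex coefficient matrix on a time-center by frequency-line grid, the
#' common carrier for short-time, chirplet and denoised spectrograms.
#'
#' @param times interval-center times in seconds (one per column).
#' @param freqs strictly increasing frequency lines in Hz (one per row).
#' @param coeffs complex matrix, `length(freqs)` x `length(times)`.
#' @return An object of class `"tfr"`.
#' @export
tfr <- function(times, freqs, coeffs) {
  coeffs <- as.matrix(coeffs)
  if (!is.complex(coeffs)) storage.mode(coeffs) <- "complex"
  if (nrow(coeffs) != length(freqs) || ncol(coeffs) != length(times))
    stop("`coeffs` must be length(freqs) x length(times)")
  if (length(freqs) > 1 && any(diff(freqs) <= 0))
    stop("`freqs` must be strictly increasing")
  if (!all(is.finite(Re(coeffs))) || !all(is.finite(Im(coeffs))))
    stop("all TFR coefficients must be finite")
  structure(list(times = as.numeric(times), freqs = as.numeric(freqs),
                 coeffs = coeffs),
            class = "tfr")
}

#' @export
print.tfr <- function(x, ...) {
  cat(sprintf(
    "<tfr> %d frequency lines [%.3g, %.3g] Hz x %d columns, t in [%.3g, %.3g] s\n",
    length(x$freqs), min(x$freqs), max(x$freqs),
    length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' @export
plot.tfr <- function(x, main = "", xlab = "time (s)", ylab = "frequency (Hz)",
                     ...) {
  graphics::image(x$times, x$freqs, t(Mod(x$coeffs)),
                  main = main, xlab = xlab, ylab = ylab,
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Read / write a TFR as a CSV pair
#'
#' The magnitude file is a matrix whose first row holds the column times and
#' whose first column holds the frequency lines; a companion file of the same
#' layout holds the phase in radians, so the complex surface round-trips.
#'
#' @param x a [tfr()].
#' @param path magnitude CSV path.
#' @param phase_path phase CSV path; default replaces the extension of
#'   `path` with `_phase.csv`.
#' @return `write_tfr_csv` returns `path` invisibly; `read_tfr_csv` returns
#'   a [tfr()].
#' @export
write_tfr_csv <- function(x, path, phase_path = default_phase_path(path)) {
  stopifnot(inherits(x, "tfr"))
  dump1 <- function(values, p) {
    m <- rbind(c(NA, x$times), cbind(x$freqs, values))
    utils::write.table(m, p, sep = ",", row.names = FALSE, col.names = FALSE,
                       na = "")
  }
  dump1(Mod(x$coeffs), path)
  dump1(Arg(x$coeffs), phase_path)
  invisible(path)
}

#' @rdname write_tfr_csv
#' @export
read_tfr_csv <- function(path, phase_path = default_phase_path(path)) {
  slurp <- function(p) {
    m <- as.matrix(utils::read.table(p, sep = ",", header = FALSE))
    list(times = as.numeric(m[1, -1]), freqs = as.numeric(m[-1, 1]),
         values = unname(m[-1, -1, drop = FALSE]))
  }
  mag <- slurp(path)
  ph <- slurp(phase_path)
  tfr(mag$times, mag$freqs, mag$values * exp(1i * ph$values))
}

default_phase_path <- function(path) {
  sub("(\\.[^.]*)?$", "_phase\\1", path)
}

#' Renyi entropy of a time-frequency surface
#'
#' Concentration measure of the normalized energy distribution
#' `p = |coeff|^2 / sum(|coeff|^2)`:
#' `(1/(1-order)) * log2(sum(p^order))`. Lower values mean sharper
#' time-frequency localization; all energy in one cell gives 0 and a uniform
#' surface over N cells gives `log2(N)`.
#'
#' @param x a [tfr()] with nonzero total energy.
#' @param order entropy order (default 3).
#' @return scalar entropy in bits.
#' @export
renyi_entropy <- function(x, order = 3) {
  stopifnot(inherits(x, "tfr"), order > 1)
  e <- Mod(x$coeffs)^2
  tot <- sum(e)
  if (tot == 0) stop("zero-energy TFR has no entropy")
  p <- e / tot
  log2(sum(p^order)) / (1 - order)
}
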