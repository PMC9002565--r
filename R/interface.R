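#' Run configuration
#'
#' Bundles every tunable of the two top-level workflows, validates it
#' against the module preconditions before any computation, and serializes
#' next to every output so a run can be reproduced bit for bit.
#'
#' @param window_sd,hop,n_lines,n_knots,n_iter transform settings
#'   ([sct()], [iterate_sct()]); `hop` doubles as the stationary interval
#'   length.
#' @param jump_penalty ridge extraction penalty (`NULL` = default).
#' @param alpha,beta,eps,em_max EM settings ([em_config()]).
#' @param rho_l,rho_h spectrum-filter thresholds; `rho_h = NULL` means
#'   automatic ([auto_rho_h()]).
#' @param min_band_bins minimum passband width in bins.
#' @param mag_alpha video amplification factor.
#' @param levels pyramid levels (`NULL` = automatic).
#' @param fps frame rate for video input.
#' @param seed integer seed governing all randomness of a run.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(window_sd = 0.5, hop = 10, n_lines = 256,
                       n_knots = 8, n_iter = 3, jump_penalty = NULL,
                       alpha = 3, beta = 1e-3, eps = 1e-4, em_max = 50,
                       rho_l = 0, rho_h = NULL, min_band_bins = 2,
                       mag_alpha = 5, levels = NULL, fps = NULL,
                       seed = 1L) {
  stopifnot(window_sd > 0, hop >= 1, n_lines >= 2, n_knots >= 2,
            n_iter >= 1, mag_alpha >= 0, min_band_bins >= 1)
  em <- em_config(alpha = alpha, beta = beta, em_max = em_max, eps = eps)
  structure(list(window_sd = window_sd, hop = as.integer(hop),
                 n_lines = as.integer(n_lines), n_knots = as.integer(n_knots),
                 n_iter = as.integer(n_iter), jump_penalty = jump_penalty,
                 em = em, rho_l = rho_l, rho_h = rho_h,
                 min_band_bins = as.integer(min_band_bins),
                 mag_alpha = mag_alpha, levels = levels, fps = fps,
                 seed = as.integer(seed)),
            class = "run_config")
}

write_config_json <- function(config, path) {
  x <- unclass(config)
  x$em <- unclass(x$em)
  jsonlite::write_json(x, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Signal-analysis workflow
#'
#' Reads a sampled signal (CSV, WAV, or an in-memory [time_series()]), fits
#' the empirical-Bayes chirplet spectrogram with [besct()], and writes the
#' raw SCT surface, the denoised surface, the EM trace, a rendered
#' spectrogram image (grayscale PNG, rows = frequency lines top-down), and
#' the resolved configuration. Deterministic: identical inputs and config
#' give byte-identical outputs.
#'
#' @param input path to a `time_s,value` CSV or a mono WAV, or a
#'   [time_series()].
#' @param out_dir output directory (created if needed).
#' @param config a [run_config()].
#' @return (invisibly) the fitted [besct()] object. Files written:
#'   `sct.csv`/`sct_phase.csv`, `besct.csv`/`besct_phase.csv`,
#'   `em_trace.csv`, `spectrogram.png`, `config.json`.
#' @export
analyze_signal <- function(input, out_dir, config = run_config()) {
  ts <- load_signal(input, config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  fit <- besct(ts, window_sd = config$window_sd, hop = config$hop,
               n_lines = config$n_lines, n_knots = config$n_knots,
               jump_penalty = config$jump_penalty, n_iter = config$n_iter,
               em = config$em)
  write_tfr_csv(fit$sct, file.path(out_dir, "sct.csv"))
  write_tfr_csv(fit$surface, file.path(out_dir, "besct.csv"))
  write_em_trace(fit$trace, file.path(out_dir, "em_trace.csv"))
  A <- Mod(fit$surface$coeffs)
  img <- A[rev(seq_len(nrow(A))), , drop = FALSE] / max(A, 1e-12)
  png::writePNG(img, file.path(out_dir, "spectrogram.png"))
  write_config_json(config, file.path(out_dir, "config.json"))
  invisible(fit)
}

load_signal <- function(input, config) {
  if (inherits(input, "time_series")) return(input)
  if (!is.character(input) || !file.exists(input))
    stop("cannot read signal input: no such file: ", input)
  if (grepl("\\.wav$", input, ignore.case = TRUE)) read_ts_wav(input)
  else read_ts_csv(input)
}

#' Video-magnification workflow
#'
#' The spectrum-aware pipeline: extract the global-motion series
#' ([emod_series()]), fit its BE-SCT spectrogram, threshold it into a
#' passband schedule ([build_weight()], [passbands_from_mask()]), magnify
#' the clip ([magnify()]), and write all artifacts: EMOD series CSV, motion
#' spectrum CSV pair, schedule CSV, magnified PNG frames, a run log and the
#' resolved config.
#'
#' @param input a [video_sequence()] or a directory of PNG frames.
#' @param out_dir output directory.
#' @param config a [run_config()]; `fps` must be set when `input` is a
#'   frame directory.
#' @return (invisibly) a list with `emod` ([time_series()]), `fit`
#'   ([besct()]), `schedule`, and `video` (the magnified
#'   [video_sequence()]).
#' @export
magnify_video <- function(input, out_dir, config = run_config()) {
  video <- if (inherits(input, "video_sequence")) input else {
    if (is.null(config$fps))
      stop("`config$fps` is required to read a frame directory")
    read_video_png(input, config$fps)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  logline <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   paste0(...))
    message(msg)
    cat(msg, "\n", file = logf, append = TRUE)
  }
  cat("", file = logf)
  d <- dim(video$frames)
  logline(sprintf("input: %d frames %dx%d @ %g fps", d[1L], d[2L], d[3L],
                  video$fps))
  emod <- emod_series(video)
  write_ts_csv(emod, file.path(out_dir, "emod.csv"))
  logline("EMOD series extracted")
  # the motion series is short: adapt window/hop/lines to its length
  n <- length(emod$values)
  win <- min(config$window_sd, n / (10 * video$fps))
  hop <- max(1L, min(config$hop, n %/% 12L))
  fit <- besct(emod, window_sd = win, hop = hop,
               n_lines = min(config$n_lines, 128L),
               n_knots = min(config$n_knots, 6L),
               jump_penalty = config$jump_penalty,
               n_iter = config$n_iter, em = config$em)
  write_tfr_csv(fit$surface, file.path(out_dir, "motion_spectrum.csv"))
  logline(sprintf("BE-SCT fitted: S = %d x I = %d", nrow(fit$obs$Y),
                  ncol(fit$obs$Y)))
  rho_h <- if (is.null(config$rho_h)) auto_rho_h(fit$surface) else
    config$rho_h
  th <- thresholds(config$rho_l, rho_h)
  mask <- build_weight(fit$surface, th)
  schedule <- passbands_from_mask(mask, fit$surface$freqs,
                                  fit$surface$times,
                                  config$min_band_bins)
  write_schedule_csv(schedule, file.path(out_dir, "schedule.csv"))
  logline(sprintf("schedule: %d bands (rho_h = %.4g)", nrow(schedule),
                  rho_h))
  out <- magnify(video, schedule, config$mag_alpha, levels = config$levels)
  write_video_png(out, file.path(out_dir, "frames"))
  write_config_json(config, file.path(out_dir, "config.json"))
  logline("magnified frames written")
  invisible(list(emod = emod, fit = fit, schedule = schedule, video = out))
}
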