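# besct

Empirical-Bayes chirplet spectrograms for nonstationary signals, and
spectrum-aware video motion magnification built on them.

## The problem

Biological and physical monitoring videos often contain two kinds of motion
at once: a large, slow movement (an organism crawling, a camera drift, a
limb gesture) and a subtle periodic micro-motion riding on top of it (a
pulse, a tremor, a vibration). Eulerian motion magnification can make the
subtle motion visible, but amplifying everything also amplifies the large
motion and drowns the result in artifacts. Selecting *which temporal
frequencies* to amplify requires a time-frequency picture of the global
motion that stays sharp for nonlinearly frequency-modulated, noisy signals
— which is exactly where windowed Fourier spectrograms fall apart.

`besct` addresses both halves:

* **BE-SCT** — a spline-kerneled chirplet transform (SCT) embedded in an
  empirical-Bayes state-space model. The SCT demodulates the record with a
  cubic-spline model κ(t) of instantaneous frequency, so a nonlinear
  frequency law appears as a concentrated ridge. Its coefficients on
  stationary intervals *i* = 1…I are then treated, per frequency line
  ω_s, as noisy observations of latent spectral increments linked by a
  random-walk continuity prior:

      Y_i,s  = ΔZ_i,s + ε_i,s,        ε_i,s ~ CN(0, σ_ε²)
      ΔZ_i,s = ΔZ_{i−1,s} + v_i,s,    v_i,s ~ CN(0, σ_{v,s}²)

  A complex Kalman filter and fixed-interval smoother give the joint
  Gaussian posterior of the increments; σ_ε² and the per-line σ_{v,s}² are
  estimated by EM with gamma priors on the precisions (empirical Bayes).
  The smoothed-mean surface is a denoised spectrogram that stays coherent
  across the whole record.

* **Spectrum-aware magnification** — each frame is reduced to an earth
  mover's distance (EMOD) against the first frame, giving a global-motion
  time series; its BE-SCT spectrogram is thresholded on amplitude (large
  motions are loud, micro-motions quiet) into per-interval frequency
  passbands; a complex steerable pyramid then amplifies only the scheduled
  temporal bands of each pixel's phase (and, by default, band-limited
  log-magnitude), reconstructing a clip in which the micro-motion is
  magnified and the large motion passes through.

## Worked example

```r
library(besct)

ts  <- add_noise(gen_example("example1"), variance = 0.1, seed = 1)
snr_db(gen_example("example1"), ts)   # 6.69 dB
fit <- besct(ts)                      # iterated SCT + Kalman/EM fit
summary(fit)
```

```
BE-SCT fit summary
  1001 samples @ 100 Hz; S = 256 x I = 100
  EM iterations: 50; sigma_eps2 = 39.54
  ...
  Renyi entropy (order 3): SCT 9.080 -> denoised 8.747 bits
  ridge: 15.1-34.7 Hz over 100 columns
```

The benchmark record sweeps 25 + 10·cos(t) Hz for six seconds and then
jumps to a 34.2 Hz tone; at ~7 dB SNR the denoised surface's ridge stays
within 1 Hz of that instantaneous frequency at more than 90% of columns,
and the entropy drop (9.08 → 8.75 bits) quantifies the sharpening from the
raw chirplet spectrogram to the smoothed one. `plot(fit)` draws the
surface; `extract_ridge(fit$surface)` returns the track.

The video pipeline runs the same way:

```r
ball <- gen_ball_video()                 # drifting, vibrating disc + truth
out  <- magnify_video(ball$video, "out/", run_config(mag_alpha = 1))
psnr(ball$ground_truth, out$video)       # higher than all-band magnification
```

A command-line front end with the same workflows is installed as
`exec/besct` (subcommands `simulate-signal`, `analyze-signal`,
`simulate-ball`, `magnify`, `evaluate`).

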