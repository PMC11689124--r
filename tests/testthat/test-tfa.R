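# Spectral core: resampling, segmentation, Welch estimates against a
# direct-DFT oracle, point metrics, and the TFA identities.

test_that("spline resampling reproduces a linear ramp exactly", {
  bt <- data.frame(beat_onset_time = cumsum(runif(40, 0.7, 0.9)))
  bt$mean <- 2 + 0.5 * bt$beat_onset_time
  s <- spline_resample(bt, "mean", rate = 4)
  t_grid <- bt$beat_onset_time[1] + (seq_along(s$values) - 1) / 4
  expect_lt(max(abs(s$values - (2 + 0.5 * t_grid)) / abs(s$values)), 1e-6)
})

test_that("a beat-sampled sinusoid keeps its amplitude through resampling", {
  set.seed(21)
  t_beat <- cumsum(runif(360, 60 / 95, 60 / 85))  # ~ heart rate 90
  bt <- data.frame(beat_onset_time = t_beat,
                   mean = 90 + 10 * sin(2 * pi * 0.05 * t_beat))
  s <- spline_resample(bt, "mean", rate = 4)
  grid <- s$start + (seq_along(s$values) - 1) / 4
  fit <- sinusoid_fit(grid, s$values, 0.05)
  expect_lt(abs(fit$amplitude - 10) / 10, 0.01)
})

test_that("resampled length and validation behave as specified", {
  bt <- data.frame(beat_onset_time = seq(0, 240, by = 0.8), mean = 1:301)
  s <- spline_resample(bt, "mean", rate = 4, start = 0, duration = 240)
  expect_length(s$values, 960)
  btdup <- bt
  btdup$beat_onset_time[2] <- btdup$beat_onset_time[1]
  expect_error(spline_resample(btdup, "mean"),
               class = "dcatfa_invalid_argument")
  expect_error(spline_resample(bt[1:5, ], "mean"),
               class = "dcatfa_too_few_beats")
})

test_that("window counts follow the segmentation arithmetic", {
  counts <- function(dur) {
    s <- us(rnorm(round(dur * 4)))
    segment_windows(s, welch_config())$n_windows
  }
  set.seed(1)
  expect_equal(counts(240), 5L)
  expect_equal(counts(80), 1L)
  expect_equal(counts(200), 4L)
  expect_error(counts(60), class = "dcatfa_invalid_argument")
})

test_that("Welch spectra match a brute-force direct DFT bin by bin", {
  set.seed(33)
  xv <- rnorm(64)
  yv <- 0.7 * xv + rnorm(64, 0, 0.3)
  x <- us(xv); y <- us(yv)
  cfg <- welch_config(window_length = 8, overlap_fraction = 0)  # 2 x 32 samples
  S <- welch_spectra(x, y, cfg)
  O <- oracle_welch(xv, yv, 4, 8, 0)
  expect_equal(S$n_windows, 2L)
  expect_lt(max(abs(S$psd_input - O$pxx) / O$pxx), 1e-9)
  expect_lt(max(abs(S$psd_output - O$pyy) / O$pyy), 1e-9)
  expect_lt(max(Mod(S$cross_spectrum - O$sxy) / Mod(O$sxy)), 1e-9)
})

test_that("identity and scaled outputs give the textbook TFA values", {
  set.seed(34)
  xv <- rnorm(960)
  x <- us(xv)
  S1 <- welch_spectra(x, x, welch_config())
  expect_true(all(abs(S1$coherence - 1) < 1e-9))
  expect_true(all(abs(S1$gain - 1) < 1e-9))
  expect_true(all(abs(S1$phase) < 1e-9))
  S2 <- welch_spectra(x, us(2 * xv), welch_config())
  expect_true(all(abs(S2$gain - 2) < 1e-9))
  expect_true(all(abs(S2$coherence - 1) < 1e-9))
})

test_that("a pure delay yields phase -2 pi f tau", {
  rate <- 4; tau <- 1.5  # 6 samples
  set.seed(35)
  base <- rnorm(1000)
  xv <- base[7:966]
  yv <- base[(7:966) - 6]  # y(t) = x(t - tau)
  S <- welch_spectra(us(xv, rate), us(yv, rate), welch_config())
  # broadband check (taper/detrend leakage bounds the per-bin error) ...
  band <- S$freqs > 0 & S$freqs <= 0.15
  expect_lt(max(abs(S$phase[band] - (-2 * pi * S$freqs[band] * tau))), 0.1)
  # ... and a tight check at a high-SNR forcing bin
  tt <- (0:965) / 4
  xs <- 90 + 10 * sin(2 * pi * 0.05 * tt) + 0.5 * rnorm(966)
  ys <- c(rep(xs[1], 6), xs[1:960])  # delayed by 6 samples
  S2 <- welch_spectra(us(xs[1:960], rate), us(ys[1:960], rate),
                      welch_config())
  i <- which.min(abs(S2$freqs - 0.05))
  expect_lt(abs(S2$phase[i] - (-2 * pi * 0.05 * tau)), 0.02)
})

test_that("coherence lies in [0,1] and drops monotonically with output noise", {
  set.seed(36)
  xv <- 10 * sin(2 * pi * 0.05 * (0:959) / 4) + rnorm(960)
  x <- us(xv)
  cohs <- sapply(c(0.5, 2, 8), function(nsd) {
    S <- welch_spectra(x, us(0.8 * xv + rnorm(960, 0, nsd)), welch_config())
    expect_true(all(S$coherence >= 0 & S$coherence <= 1 + 1e-12))
    S$coherence[which.min(abs(S$freqs - 0.05))]
  })
  expect_true(all(diff(cohs) < 0))
})

test_that("PSD integrates to the mean per-window variance (Parseval)", {
  set.seed(5)
  n_win <- 100
  v <- rnorm(128 * n_win)
  x <- us(v)
  cfg <- welch_config(window_length = 32, overlap_fraction = 0)
  S <- welch_spectra(x, x, cfg)
  expect_equal(S$n_windows, n_win)
  int_psd <- sum(S$psd_input) * (S$freqs[2] - S$freqs[1])
  nw <- 128
  taper <- 0.5 - 0.5 * cos(2 * pi * (0:(nw - 1)) / (nw - 1))
  starts <- (seq_len(n_win) - 1) * nw + 1
  # taper-power-corrected variance of the detrended segments
  mean_var <- mean(sapply(starts, function(s) {
    seg <- v[s:(s + nw - 1)]
    tt <- seq_len(nw)
    sum((residuals(lm(seg ~ tt)) * taper)^2) / sum(taper^2)
  }))
  expect_lt(abs(int_psd - mean_var) / mean_var, 0.01)
  # and for unit-variance white noise the integral sits near 1
  expect_lt(abs(int_psd - 1), 0.05)
})

test_that("normalized gain agrees between post-hoc and pre-normalized routes", {
  set.seed(37)
  xv <- 90 + 10 * sin(2 * pi * 0.05 * (0:959) / 4) + rnorm(960)
  yv <- 60 + 8 * sin(2 * pi * 0.05 * (0:959) / 4 + 0.4) + rnorm(960)
  S <- welch_spectra(us(xv), us(yv), welch_config())
  pm <- point_metrics(S, 0.05, mean_output_level = mean(yv))
  Sn <- welch_spectra(us(xv), us(yv / mean(yv) * 100), welch_config())
  pmn <- point_metrics(Sn, 0.05, mean_output_level = 100)
  expect_lt(abs(pm$ngain - pmn$gain) / pm$ngain, 1e-6)
})

test_that("point metrics read the exact bin and apply the coherence criterion", {
  # noiseless transfer: gain 0.8, phase +0.40 rad at 0.05 Hz
  tt <- (0:959) / 4
  xv <- 90 + 10 * sin(2 * pi * 0.05 * tt)
  yv <- 50 + 0.8 * 10 * sin(2 * pi * 0.05 * tt + 0.40)
  S <- welch_spectra(us(xv), us(yv), welch_config())
  pm <- point_metrics(S, 0.05, mean_output_level = 50)
  expect_equal(pm$frequency, 0.05)
  expect_lt(abs(pm$gain - 0.8) / 0.8, 0.02)
  expect_lt(abs(pm$phase - 0.40), 0.02)
  expect_gte(pm$coherence, 0.99)
  expect_equal(pm$ngain, pm$gain / 50 * 100)

  S$coherence[which.min(abs(S$freqs - 0.05))] <- 0.45
  expect_false(point_metrics(S, 0.05, 50)$coherence_pass)
  expect_error(point_metrics(S, 3, 50), class = "dcatfa_invalid_argument")
})

test_that("wraparound flag fires only on adjacent-bin jumps exceeding pi", {
  freqs <- seq(0, 0.5, by = 0.0125)
  smooth <- seq(0, 0.5, length.out = length(freqs))
  expect_false(detect_wraparound(smooth, freqs, c(0.02, 0.3)))
  jump <- smooth
  jump[20] <- jump[20] + 2 * pi
  expect_true(detect_wraparound(jump, freqs, c(0.02, 0.3)))
  expect_false(detect_wraparound(smooth, freqs, c(0.05, 0.055)))  # single bin
  expect_error(detect_wraparound(smooth, freqs, c(0.9, 1.0)),
               class = "dcatfa_invalid_argument")
})
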