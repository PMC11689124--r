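# Synthetic generator: pulse levels, forcing injection, transfer truths,
# PETCO2 clamping, cohort structure and determinism.

test_that("unforced BP waveform hits the prescribed beat count and levels", {
  rec <- simulate_bp_waveform(hr = 60, sbp = 120, dbp = 80, forcing_freq = 0,
                              forcing_amp = 0, duration = 60,
                              sample_rate = 100, rr_jitter_sd = 0, seed = 1)
  tb <- attr(rec, "beats")
  expect_true(abs(nrow(tb) - 60) <= 1)
  bt <- decompose_beats(rec$bp, c(tb$onset, tb$onset[nrow(tb)] + tb$rr[nrow(tb)]),
                        rec$sample_rate)
  expect_true(all(abs(bt$systolic - 120) / 120 < 0.01))
  expect_true(all(abs(bt$diastolic - 80) / 80 < 0.01))
})

test_that("forcing amplitude is recovered from the beat-mean series", {
  rec <- simulate_bp_waveform(hr = 75, sbp = 120, dbp = 80,
                              forcing_freq = 0.05, forcing_amp = 10,
                              duration = 240, sample_rate = 100, seed = 4)
  tb <- attr(rec, "beats")
  bt <- decompose_beats(rec$bp, c(tb$onset, tb$onset[nrow(tb)] + tb$rr[nrow(tb)]),
                        rec$sample_rate)
  fit <- sinusoid_fit(bt$beat_onset_time, bt$mean, 0.05)
  expect_lt(abs(fit$amplitude - 10) / 10, 0.05)
})

test_that("waveform preconditions are enforced", {
  expect_error(simulate_bp_waveform(hr = 25, sbp = 120, dbp = 80),
               class = "dcatfa_invalid_argument")
  expect_error(simulate_bp_waveform(hr = 60, sbp = 80, dbp = 120),
               class = "dcatfa_invalid_argument")
  expect_error(simulate_bp_waveform(hr = 60, sbp = 120, dbp = 80,
                                    duration = -1),
               class = "dcatfa_invalid_argument")
  expect_error(simulate_bp_waveform(hr = 35, sbp = 120, dbp = 80,
                                    forcing_freq = 0.4),
               class = "dcatfa_invalid_argument")
})

test_that("zero gain yields a flat velocity beat series; unit gain tracks BP", {
  rec <- simulate_bp_waveform(hr = 80, sbp = 120, dbp = 80,
                              forcing_freq = 0.05, forcing_amp = 10,
                              duration = 120, sample_rate = 100, seed = 6)
  zero <- data.frame(vessel = "MCA",
                     component = c("diastolic", "systolic"),
                     gain_true = 0, phase_true = 0,
                     baseline_velocity = c(40, 80))
  r0 <- apply_transfer(rec, zero, noise_sd = 0)
  tb <- attr(rec, "beats")
  ends <- c(tb$onset, tb$onset[nrow(tb)] + tb$rr[nrow(tb)])
  bt0 <- decompose_beats(r0$mcav, ends, 100)
  # constant up to sampling discretization of the pulse peak/foot
  expect_lt(diff(range(bt0$systolic)) / 80, 0.005)
  expect_lt(diff(range(bt0$diastolic)) / 40, 0.005)

  unit <- data.frame(vessel = "MCA", component = "mean", gain_true = 1,
                     phase_true = 0, baseline_velocity = 60)
  r1 <- apply_transfer(rec, unit, noise_sd = 0)
  btv <- decompose_beats(r1$mcav, ends, 100)
  btp <- decompose_beats(rec$bp, ends, 100)
  expect_gte(cor(btp$mean, btv$mean), 0.999)
})

test_that("injected phase lead shows up as a cross-correlation lead of phi/(2 pi f)", {
  rec <- simulate_bp_waveform(hr = 80, sbp = 120, dbp = 80,
                              forcing_freq = 0.05, forcing_amp = 10,
                              duration = 240, sample_rate = 100,
                              rr_jitter_sd = 0, seed = 8)
  tr <- data.frame(vessel = "MCA", component = "mean", gain_true = 0.8,
                   phase_true = 0.40, baseline_velocity = 60)
  rec <- apply_transfer(rec, tr, noise_sd = 0)
  tb <- attr(rec, "beats")
  ends <- c(tb$onset, tb$onset[nrow(tb)] + tb$rr[nrow(tb)])
  btp <- decompose_beats(rec$bp, ends, 100)
  btv <- decompose_beats(rec$mcav, ends, 100)
  # oracle: cross-correlation lag between the two beat-mean series on a
  # fine common grid
  grid <- seq(0, 230, by = 0.05)
  xp <- approx(btp$beat_onset_time, btp$mean - mean(btp$mean), grid)$y
  xv <- approx(btv$beat_onset_time, btv$mean - mean(btv$mean), grid)$y
  lags <- seq(-60, 60)
  cc <- sapply(lags, function(l) {
    i <- seq_along(grid)
    j <- i + l
    ok <- j >= 1 & j <= length(grid)
    cor(xp[i[ok]], xv[j[ok]])
  })
  lag_s <- lags[which.max(cc)] * 0.05
  expect_lt(abs(-lag_s - 0.40 / (2 * pi * 0.05)), 0.1)
})

test_that("PETCO2 clamping holds breath peaks at the stage target", {
  co2 <- simulate_petco2(40, breath_rate = 15, duration = 120,
                         sample_rate = 50, jitter_sd = 0, seed = 2)
  expect_true(all(abs(co2$truth$peak - 40) <= 1))
  co2b <- simulate_petco2(40, breath_rate = 20, duration = 60,
                          sample_rate = 50, jitter_sd = 0, seed = 3)
  expect_true(abs(nrow(co2b$truth) - 20) <= 1)
  lo <- simulate_petco2(25, duration = 60, sample_rate = 50, seed = 4)
  hi <- simulate_petco2(55, duration = 60, sample_rate = 50, seed = 4)
  expect_lt(abs(mean(hi$truth$peak) - mean(lo$truth$peak) - 30), 0.5)
  expect_error(simulate_petco2(-5), class = "dcatfa_invalid_argument")
})

test_that("cohort has one recording per participant x stage x frequency", {
  coh <- generate_cohort(cohort_spec(n_female = 2, n_male = 1,
                                     stages = c("eucapnia", "hypercapnia"),
                                     ssm_frequencies = 0.05, duration = 60,
                                     seed = 9))
  expect_length(coh$recordings, 3 * 2 * 1)
  expect_equal(nrow(coh$truth), 3 * 2 * 1 * 6)
  labs <- t(sapply(coh$recordings, function(r)
    unlist(r$labels[c("participant", "stage")])))
  expect_equal(anyDuplicated(labs), 0L)
})

test_that("identical spec and seed give byte-identical cohorts", {
  spec <- cohort_spec(n_female = 1, n_male = 1, stages = "eucapnia",
                      ssm_frequencies = 0.10, duration = 60, seed = 11)
  expect_identical(generate_cohort(spec), generate_cohort(spec))
})

test_that("default mean-component stage truths are ordered like CO2 physiology", {
  # phase: hypocapnia > eucapnia > hypercapnia; baseline velocity reversed
  derived <- lapply(c("hypocapnia", "eucapnia", "hypercapnia"), function(st)
    mean_component_truth(default_transfer_truths(st)))
  for (v in c("MCA", "PCA")) {
    ph <- sapply(derived, function(d) d$phase_true[d$vessel == v])
    expect_true(ph[1] > ph[2] && ph[2] > ph[3])
    bl <- sapply(derived, function(d) d$baseline_velocity[d$vessel == v])
    expect_true(bl[1] < bl[2] && bl[2] < bl[3])
  }
})

test_that("forced energy lands in the forcing frequency bin", {
  for (f in c(0.05, 0.10)) {
    rec <- simulate_bp_waveform(hr = 90, sbp = 120, dbp = 80,
                                forcing_freq = f, forcing_amp = 15,
                                duration = 240, sample_rate = 100, seed = 13)
    onsets <- detect_beats(rec$bp, 100)
    bt <- decompose_beats(rec$bp, onsets, 100)
    series <- spline_resample(bt, "mean", rate = 4, start = 0, duration = 240)
    S <- welch_spectra(series, series, welch_config())
    nonzero <- S$freqs > 0
    expect_equal(S$freqs[nonzero][which.max(S$psd_input[nonzero])], f)
  }
})

test_that("metronome transition counts follow the pacing frequency", {
  expect_equal(transitions_per_minute(0.05), 6)
  expect_equal(transitions_per_minute(0.10), 12)
  expect_error(transitions_per_minute(0), class = "dcatfa_invalid_argument")
})
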