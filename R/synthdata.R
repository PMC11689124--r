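# Synthetic squat-stand cohort generator.
#
# Squat-stand manoeuvres (SSMs) paced at 0.05 or 0.10 Hz drive large,
# near-sinusoidal oscillations in arterial blood pressure (BP). The
# generator emulates those recordings with known ground truth: a pulsatile
# BP wave whose per-beat diastolic and systolic levels carry an additive
# sinusoid at the pacing frequency, cerebral blood velocity (CBv) channels
# obtained by a component-specific linear transfer (gain, phase lead,
# baseline), and a breath-wise end-tidal CO2 trace clamped near a stage
# target. Forcing enters the per-beat levels additively so that the
# injected transfer is exactly linear and can be recovered by the spectral
# pipeline without model error.

#' Simulate a pulsatile blood-pressure waveform with sinusoidal forcing
#'
#' Generates an arterial pressure trace as a train of parametric pulses
#' (see [pulse_shape_params()]) whose per-beat diastolic and systolic
#' levels each carry an additive sinusoid `forcing_amp * sin(2*pi*
#' forcing_freq * t_onset)`, emulating paced squat-stand oscillations.
#' Beat-to-beat R-R intervals get Gaussian jitter with sd 2% of the mean
#' interval, truncated at +/-10%.
#'
#' @param hr Mean heart rate, beats/min; must lie in \[30, 220\] and exceed
#'   twice the forcing frequency.
#' @param sbp,dbp Baseline systolic and diastolic pressure, mmHg (`dbp < sbp`).
#' @param forcing_freq Forcing frequency, Hz (0.05 or 0.10 for SSMs; 0 for
#'   an unforced trace).
#' @param forcing_amp Forcing amplitude, mmHg (>= 0).
#' @param duration Record length, s.
#' @param sample_rate Sampling rate, Hz.
#' @param pulse Pulse kernel parameters, a [pulse_shape_params()] object.
#' @param rr_jitter_sd R-R jitter sd as a fraction of the mean interval.
#' @param seed Integer seed; the caller's RNG state is untouched.
#' @return A `raw_recording` with the `bp` channel filled in. The attribute
#'   `"beats"` holds the ground-truth beat table (onset, rr, diastolic and
#'   systolic levels) and `"forcing"` the forcing frequency/amplitude, both
#'   used by [apply_transfer()] and by tests.
#' @export
simulate_bp_waveform <- function(hr, sbp, dbp, forcing_freq = 0,
                                 forcing_amp = 0, duration = 240,
                                 sample_rate = 100,
                                 pulse = pulse_shape_params(),
                                 rr_jitter_sd = 0.02, seed = NULL) {
  check_scalar(duration, "duration", 0, strict_lower = TRUE)
  check_scalar(sample_rate, "sample_rate", 0, strict_lower = TRUE)
  check_scalar(hr, "hr", 30, 220)
  check_scalar(forcing_freq, "forcing_freq", 0)
  check_scalar(forcing_amp, "forcing_amp", 0)
  check_scalar(rr_jitter_sd, "rr_jitter_sd", 0)
  if (dbp >= sbp)
    stop_dcatfa("dbp must be below sbp", "dcatfa_invalid_argument")
  if (hr / 60 <= 2 * forcing_freq)
    stop_dcatfa("heart rate must exceed twice the forcing frequency",
                "dcatfa_invalid_argument")

  with_seed(seed, {
    rr0 <- 60 / hr
    n_beat_max <- ceiling(duration / rr0 * 1.25) + 2L
    jit <- rnorm_trunc(n_beat_max, 0, rr_jitter_sd, -0.10, 0.10)
    rr <- rr0 * (1 + jit)
    onsets <- c(0, cumsum(rr))
    keep <- seq_len(min(which(onsets >= duration)))
    onsets <- onsets[keep]
    n_beat <- length(onsets) - 1L
    osc <- forcing_amp * sin(2 * pi * forcing_freq * onsets)
    dias <- dbp + osc
    sys <- (sbp + osc)[seq_len(n_beat)]
    time <- seq(0, by = 1 / sample_rate, length.out = round(duration * sample_rate))
    bp <- pulse_train(time, onsets, dias, sys, pulse)
    rec <- new_raw_recording(time, bp = bp, sample_rate = sample_rate)
    attr(rec, "beats") <- data.frame(
      onset = onsets[seq_len(n_beat)],
      rr = diff(onsets),
      dias_level = dias[seq_len(n_beat)],
      sys_level = sys)
    attr(rec, "forcing") <- list(freq = forcing_freq, amp = forcing_amp)
    attr(rec, "pulse") <- pulse
    rec
  })
}

#' Transfer-parameter truth table for one vessel
#'
#' Convenience constructor for the per-component truth rows consumed by
#' [apply_transfer()]. Diastolic and systolic rows are the primitives; the
#' mean-component truth is derived from them (see [apply_transfer()]).
#'
#' @param vessel `"MCA"` or `"PCA"`.
#' @param gain Named vector `c(diastolic = , systolic = )`, cm/s/mmHg (>= 0).
#' @param phase Named vector `c(diastolic = , systolic = )`, radians in
#'   (-pi, pi\]; positive means velocity leads pressure.
#' @param baseline Named vector `c(diastolic = , systolic = )`, cm/s (> 0):
#'   the unforced per-beat velocity levels.
#' @return A data frame with one row per component.
#' @export
transfer_truth <- function(vessel, gain, phase, baseline) {
  vessel <- match.arg(vessel, c("MCA", "PCA"))
  comp <- c("diastolic", "systolic")
  for (v in list(gain, phase, baseline))
    if (!all(comp %in% names(v)))
      stop_dcatfa("gain/phase/baseline need `diastolic` and `systolic` entries",
                  "dcatfa_invalid_argument")
  if (any(gain[comp] < 0))
    stop_dcatfa("gain_true must be non-negative", "dcatfa_invalid_argument")
  if (any(phase[comp] <= -pi | phase[comp] > pi))
    stop_dcatfa("phase_true must lie in (-pi, pi]", "dcatfa_invalid_argument")
  if (any(baseline[comp] <= 0))
    stop_dcatfa("baseline_velocity must be positive", "dcatfa_invalid_argument")
  if (baseline["diastolic"] >= baseline["systolic"])
    stop_dcatfa("diastolic baseline must be below systolic baseline",
                "dcatfa_invalid_argument")
  data.frame(vessel = vessel, component = comp,
             gain_true = unname(gain[comp]),
             phase_true = unname(phase[comp]),
             baseline_velocity = unname(baseline[comp]))
}

# Combine diastolic and systolic truth phasors into the implied
# mean-component truth. The beat mean of the kernel decomposes as
#   mean_i = a * d_i + b * d_{i+1} + ws * s_i,
# a = sf/2 (upstroke from this beat's foot), b = (1-sf)(1-gbar) (run-off
# toward the next foot), ws = sf/2 + (1-sf)*gbar, gbar the run-off time
# average. The next foot leads this one by Delta = 2*pi*f*rr. The same
# decomposition applies to the BP beat mean, whose diastolic and systolic
# levels share one oscillation, so the mean-component transfer truth is
# the ratio of the velocity and BP mean-oscillation phasors:
#   H_mean = [(a + b e^{iD}) Gd e^{i phd} + ws Gs e^{i phs}] /
#            [(1 - b) + b e^{iD}].
derive_mean_truth <- function(truth_vessel, pulse, rr_mean, freq) {
  d <- truth_vessel[truth_vessel$component == "diastolic", ]
  s <- truth_vessel[truth_vessel$component == "systolic", ]
  sf <- pulse$systolic_fraction
  x <- pulse$decay_rate * (1 - sf) * rr_mean
  E <- exp(-x)
  gbar <- (1 - E - x * E) / (x * (1 - E))
  a <- sf / 2
  b <- (1 - sf) * (1 - gbar)
  ws <- sf / 2 + (1 - sf) * gbar
  delta <- 2 * pi * freq * rr_mean
  z <- ((a + b * exp(1i * delta)) * d$gain_true * exp(1i * d$phase_true) +
          ws * s$gain_true * exp(1i * s$phase_true)) /
    ((1 - b) + b * exp(1i * delta))
  data.frame(vessel = d$vessel, component = "mean",
             gain_true = Mod(z), phase_true = Arg(z),
             baseline_velocity = (a + b) * d$baseline_velocity +
               ws * s$baseline_velocity)
}

#' Mean-component transfer truth implied by diastolic/systolic truths
#'
#' Computes, without simulating, the effective mean-component gain/phase
#' that [apply_transfer()] realizes for a given diastolic + systolic truth
#' table, pulse shape, mean R-R interval and forcing frequency.
#'
#' @param truths Truth rows (diastolic + systolic per vessel), as from
#'   [default_transfer_truths()].
#' @param pulse Pulse kernel parameters.
#' @param rr Mean R-R interval, s.
#' @param ssm_freq Forcing frequency, Hz.
#' @return One derived `mean` truth row per vessel.
#' @export
mean_component_truth <- function(truths, pulse = pulse_shape_params(),
                                 rr = 60 / 90, ssm_freq = 0.05) {
  out <- lapply(unique(truths$vessel), function(v) {
    derive_mean_truth(truths[truths$vessel == v, ], pulse, rr, ssm_freq)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Add cerebral-blood-velocity channels by linear transfer from BP
#'
#' For each vessel, per-beat diastolic and systolic velocity levels are set
#' to `baseline + gain_true * A * sin(2*pi*f*t_onset + phase_true) +
#' N(0, noise_sd)`, where `A` and `f` are the forcing amplitude and
#' frequency stored in the BP recording, and a velocity pulse train is
#' built on the same beat boundaries. A two-level pulse kernel cannot carry
#' three independent component truths, so the mean-component truth is
#' derived from the diastolic and systolic phasors via
#' `Gm * exp(i*phm) = (1-w) * Gd * exp(i*phd) + w * Gs * exp(i*phs)`,
#' with `w` the kernel's analytic mean weight at the mean R-R interval; the
#' returned truth table contains all three components per vessel.
#'
#' Supplying only a `mean` row for a vessel applies that gain/phase to both
#' levels (the derived mean then equals it exactly).
#'
#' @param rec A `raw_recording` from [simulate_bp_waveform()] (must carry
#'   the `"beats"` and `"forcing"` attributes).
#' @param truths Data frame with columns vessel, component, gain_true,
#'   phase_true, baseline_velocity; rows for components `diastolic` and
#'   `systolic` (or a single `mean` row) per vessel.
#' @param noise_sd Per-beat Gaussian noise on the velocity levels, cm/s.
#' @param seed Integer seed for the noise.
#' @return The recording with `mcav`/`pcav` channels filled for the vessels
#'   present in `truths`; attribute `"transfer_truth"` holds the effective
#'   per-component truth table (including the derived mean rows).
#' @export
apply_transfer <- function(rec, truths, noise_sd = 0, seed = NULL) {
  if (is.null(rec$bp))
    stop_dcatfa("recording has no bp channel", "dcatfa_missing_channel")
  beats <- attr(rec, "beats")
  forcing <- attr(rec, "forcing")
  if (is.null(beats) || is.null(forcing))
    stop_dcatfa("recording lacks simulator beat/forcing ground truth",
                "dcatfa_invalid_argument")
  if (any(truths$gain_true < 0))
    stop_dcatfa("gain_true must be non-negative", "dcatfa_invalid_argument")
  check_scalar(noise_sd, "noise_sd", 0)
  pulse <- attr(rec, "pulse")
  if (is.null(pulse)) pulse <- pulse_shape_params()

  onsets <- c(beats$onset, beats$onset[nrow(beats)] + beats$rr[nrow(beats)])
  n_beat <- nrow(beats)
  theta <- 2 * pi * forcing$freq * onsets
  rr_mean <- mean(beats$rr)

  truth_out <- list()
  with_seed(seed, {
    for (vessel in unique(truths$vessel)) {
      tv <- truths[truths$vessel == vessel, ]
      if (!all(c("diastolic", "systolic") %in% tv$component)) {
        if ("mean" %in% tv$component) {
          m <- tv[tv$component == "mean", ]
          tv <- rbind(
            transform(m, component = "diastolic",
                      baseline_velocity = m$baseline_velocity * 0.7),
            transform(m, component = "systolic",
                      baseline_velocity = m$baseline_velocity * 1.45))
        } else {
          stop_dcatfa("truths must include diastolic+systolic (or mean) rows",
                      "dcatfa_invalid_argument")
        }
      }
      d <- tv[tv$component == "diastolic", ]
      s <- tv[tv$component == "systolic", ]
      A <- forcing$amp
      dias <- d$baseline_velocity +
        d$gain_true * A * sin(theta + d$phase_true) +
        rnorm(n_beat + 1L, 0, noise_sd)
      sys <- (s$baseline_velocity +
                s$gain_true * A * sin(theta + s$phase_true))[seq_len(n_beat)] +
        rnorm(n_beat, 0, noise_sd)
      chan <- if (vessel == "MCA") "mcav" else "pcav"
      rec[[chan]] <- pulse_train(rec$time, onsets, dias, sys, pulse)
      truth_out[[vessel]] <- rbind(
        d, derive_mean_truth(rbind(d, s), pulse, rr_mean, forcing$freq), s)
    }
  })
  tt <- do.call(rbind, truth_out)
  rownames(tt) <- NULL
  attr(rec, "transfer_truth") <- tt
  rec
}

#' Simulate a breath-wise end-tidal CO2 trace clamped at a stage target
#'
#' Each breath is a raised-cosine excursion from `stage_target - depth` up
#' to a peak at `stage_target` (plus per-breath Gaussian jitter), emulating
#' dynamic end-tidal forcing that holds the end-tidal peak within 1 mmHg of
#' the clamp target. Breath-to-breath period jitter is 2% (truncated).
#'
#' @param stage_target Clamp target, mmHg (> 0).
#' @param breath_rate Breaths/min, in \[6, 40\].
#' @param duration Record length, s.
#' @param sample_rate Sampling rate, Hz.
#' @param jitter_sd Per-breath peak jitter sd, mmHg.
#' @param depth Within-breath excursion below the peak, mmHg.
#' @param seed Integer seed.
#' @return List with `time`, `petco2`, `sample_rate` and a `truth` data
#'   frame of per-breath peak times and values.
#' @export
simulate_petco2 <- function(stage_target, breath_rate = 15, duration = 240,
                            sample_rate = 100, jitter_sd = 0, depth = 8,
                            seed = NULL) {
  check_scalar(stage_target, "stage_target", 0, strict_lower = TRUE)
  check_scalar(breath_rate, "breath_rate", 6, 40)
  check_scalar(duration, "duration", 0, strict_lower = TRUE)
  check_scalar(sample_rate, "sample_rate", 0, strict_lower = TRUE)
  with_seed(seed, {
    per0 <- 60 / breath_rate
    n_max <- ceiling(duration / per0 * 1.25) + 2L
    per <- per0 * (1 + rnorm_trunc(n_max, 0, 0.02, -0.10, 0.10))
    onsets <- c(0, cumsum(per))
    onsets <- onsets[seq_len(min(which(onsets >= duration)))]
    n_breath <- length(onsets) - 1L
    peaks <- stage_target + rnorm(n_breath, 0, jitter_sd)
    time <- seq(0, by = 1 / sample_rate,
                length.out = round(duration * sample_rate))
    idx <- pmin(pmax(findInterval(time, onsets), 1L), n_breath)
    u <- (time - onsets[idx]) / (onsets[idx + 1L] - onsets[idx])
    u <- pmin(pmax(u, 0), 1)
    petco2 <- (peaks[idx] - depth) + depth * (1 - cos(2 * pi * u)) / 2
    list(time = time, petco2 = petco2, sample_rate = sample_rate,
         truth = data.frame(onset = onsets[seq_len(n_breath)],
                            peak_time = onsets[seq_len(n_breath)] +
                              (onsets[-1L] - onsets[seq_len(n_breath)]) / 2,
                            peak = peaks))
  })
}

#' Squat-stand transitions per minute for a pacing frequency
#'
#' One squat and one stand per oscillation cycle, hence
#' `2 * ssm_freq * 60` transitions per minute: 6/min at 0.05 Hz and
#' 12/min at 0.10 Hz (the metronome settings used to pace the manoeuvres).
#'
#' @param ssm_freq Pacing frequency, Hz (> 0).
#' @return Transitions per minute.
#' @export
transitions_per_minute <- function(ssm_freq) {
  check_scalar(ssm_freq, "ssm_freq", 0, strict_lower = TRUE)
  2 * ssm_freq * 60
}
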