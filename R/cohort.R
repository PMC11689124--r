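# Cohort-level simulation: one recording per participant x CO2 stage x
# SSM frequency, with per-participant physiology and per-recording
# transfer truths recorded in a ground-truth table.

#' Specification of a synthetic squat-stand cohort
#'
#' Defaults emulate the study design: 10 female + 10 male participants,
#' three CO2 stages (clamp targets 25/40/55 mmHg), SSMs at 0.05 and
#' 0.10 Hz, 4-min records sampled at 100 Hz, heart rates 80-105 beats/min.
#'
#' @param n_female,n_male Participant counts.
#' @param stages Subset of `c("hypocapnia", "eucapnia", "hypercapnia")`.
#' @param ssm_frequencies Pacing frequencies, Hz (subset of 0.05/0.10).
#' @param duration Record length per recording, s.
#' @param sample_rate Sampling rate, Hz (>= 20).
#' @param petco2_targets Named clamp targets per stage, mmHg.
#' @param forcing_amplitude BP forcing amplitude, mmHg.
#' @param noise_sd Per-beat velocity noise, cm/s.
#' @param hr_range Heart-rate range across participants, beats/min.
#' @param breath_rate Breathing rate for the PETCO2 channel, breaths/min.
#' @param seed Integer master seed; the whole cohort is a deterministic
#'   function of the spec including this seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_female = 10, n_male = 10,
                        stages = c("hypocapnia", "eucapnia", "hypercapnia"),
                        ssm_frequencies = c(0.05, 0.10),
                        duration = 240, sample_rate = 100,
                        petco2_targets = c(hypocapnia = 25, eucapnia = 40,
                                           hypercapnia = 55),
                        forcing_amplitude = 15, noise_sd = 2,
                        hr_range = c(80, 105), breath_rate = 15,
                        seed = 1L) {
  stages <- match.arg(stages, c("hypocapnia", "eucapnia", "hypercapnia"),
                      several.ok = TRUE)
  if (length(stages) == 0L || length(ssm_frequencies) == 0L)
    stop_dcatfa("stages and ssm_frequencies must be non-empty",
                "dcatfa_invalid_argument")
  check_scalar(duration, "duration", 0, strict_lower = TRUE)
  check_scalar(sample_rate, "sample_rate", 20)
  check_scalar(forcing_amplitude, "forcing_amplitude", 0)
  check_scalar(noise_sd, "noise_sd", 0)
  if (any(petco2_targets[stages] <= 0))
    stop_dcatfa("petco2_targets must be positive", "dcatfa_invalid_argument")
  structure(list(n_female = n_female, n_male = n_male, stages = stages,
                 ssm_frequencies = ssm_frequencies, duration = duration,
                 sample_rate = sample_rate, petco2_targets = petco2_targets,
                 forcing_amplitude = forcing_amplitude, noise_sd = noise_sd,
                 hr_range = hr_range, breath_rate = breath_rate,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default stage-level transfer truths
#'
#' Diastolic and systolic gain/phase defaults per vessel and stage, loosely
#' calibrated to the magnitudes reported for cardiac-cycle-resolved TFA
#' during squat-stand manoeuvres (gain roughly 0.2-1.1 cm/s/mmHg, phase
#' roughly 0.2-1.9 rad) and ordered so that phase falls and baseline
#' velocity rises from hypocapnia through eucapnia to hypercapnia (CO2
#' vasodilation raises velocity and erodes the autoregulatory phase lead).
#' These are emulation defaults, not estimates of any real cohort. The
#' mean-component truth implied by these rows preserves the same stage
#' ordering.
#'
#' @param stage One of `"hypocapnia"`, `"eucapnia"`, `"hypercapnia"`.
#' @return A data frame of truth rows (both vessels, diastolic + systolic),
#'   suitable for [apply_transfer()].
#' @export
default_transfer_truths <- function(stage = c("eucapnia", "hypocapnia",
                                              "hypercapnia")) {
  stage <- match.arg(stage)
  p <- switch(stage,
    hypocapnia = list(
      MCA = list(gain = c(diastolic = 0.77, systolic = 0.40),
                 phase = c(diastolic = 0.68, systolic = 1.93),
                 baseline = c(diastolic = 32, systolic = 68)),
      PCA = list(gain = c(diastolic = 0.62, systolic = 0.20),
                 phase = c(diastolic = 0.62, systolic = 1.83),
                 baseline = c(diastolic = 22, systolic = 46))),
    eucapnia = list(
      MCA = list(gain = c(diastolic = 0.98, systolic = 0.46),
                 phase = c(diastolic = 0.52, systolic = 0.93),
                 baseline = c(diastolic = 42, systolic = 88)),
      PCA = list(gain = c(diastolic = 0.68, systolic = 0.28),
                 phase = c(diastolic = 0.44, systolic = 0.93),
                 baseline = c(diastolic = 28, systolic = 58))),
    hypercapnia = list(
      MCA = list(gain = c(diastolic = 1.12, systolic = 0.53),
                 phase = c(diastolic = 0.22, systolic = 0.41),
                 baseline = c(diastolic = 52, systolic = 108)),
      PCA = list(gain = c(diastolic = 0.66, systolic = 0.33),
                 phase = c(diastolic = 0.22, systolic = 0.35),
                 baseline = c(diastolic = 35, systolic = 72))))
  rbind(transfer_truth("MCA", p$MCA$gain, p$MCA$phase, p$MCA$baseline),
        transfer_truth("PCA", p$PCA$gain, p$PCA$phase, p$PCA$baseline))
}

#' Generate a synthetic squat-stand cohort
#'
#' Produces one `raw_recording` per participant x stage x SSM frequency,
#' deterministically from the spec's seed. Per participant, heart rate is
#' drawn uniformly from `hr_range`, baseline pressures around 120/80 mmHg,
#' and individual deviations are applied to the stage-level transfer
#' truths (log-normal gain multipliers, Gaussian phase offsets, baseline
#' velocity shifts, plus a small positive velocity offset for female
#' participants). The effective per-recording truths, including the derived
#' mean component, are returned in a long ground-truth table.
#'
#' @param spec A [cohort_spec()].
#' @return List with `recordings` (list of `raw_recording`, labelled with
#'   participant/sex/stage/ssm_frequency) and `truth` (data frame:
#'   participant, sex, vessel, component, stage, ssm_frequency_hz,
#'   gain_true, phase_true, baseline_velocity).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_female + spec$n_male
  if (n < 1L)
    stop_dcatfa("cohort must contain at least one participant",
                "dcatfa_invalid_argument")
  sex <- c(rep("female", spec$n_female), rep("male", spec$n_male))
  ids <- sprintf("P%02d", seq_len(n))

  recordings <- list()
  truth <- list()
  with_seed(spec$seed, {
    hr <- runif(n, spec$hr_range[1], spec$hr_range[2])
    sbp <- rnorm(n, 120, 8)
    dbp <- pmin(rnorm(n, 80, 6), sbp - 25)
    gain_mult <- matrix(exp(rnorm(n * 2, 0, 0.08)), n, 2,
                        dimnames = list(NULL, c("MCA", "PCA")))
    phase_off <- matrix(rnorm(n * 2, 0, 0.04), n, 2,
                        dimnames = list(NULL, c("MCA", "PCA")))
    base_off <- matrix(rnorm(n * 2, 0, 3), n, 2,
                       dimnames = list(NULL, c("MCA", "PCA")))
    sex_shift <- ifelse(sex == "female", 3, 0)  # cm/s, on velocity baselines

    for (i in seq_len(n)) {
      for (stage in spec$stages) {
        truths <- default_transfer_truths(stage)
        for (vessel in c("MCA", "PCA")) {
          sel <- truths$vessel == vessel
          truths$gain_true[sel] <- truths$gain_true[sel] * gain_mult[i, vessel]
          truths$phase_true[sel] <- truths$phase_true[sel] + phase_off[i, vessel]
          truths$baseline_velocity[sel] <- truths$baseline_velocity[sel] +
            base_off[i, vessel] + sex_shift[i]
        }
        for (f in spec$ssm_frequencies) {
          rec <- simulate_bp_waveform(
            hr = hr[i], sbp = sbp[i], dbp = dbp[i], forcing_freq = f,
            forcing_amp = spec$forcing_amplitude, duration = spec$duration,
            sample_rate = spec$sample_rate)
          rec <- apply_transfer(rec, truths, noise_sd = spec$noise_sd)
          co2 <- simulate_petco2(
            stage_target = spec$petco2_targets[[stage]],
            breath_rate = spec$breath_rate, duration = spec$duration,
            sample_rate = spec$sample_rate, jitter_sd = 0.3)
          rec$petco2 <- co2$petco2
          rec$labels <- list(participant = ids[i], sex = sex[i],
                             stage = stage, ssm_frequency = f)
          key <- sprintf("%s_%s_%.2f", ids[i], stage, f)
          recordings[[key]] <- rec
          tt <- attr(rec, "transfer_truth")
          truth[[key]] <- data.frame(
            participant = ids[i], sex = sex[i], vessel = tt$vessel,
            component = tt$component, stage = stage, ssm_frequency_hz = f,
            gain_true = tt$gain_true, phase_true = tt$phase_true,
            baseline_velocity = tt$baseline_velocity)
        }
      }
    }
  })
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(recordings = recordings, truth = truth)
}
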