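# Beat detection and cardiac-cycle decomposition.
#
# Beats are located on the arterial pressure wave at the diastolic foot
# (the local minimum preceding the systolic upstroke); the same boundaries
# are applied to the velocity channels so that per-beat systolic/diastolic/
# mean series stay aligned across channels. A beat spans the half-open
# interval [onset_i, onset_{i+1}) so every sample belongs to exactly one
# beat.

#' Detect cardiac beat onsets (pressure feet) in a pulsatile trace
#'
#' Systolic peaks are found on a high-passed copy of the trace (the running
#' median over ~1.5 beats removes the slow forcing oscillation), with a
#' refractory period of `60/hr_bounds[2]` seconds; each beat onset is then
#' the sample-level minimum between consecutive peaks, plus the foot
#' preceding the first peak.
#'
#' @param x Numeric trace (mmHg or cm/s).
#' @param sample_rate Sampling rate, Hz.
#' @param hr_bounds Plausible heart-rate range, beats/min, within
#'   \[30, 220\].
#' @return Vector of onset times in seconds.
#' @export
detect_beats <- function(x, sample_rate, hr_bounds = c(40, 180)) {
  if (length(x) / sample_rate < 10)
    stop_dcatfa("trace shorter than 10 s", "dcatfa_invalid_argument")
  if (hr_bounds[1] < 30 || hr_bounds[2] > 220 || hr_bounds[1] >= hr_bounds[2])
    stop_dcatfa("hr_bounds must lie within [30, 220]", "dcatfa_invalid_argument")
  if (sd(x) == 0)
    stop_dcatfa("flat trace: no beats to detect", "dcatfa_flat_trace")

  refractory <- 60 / hr_bounds[2]
  k <- ceiling(1.5 * 60 / hr_bounds[1] * sample_rate)
  if (k %% 2 == 0) k <- k + 1L
  k <- min(k, if (length(x) %% 2 == 0) length(x) - 1L else length(x))
  z <- x - runmed(x, k)
  thr <- 0.3 * quantile(z, 0.98)

  peaks <- find_peaks(z, min_dist = round(refractory * sample_rate), thr = thr)
  if (length(peaks) < 2L)
    stop_dcatfa("fewer than 2 systolic peaks detected", "dcatfa_too_few_beats")

  onsets <- integer(length(peaks))
  # foot preceding the first peak: minimum over up to one slow-beat window
  lo <- max(1L, peaks[1] - ceiling(60 / hr_bounds[1] * sample_rate))
  onsets[1] <- lo - 1L + which.min(x[lo:peaks[1]])
  for (j in seq_len(length(peaks) - 1L)) {
    seg <- peaks[j]:peaks[j + 1L]
    onsets[j + 1L] <- seg[which.min(x[seg])]
  }
  onsets <- unique(onsets)
  if (length(onsets) < 8L)
    stop_dcatfa("fewer than 8 beats detected: record too short for spectral analysis",
                "dcatfa_too_few_beats")
  (onsets - 1L) / sample_rate
}

# Local maxima above `thr`, separated by at least `min_dist` samples;
# among conflicting candidates the larger wins.
find_peaks <- function(z, min_dist, thr = -Inf) {
  n <- length(z)
  cand <- which(z > thr)
  cand <- cand[cand > 1L & cand < n]
  cand <- cand[z[cand] >= z[cand - 1L] & z[cand] >= z[cand + 1L]]
  if (length(cand) == 0L) return(integer())
  cand <- cand[order(z[cand], decreasing = TRUE)]
  taken <- integer()
  for (i in cand) {
    if (length(taken) == 0L || min(abs(taken - i)) >= min_dist) {
      taken <- c(taken, i)
    }
  }
  sort(taken)
}

#' Decompose a trace into per-beat systolic, diastolic and mean values
#'
#' For each beat `[onset_i, onset_{i+1})`: systolic = maximum sample,
#' diastolic = minimum sample, mean = arithmetic mean of all samples in the
#' beat; the R-R interval is the onset spacing and heart rate 60/RR.
#'
#' @param x Numeric trace.
#' @param onsets Beat onset times in seconds (from [detect_beats()]),
#'   strictly increasing; at least 2.
#' @param sample_rate Sampling rate, Hz.
#' @return A `beat_table` data frame: beat_onset_time, systolic, diastolic,
#'   mean, rr_interval, heart_rate, corrected_flag.
#' @export
decompose_beats <- function(x, onsets, sample_rate) {
  if (length(onsets) < 2L)
    stop_dcatfa("need at least 2 beat boundaries", "dcatfa_invalid_argument")
  if (is.unsorted(onsets, strictly = TRUE))
    stop_dcatfa("beat boundaries must be strictly increasing",
                "dcatfa_invalid_argument")
  idx <- round(onsets * sample_rate) + 1L
  # drop boundaries beyond the trace: a final beat without its closing
  # boundary inside the record cannot be decomposed
  keep <- idx <= length(x) + 1L
  idx <- idx[keep]
  onsets <- onsets[keep]
  if (length(onsets) < 2L)
    stop_dcatfa("no complete beat inside the trace", "dcatfa_invalid_argument")
  n_beat <- length(onsets) - 1L
  out <- data.frame(beat_onset_time = onsets[seq_len(n_beat)],
                    systolic = NA_real_, diastolic = NA_real_,
                    mean = NA_real_,
                    rr_interval = diff(onsets),
                    heart_rate = 60 / diff(onsets),
                    corrected_flag = FALSE)
  for (i in seq_len(n_beat)) {
    seg <- x[idx[i]:(idx[i + 1L] - 1L)]
    out$systolic[i] <- max(seg)
    out$diastolic[i] <- min(seg)
    out$mean[i] <- mean(seg)
  }
  class(out) <- c("beat_table", "data.frame")
  out
}

#' Flag and correct systolic artifacts in a beat table
#'
#' Automates the interpolation of corrupted systolic peaks: beats whose
#' systolic value deviates from an 11-beat rolling median by more than
#' `z_threshold` robust standard deviations (1.4826 x MAD of the rolling
#' residuals) are replaced by cubic-spline interpolation of the
#' neighbouring uncorrupted systolic values and flagged.
#'
#' @param bt A `beat_table` (>= 5 beats).
#' @param z_threshold Robust z cut-off (> 0). Default 4.
#' @param window Rolling-median window, beats (odd). Default 11.
#' @return The corrected `beat_table`; attribute `"corrected_fraction"`
#'   holds the fraction of beats corrected. Refuses (errors) if more than
#'   half the beats would be flagged.
#' @export
flag_and_correct_artifacts <- function(bt, z_threshold = 4, window = 11) {
  if (nrow(bt) < 5L)
    stop_dcatfa("need at least 5 beats", "dcatfa_invalid_argument")
  check_scalar(z_threshold, "z_threshold", 0, strict_lower = TRUE)
  k <- min(window, if (nrow(bt) %% 2 == 0) nrow(bt) - 1L else nrow(bt))
  med <- runmed(bt$systolic, k)
  resid <- bt$systolic - med
  # plausibility guard: genuine systolic peaks do not depart from an
  # 11-beat rolling median by >10% in a majority of beats; a table that
  # does is corrupted wholesale and interpolation would be meaningless
  if (mean(abs(resid) > 0.1 * median(bt$systolic)) > 0.5)
    stop_dcatfa("majority of beats deviate grossly: refusing silent mass correction",
                "dcatfa_mass_artifact")
  robust_sd <- mad(resid)
  flagged <- if (robust_sd > 0) abs(resid) > z_threshold * robust_sd
             else rep(FALSE, nrow(bt))
  if (mean(flagged) > 0.5)
    stop_dcatfa("majority of beats flagged: refusing silent mass correction",
                "dcatfa_mass_artifact")
  if (any(flagged)) {
    ok <- which(!flagged)
    bad <- which(flagged)
    interp <- spline(bt$beat_onset_time[ok], bt$systolic[ok],
                     xout = bt$beat_onset_time[bad], method = "natural")$y
    bt$systolic[bad] <- pmax(interp, bt$mean[bad])
    bt$corrected_flag[bad] <- TRUE
  }
  attr(bt, "corrected_fraction") <- mean(flagged)
  bt
}

#' Extract breath-to-breath end-tidal CO2 peaks
#'
#' Per-breath maxima located with a refractory period of
#' `60/breath_bounds[2]` seconds.
#'
#' @param petco2 Numeric PETCO2 trace, mmHg.
#' @param sample_rate Sampling rate, Hz.
#' @param breath_bounds Plausible breathing-rate range, breaths/min.
#' @return A `breath_table` data frame (breath_time, petco2_peak) with
#'   attributes `"mean_peak"` and `"sd_peak"`.
#' @export
extract_breath_peaks <- function(petco2, sample_rate, breath_bounds = c(6, 40)) {
  if (length(petco2) / sample_rate < 30)
    stop_dcatfa("PETCO2 trace shorter than 30 s", "dcatfa_invalid_argument")
  if (sd(petco2) == 0)
    stop_dcatfa("flat PETCO2 trace", "dcatfa_flat_trace")
  min_dist <- round(60 / breath_bounds[2] * sample_rate)
  z <- petco2 - median(petco2)
  peaks <- find_peaks(z, min_dist = min_dist, thr = 0.25 * quantile(z, 0.98))
  out <- data.frame(breath_time = (peaks - 1L) / sample_rate,
                    petco2_peak = petco2[peaks])
  class(out) <- c("breath_table", "data.frame")
  attr(out, "mean_peak") <- mean(out$petco2_peak)
  attr(out, "sd_peak") <- sd(out$petco2_peak)
  out
}
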