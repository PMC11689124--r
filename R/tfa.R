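# Transfer function analysis: uniform resampling of beat-to-beat series,
# Welch auto/cross spectra with Hanning tapering, and coherence/phase/
# gain/nGain point estimates at the forcing frequencies.
#
# Conventions. Coherence is magnitude-squared (|Sxy|^2 / (Pxx * Pyy), in
# [0, 1]); phase is arg(Sxy) with Sxy = mean(conj(X) * Y), so a delayed
# output y(t) = x(t - tau) yields phase -2*pi*f*tau and a positive phase
# means the output (velocity) leads the input (pressure) - the reading
# associated with active autoregulation. Gain is |Sxy| / Pxx (cm/s/mmHg);
# normalized gain divides by the output series' own segment mean and is
# expressed in %/mmHg. With the default 4 Hz rate and 80-s windows the
# frequency step is 0.0125 Hz, so 0.05 and 0.10 Hz fall on exact bins
# (4 and 8): point estimates are single-bin reads, not band averages.

#' Resample a beat-to-beat component series onto a uniform grid
#'
#' Cubic-spline interpolation of (beat time, component value) points
#' evaluated on a uniform grid, the standard preprocessing before spectral
#' estimation of beat-to-beat series. Outside the observed beat span the
#' series is held at the nearest beat value (no spline extrapolation).
#'
#' @param bt A `beat_table` with at least 8 beats.
#' @param component `"mean"`, `"systolic"` or `"diastolic"`.
#' @param rate Target rate, Hz. Default 4.
#' @param start,duration Optional grid origin and length, s; default to the
#'   observed beat span. The pipeline passes the nominal record span (0 to
#'   240 s) so that every recording yields the same grid.
#' @return A `uniform_series`: list(values, rate, start, component).
#' @export
spline_resample <- function(bt, component = c("mean", "systolic", "diastolic"),
                            rate = 4, start = NULL, duration = NULL) {
  component <- match.arg(component)
  if (nrow(bt) < 8L)
    stop_dcatfa("need at least 8 beats for spectral analysis",
                "dcatfa_too_few_beats")
  t_beat <- bt$beat_onset_time
  if (anyDuplicated(t_beat))
    stop_dcatfa("duplicate beat times", "dcatfa_invalid_argument")
  if (is.unsorted(t_beat, strictly = TRUE))
    stop_dcatfa("beat times must be strictly increasing",
                "dcatfa_invalid_argument")
  v <- bt[[component]]
  if (is.null(start)) start <- t_beat[1]
  if (is.null(duration)) duration <- t_beat[length(t_beat)] - start
  n_out <- round(duration * rate)
  grid <- start + seq_len(n_out) / rate - 1 / rate
  f <- splinefun(t_beat, v, method = "fmm")
  out <- f(pmin(pmax(grid, t_beat[1]), t_beat[length(t_beat)]))
  structure(list(values = out, rate = rate, start = start,
                 component = component),
            class = "uniform_series")
}

#' Welch segmentation and tapering settings
#'
#' Defaults follow the standard squat-stand TFA configuration: 80-s
#' windows, 50% overlap, Hanning taper, per-window linear detrend, over a
#' 240-s record (which yields 5 windows).
#'
#' @param window_length Window length, s.
#' @param overlap_fraction Overlap between consecutive windows, in \[0, 1).
#' @param detrend `"linear"`, `"mean"` or `"none"` (applied per window).
#' @param smooth_spectra If `TRUE`, a 3-point triangular smoother is
#'   applied over frequency to the averaged auto/cross spectra before
#'   metrics are formed. Default `FALSE` (the reproducible setting).
#' @return An object of class `welch_config`.
#' @export
welch_config <- function(window_length = 80, overlap_fraction = 0.5,
                         detrend = c("linear", "mean", "none"),
                         smooth_spectra = FALSE) {
  check_scalar(window_length, "window_length", 0, strict_lower = TRUE)
  check_scalar(overlap_fraction, "overlap_fraction", 0, 1, strict_upper = TRUE)
  structure(list(window_length = window_length,
                 overlap_fraction = overlap_fraction,
                 detrend = match.arg(detrend),
                 smooth_spectra = isTRUE(smooth_spectra)),
            class = "welch_config")
}

#' Segment a uniform series into detrended, Hanning-tapered windows
#'
#' Windows start every `window_length * (1 - overlap_fraction)` seconds;
#' the count is `floor((duration - window_length) / step) + 1`. Each window
#' is detrended (linear by default) and multiplied by a Hanning taper.
#'
#' @param series A `uniform_series`.
#' @param cfg A [welch_config()].
#' @return List with `windows` (n_samples x n_windows matrix), `taper`,
#'   `n_windows` and the sample count per window.
#' @export
segment_windows <- function(series, cfg = welch_config()) {
  n <- length(series$values)
  nw <- round(cfg$window_length * series$rate)
  if (nw > n)
    stop_dcatfa("window longer than record", "dcatfa_invalid_argument")
  step <- max(1L, round(nw * (1 - cfg$overlap_fraction)))
  n_win <- (n - nw) %/% step + 1L
  taper <- signal::hanning(nw)
  starts <- (seq_len(n_win) - 1L) * step + 1L
  w <- vapply(starts, function(s) {
    seg <- series$values[s:(s + nw - 1L)]
    seg <- switch(cfg$detrend,
                  linear = {
                    tt <- seq_len(nw)
                    fit <- lm.fit(cbind(1, tt), seg)
                    seg - fit$fitted.values
                  },
                  mean = seg - mean(seg),
                  none = seg)
    seg * taper
  }, numeric(nw))
  list(windows = matrix(w, nrow = nw), taper = taper, n_windows = n_win,
       window_samples = nw)
}

# 3-point triangular smoother over frequency, ends renormalized.
smooth3 <- function(v) {
  n <- length(v)
  if (n < 3L) return(v)
  out <- v
  out[2:(n - 1L)] <- (v[1:(n - 2L)] + 2 * v[2:(n - 1L)] + v[3:n]) / 4
  out[1L] <- (2 * v[1L] + v[2L]) / 3
  out[n] <- (v[n - 1L] + 2 * v[n]) / 3
  out
}

#' Welch auto- and cross-spectral estimates between two uniform series
#'
#' Per-window FFTs of the detrended, tapered segments are averaged:
#' `Pxx = c * mean(|X|^2)`, `Pyy = c * mean(|Y|^2)`,
#' `Sxy = c * mean(conj(X) * Y)`, with the one-sided normalization
#' `c = 2 / (rate * sum(taper^2))` (1x at DC and Nyquist) so that the PSD
#' of unit-variance white noise integrates to 1. Coherence (magnitude-
#' squared), phase and gain follow from the averaged spectra; coherence
#' requires at least 2 windows (it is identically 1 for a single window).
#'
#' @param x,y `uniform_series` of the same rate and length (input = BP,
#'   output = velocity).
#' @param cfg A [welch_config()].
#' @return A `spectral_estimates` list: freqs, psd_input, psd_output,
#'   cross_spectrum (complex), coherence, phase, gain, n_windows.
#' @export
welch_spectra <- function(x, y, cfg = welch_config()) {
  if (x$rate != y$rate || length(x$values) != length(y$values))
    stop_dcatfa("input and output series must share rate and length",
                "dcatfa_invalid_argument")
  sx <- segment_windows(x, cfg)
  sy <- segment_windows(y, cfg)
  if (sx$n_windows < 2L)
    stop_dcatfa("need at least 2 windows: coherence undefined for one",
                "dcatfa_invalid_argument")
  nw <- sx$window_samples
  X <- mvfft(sx$windows)
  Y <- mvfft(sy$windows)
  n_freq <- nw %/% 2L + 1L
  keep <- seq_len(n_freq)
  scale <- 2 / (x$rate * sum(sx$taper^2))
  one_sided <- rep(scale, n_freq)
  one_sided[1L] <- scale / 2
  if (nw %% 2L == 0L) one_sided[n_freq] <- scale / 2
  pxx <- rowMeans(Mod(X[keep, , drop = FALSE])^2) * one_sided
  pyy <- rowMeans(Mod(Y[keep, , drop = FALSE])^2) * one_sided
  sxy <- rowMeans(Conj(X[keep, , drop = FALSE]) * Y[keep, , drop = FALSE]) *
    one_sided
  if (cfg$smooth_spectra) {
    pxx <- smooth3(pxx)
    pyy <- smooth3(pyy)
    sxy <- complex(real = smooth3(Re(sxy)), imaginary = smooth3(Im(sxy)))
  }
  coh <- Mod(sxy)^2 / (pxx * pyy)
  coh[!is.finite(coh)] <- 0
  structure(list(freqs = (keep - 1L) * x$rate / nw,
                 psd_input = pxx, psd_output = pyy, cross_spectrum = sxy,
                 coherence = coh, phase = Arg(sxy), gain = Mod(sxy) / pxx,
                 n_windows = sx$n_windows),
            class = "spectral_estimates")
}

#' Single-frequency TFA point estimate
#'
#' Reads the spectral metrics at the bin nearest `f0` (an exact bin under
#' the default grid), computes normalized gain as
#' `gain / mean_output_level * 100` (%/mmHg), and applies the coherence
#' criterion: point estimates with magnitude-squared coherence below the
#' critical value (default 0.46, the recommended cut-off at alpha = 0.01
#' for 5 Hanning windows) are flagged, not dropped.
#'
#' @param S A `spectral_estimates`.
#' @param f0 Frequency of interest, Hz (must not exceed Nyquist).
#' @param mean_output_level Segment mean of the output series, cm/s (> 0).
#' @param critical_coherence Coherence criterion. Default 0.46.
#' @param wraparound_band Optional band (Hz, length 2) over which phase
#'   wraparound is flagged via [detect_wraparound()]; `NA` flag if omitted.
#' @return A `point_estimate` data frame row: frequency, psd_input,
#'   psd_output, coherence, phase, gain, ngain, coherence_pass,
#'   wraparound_flag.
#' @export
point_metrics <- function(S, f0, mean_output_level,
                          critical_coherence = 0.46,
                          wraparound_band = NULL) {
  if (f0 > max(S$freqs))
    stop_dcatfa("f0 above Nyquist frequency", "dcatfa_invalid_argument")
  check_scalar(mean_output_level, "mean_output_level", 0, strict_lower = TRUE)
  i <- which.min(abs(S$freqs - f0))
  wrap <- if (is.null(wraparound_band)) NA else
    detect_wraparound(S$phase, S$freqs, wraparound_band)
  data.frame(frequency = S$freqs[i],
             psd_input = S$psd_input[i], psd_output = S$psd_output[i],
             coherence = S$coherence[i], phase = S$phase[i],
             gain = S$gain[i],
             ngain = S$gain[i] / mean_output_level * 100,
             coherence_pass = S$coherence[i] >= critical_coherence,
             wraparound_flag = wrap)
}

#' Flag phase wraparound within a frequency band
#'
#' `TRUE` iff any adjacent-bin phase difference inside the band exceeds pi
#' in absolute value. A single-bin band has no adjacent pair and returns
#' `FALSE`.
#'
#' @param phase Phase spectrum, radians.
#' @param freqs Frequency grid, Hz.
#' @param band Length-2 band limits, Hz.
#' @return Logical flag.
#' @export
detect_wraparound <- function(phase, freqs, band) {
  idx <- which(freqs >= band[1] & freqs <= band[2])
  if (length(idx) == 0L)
    stop_dcatfa("empty band", "dcatfa_invalid_argument")
  if (length(idx) < 2L) return(FALSE)
  any(abs(diff(phase[idx])) > pi)
}
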