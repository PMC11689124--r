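#' Parametric pulse-wave kernel
#'
#' A minimal two-parameter description of one arterial pulse: a half
#' raised-cosine upstroke from the diastolic foot to the systolic peak over
#' `systolic_fraction` of the beat, followed by an exponential run-off that
#' reaches the next beat's diastolic level exactly at the beat boundary.
#' The shape has an unambiguous per-beat maximum (the systolic level),
#' minimum (the diastolic feet) and a closed-form time average, which makes
#' beat-decomposition ground truth exact.
#'
#' @param systolic_fraction Fraction of the beat occupied by the upstroke,
#'   in (0, 1). Default 0.3 (upstroke of roughly 0.2 s at 70 beats/min).
#' @param decay_rate Diastolic run-off constant, 1/s; must be positive.
#'   Default 3.
#' @return An object of class `pulse_shape_params`.
#' @examples
#' pulse_shape_params(systolic_fraction = 0.3, decay_rate = 3)
#' @export
pulse_shape_params <- function(systolic_fraction = 0.3, decay_rate = 3) {
  check_scalar(systolic_fraction, "systolic_fraction", 0, 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_scalar(decay_rate, "decay_rate", 0, strict_lower = TRUE)
  structure(list(systolic_fraction = systolic_fraction,
                 decay_rate = decay_rate),
            class = "pulse_shape_params")
}

# Normalized kernel height h(u) in [0, 1] at within-beat fraction u in [0, 1),
# for a beat of duration rr seconds. h(0) = 0, h(sf) = 1, h(1-) -> 0.
pulse_profile <- function(u, rr, pulse) {
  rr <- rep_len(rr, length(u))
  sf <- pulse$systolic_fraction
  k <- pulse$decay_rate
  h <- numeric(length(u))
  up <- u < sf
  h[up] <- (1 - cos(pi * u[up] / sf)) / 2
  td <- (1 - sf) * rr
  E <- exp(-k * td)
  dn <- !up
  x <- exp(-k * (u[dn] - sf) * rr[dn])
  h[dn] <- (x - E[dn]) / (1 - E[dn])
  h
}

# Analytic time-average of pulse_profile over one beat of duration rr:
# the weight w such that mean(level) = diastolic + (systolic - diastolic) * w.
pulse_mean_weight <- function(rr, pulse) {
  sf <- pulse$systolic_fraction
  x <- pulse$decay_rate * (1 - sf) * rr
  E <- exp(-x)
  decay_mean <- (1 - E - x * E) / (x * (1 - E))
  sf / 2 + (1 - sf) * decay_mean
}

# Build a sampled pulse train from per-beat onset times and per-beat
# diastolic/systolic levels. `time` is the uniform sample grid; beats span
# [onset_i, onset_{i+1}) and samples beyond the last onset hold the last
# diastolic level. Returns the sampled trace.
pulse_train <- function(time, onsets, dias, sys, pulse) {
  n_beat <- length(onsets) - 1L
  stopifnot(n_beat >= 1L, length(dias) >= n_beat + 1L, length(sys) >= n_beat)
  idx <- findInterval(time, onsets)
  out <- rep(dias[length(dias)], length(time))
  inside <- idx >= 1L & idx <= n_beat
  i <- idx[inside]
  rr <- (onsets[i + 1L] - onsets[i])
  u <- (time[inside] - onsets[i]) / rr
  h <- pulse_profile(u, rr, pulse)
  d0 <- dias[i]
  d1 <- dias[i + 1L]
  s <- sys[i]
  sf <- pulse$systolic_fraction
  # upstroke interpolates from this beat's foot, run-off decays to the next
  base <- ifelse(u < sf, d0, d1)
  out[inside] <- base + (s - base) * h
  out[!inside & idx < 1L] <- dias[1L]
  out
}
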