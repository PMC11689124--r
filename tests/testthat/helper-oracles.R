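# Independent oracles and small fixture builders used across the suite.

# Least-squares sinusoid fit at a known frequency: returns amplitude and
# phase of v(t) ~ A*sin(2*pi*f*t + phi) + const.
sinusoid_fit <- function(t, v, f) {
  X <- cbind(1, sin(2 * pi * f * t), cos(2 * pi * f * t))
  b <- qr.solve(X, v)
  list(amplitude = sqrt(b[2]^2 + b[3]^2), phase = atan2(b[3], b[2]))
}

# Brute-force Welch auto/cross spectra by direct DFT summation: its own
# detrend (stats::lm), its own Hann taper formula, and explicit
# O(N^2) Fourier sums. Mirrors the documented normalization.
oracle_welch <- function(xv, yv, rate, window_length, overlap) {
  nw <- round(window_length * rate)
  step <- round(nw * (1 - overlap))
  n_win <- (length(xv) - nw) %/% step + 1L
  taper <- 0.5 - 0.5 * cos(2 * pi * (0:(nw - 1)) / (nw - 1))
  n_freq <- nw %/% 2 + 1L
  dft <- function(v) {
    sapply(seq_len(n_freq) - 1L, function(k) {
      ph <- -2i * pi * k * (0:(nw - 1)) / nw
      sum(v * exp(ph))
    })
  }
  prep <- function(v, s) {
    seg <- v[s:(s + nw - 1L)]
    tt <- seq_len(nw)
    residuals(lm(seg ~ tt)) * taper
  }
  starts <- (seq_len(n_win) - 1L) * step + 1L
  X <- sapply(starts, function(s) dft(prep(xv, s)))
  Y <- sapply(starts, function(s) dft(prep(yv, s)))
  scale <- 2 / (rate * sum(taper^2))
  side <- rep(scale, n_freq)
  side[1] <- scale / 2
  if (nw %% 2 == 0) side[n_freq] <- scale / 2
  list(freqs = (seq_len(n_freq) - 1L) * rate / nw,
       pxx = rowMeans(Mod(X)^2) * side,
       pyy = rowMeans(Mod(Y)^2) * side,
       sxy = rowMeans(Conj(X) * Y) * side)
}

# Uniform series wrapper for raw vectors.
us <- function(values, rate = 4, component = "mean") {
  structure(list(values = values, rate = rate, start = 0,
                 component = component),
            class = "uniform_series")
}

# Long-format metric table for one cell, with known fixed effects:
# 10 female + 10 male participants x three CO2 stages.
sim_metric_table <- function(beta_hypo = 0, beta_hyper = 0, beta_sex = 0,
                             mu = 0.5, sd_participant = 0.1,
                             sd_resid = 0.05, n_female = 10, n_male = 10) {
  n <- n_female + n_male
  p <- sprintf("P%02d", seq_len(n))
  sex <- c(rep("female", n_female), rep("male", n_male))
  d <- expand.grid(participant = p,
                   stage = c("eucapnia", "hypocapnia", "hypercapnia"),
                   stringsAsFactors = FALSE)
  d$sex <- sex[match(d$participant, p)]
  u <- rnorm(n, 0, sd_participant)
  d$value <- mu + u[match(d$participant, p)] +
    beta_hypo * (d$stage == "hypocapnia") +
    beta_hyper * (d$stage == "hypercapnia") +
    beta_sex * (d$sex == "male") +
    rnorm(nrow(d), 0, sd_resid)
  d$ssm_frequency_hz <- 0.05
  d$vessel <- "MCA"
  d$component <- "mean"
  d$metric_name <- "phase"
  d
}
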