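#!/usr/bin/env Rscript
# Cardiac-cycle-resolved transfer function analysis over the whole
# cohort: spline-resampled beat series at 4 Hz, Welch spectra (80-s
# Hanning windows, 50% overlap, linear detrend), point estimates of
# coherence/phase/gain/nGain at each recording's SSM frequency. Also
# reports how well the estimates recover the injected ground truth.

library(dcatfa)

spec <- cohort_spec(seed = 1L)   # same spec as 01_simulate.R
coh <- generate_cohort(spec)
cfg <- pipeline_config(cohort = spec)

wide <- tfa_metric_table(coh$recordings, cfg)
write.table(wide, "results/tfa_points.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("TFA point estimates: %d rows (%d recordings x 6 vessel-component cells)\n",
            nrow(wide), length(coh$recordings)))
cat(sprintf("Coherence criterion (>= 0.46) passed in %.1f%% of estimates\n",
            100 * mean(wide$coherence_pass)))
cat(sprintf("Phase wraparound flagged in %d estimates\n",
            sum(wide$wraparound_flag)))

m <- merge(wide, coh$truth,
           by = c("participant", "stage", "vessel", "component"),
           suffixes = c("", ".t"))
m <- m[abs(m$ssm_frequency_hz - m$ssm_frequency_hz.t) < 1e-9, ]
rec_summary <- data.frame(
  median_abs_gain_err_pct = 100 * median(abs(m$gain_cms_mmhg - m$gain_true) /
                                           m$gain_true),
  median_abs_phase_err_rad = median(abs(m$phase_rad - m$phase_true)),
  min_coherence = min(m$coherence))
print(rec_summary)
write.csv(rec_summary, "results/tfa_recovery_summary.csv", row.names = FALSE)
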