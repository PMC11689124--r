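# dcatfa

Cardiac-cycle-resolved transfer function analysis (TFA) of dynamic
cerebral autoregulation (dCA) during squat–stand manoeuvres (SSMs) under
end-tidal CO₂ clamping — as a tested, reproducible R pipeline with a
synthetic-cohort generator standing in for raw participant recordings.

**Who it is for.** Cerebrovascular physiologists analysing paced
squat–stand protocols (forced BP oscillations at 0.05/0.10 Hz, transcranial
Doppler velocities in the middle and posterior cerebral arteries, PETCO₂
clamped near 25/40/55 mmHg), and methodologists who want every stage of
that analysis — beat decomposition, spectral estimation, mixed-model
inference — unit-tested against known ground truth.

## The method

Each arterial pulse is decomposed into systolic (waveform maximum),
diastolic (minimum) and mean (waveform average) values; each component
series, for blood pressure (input *x*) and cerebral blood velocity
(output *y*), is spline-resampled to 4 Hz and taken through Welch
estimation (80-s Hanning windows, 50% overlap, linear detrend; a 240-s
record gives 5 windows and a 0.0125 Hz grid). From the averaged spectra
S<sub>xx</sub>, S<sub>yy</sub>, S<sub>xy</sub>:

- coherence γ²(f) = |S<sub>xy</sub>|² / (S<sub>xx</sub>·S<sub>yy</sub>) ∈ [0, 1], criterion 0.46;
- phase φ(f) = arg S<sub>xy</sub> (rad; positive = velocity leads pressure);
- gain G(f) = |S<sub>xy</sub>| / S<sub>xx</sub> (cm/s/mmHg);
- normalized gain = G / mean(y) × 100 (%/mmHg),

read at the exact 0.05 and 0.10 Hz bins. Stage/sex inference fits, per
metric × vessel × component × frequency,
`value ~ stage + sex + (1 | participant)` by maximum likelihood
(eucapnia/female reference) with a likelihood-ratio test against the
fixed-effects-free null (χ², 3 df). The synthetic generator injects known
per-component gain/phase/baseline transfer truths into pulsatile
recordings so the whole chain is verifiable end to end; see the methods
vignette (`vignettes/cardiac-cycle-tfa.Rmd`) for the model and every
default.

## Worked example

The `analysis/` scripts run the full study on the synthetic cohort
(20 participants × 3 CO₂ stages × 2 SSM frequencies, 240-s recordings):

```sh
Rscript analysis/01_simulate.R   # cohort + ground truth + PETCO2 audit
Rscript analysis/02_beats.R      # beat/breath decomposition example
Rscript analysis/03_tfa.R        # TFA point estimates for all recordings
Rscript analysis/04_stats.R      # mixed-model stage/sex comparison
```

`01_simulate.R` verifies the CO₂ clamp (mean breath-to-breath PETCO₂
peaks 25.0 / 40.0 / 55.0 mmHg for the hypo-/eu-/hypercapnic stages).
`03_tfa.R` prints, for the default noisy cohort:

```
TFA point estimates: 720 rows (120 recordings x 6 vessel-component cells)
Coherence criterion (>= 0.46) passed in 100.0% of estimates
Phase wraparound flagged in 0 estimates
  median_abs_gain_err_pct median_abs_phase_err_rad min_coherence
1                1.211121               0.01129887     0.9736516
```

i.e. with 2 cm/s beat-level velocity noise the pipeline recovers injected
gains to ~1.2% (median) and phases to ~0.011 rad. `04_stats.R` then
recovers the injected stage physiology on mean-component phase — the
autoregulatory lead grows under hypocapnia and erodes under hypercapnia:

```
 vessel ssm_frequency_hz             term       beta      ci_lo      ci_hi
    MCA             0.05  stagehypocapnia  0.3845766  0.3792620  0.3898913
    MCA             0.05 stagehypercapnia -0.3531629 -0.3584775 -0.3478482
```

(betas in radians relative to eucapnia; LR p-values < 1e-60 at this noise
level).

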