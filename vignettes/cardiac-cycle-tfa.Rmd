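---
title: "Cardiac-cycle-resolved transfer function analysis of dynamic cerebral autoregulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cardiac-cycle-resolved transfer function analysis of dynamic cerebral autoregulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcatfa)
```

## The problem

Dynamic cerebral autoregulation (dCA) is the brain's buffering of cerebral
blood flow against transient swings in arterial blood pressure (BP).
Repeated squat–stand manoeuvres (SSMs), paced by metronome at 0.05 or
0.10 Hz, drive large near-sinusoidal BP oscillations at the pacing
frequency; transcranial Doppler records middle and posterior cerebral
artery velocities (MCAv, PCAv) while dynamic end-tidal forcing clamps
end-tidal CO~2~ (PETCO~2~) near 25, 40 or 55 mmHg (hypo-, eu-,
hypercapnia). Transfer function analysis (TFA) between BP and cerebral
blood velocity (CBv) then quantifies dCA frequency by frequency:

* **coherence** — magnitude-squared cross-spectral correlation,
  $\gamma^2(f) = |S_{xy}|^2 / (S_{xx} S_{yy}) \in [0, 1]$, the gate for
  interpreting the other metrics;
* **phase** (rad) — $\arg S_{xy}$; positive values mean velocity leads
  pressure, the signature of active autoregulation;
* **gain** (cm/s/mmHg) — $|S_{xy}| / S_{xx}$, amplitude transmission of
  BP oscillations into velocity;
* **normalized gain** (%/mmHg) — gain divided by the output series' own
  segment mean, times 100.

The cardiac-cycle-resolved twist: each pulse wave is decomposed into its
systolic (per-beat maximum), diastolic (minimum) and mean (per-beat
average) values, and TFA is run separately on each component pair
(diastolic BP → diastolic CBv, and so on), because autoregulatory
behaviour differs across the cardiac cycle.

This package implements that full pipeline — beat detection and
decomposition, breath-wise PETCO~2~ peak extraction, spline resampling,
Welch cross-spectral estimation, point estimates at the SSM frequencies,
and a linear mixed-effects stage-by-sex comparison — together with a
synthetic-cohort generator with known ground truth, so that every stage is
testable without any participant data.

## The synthetic generator

Raw multi-channel recordings from this protocol are not publicly
deposited, so the package ships a simulator whose recovery properties
stand in for real-data validation.

**Pulse kernel.** One beat is a half-raised-cosine upstroke from the
diastolic foot to the systolic peak over a fraction `systolic_fraction`
(default 0.3) of the beat, then an exponential run-off (rate
`decay_rate`, default 3 s⁻¹) that lands exactly on the next beat's
diastolic level. This minimal shape has an unambiguous per-beat maximum,
minimum and closed-form time average, which makes decomposition ground
truth exact.

**Forcing.** The SSM oscillation enters the per-beat diastolic and
systolic *levels* additively: both levels carry
$A \sin(2\pi f t_\mathrm{onset})$. Additive level forcing (rather than,
say, multiplicative modulation) keeps the injected BP→CBv transfer exactly
linear, so the spectral pipeline should recover it up to numerical error —
the repository's central property. Protocol descriptions do not pin down
the BP oscillation amplitude SSMs produce; the default `forcing_amplitude
= 15` mmHg was chosen once so that the beat-mean BP power spectral density
at the forcing bin lands at the order of magnitude reported for this kind
of protocol (~10^4 mmHg²/Hz).

**Velocity channels.** For each vessel, per-beat diastolic and systolic
velocity levels are
$B + G \cdot A \sin(2\pi f t + \varphi) + \varepsilon$, with
$\varepsilon \sim N(0, \texttt{noise\_sd})$ (default 2 cm/s). A two-level
kernel cannot carry three independent component truths, so the
mean-component truth is *derived*: the beat mean decomposes as
$a\,d_i + b\,d_{i+1} + w_s\,s_i$ (upstroke from this foot, run-off toward
the next, systolic weight), the next foot leads by
$\Delta = 2\pi f \cdot \overline{RR}$, and the same decomposition applies
to the BP beat mean, so

$$H_\mathrm{mean}
  = \frac{(a + b e^{i\Delta})\, G_d e^{i\varphi_d} + w_s G_s e^{i\varphi_s}}
         {(1 - b) + b e^{i\Delta}}.$$

`mean_component_truth()` exposes this phasor identity; `apply_transfer()`
stores the effective truths for all three components alongside the
recording.

**Timing and stages.** R-R intervals get Gaussian jitter with sd 2% of
the mean interval, truncated at ±10% — realistic beat irregularity without
aliasing. Heart rates are drawn from 80–105 beats/min, baseline pressures
around 120/80 mmHg. Stage-level gain/phase/baseline defaults
(`default_transfer_truths()`) are loosely calibrated to the magnitudes
reported for this protocol (gain ≈ 0.2–1.1 cm/s/mmHg, phase ≈
0.2–1.9 rad) with the physiological orderings: phase falls and baseline
velocity rises from hypocapnia through eucapnia to hypercapnia (CO~2~
vasodilation raises flow and erodes the autoregulatory phase lead). They
are emulation defaults, explicitly not estimates of any real cohort.
PETCO~2~ is a breath-wise raised-cosine trace whose per-breath peaks sit
within 1 mmHg of the stage clamp target, mimicking dynamic end-tidal
forcing.

**What the generator does not emulate:** Windkessel or baroreflex
dynamics, nonlinear or frequency-dependent autoregulation,
respiration–BP coupling, measurement dropouts, probe artifacts. Passing
recovery tests therefore demonstrates that the estimation chain is
correct for linear transfer with realistic beat timing and noise — not
that real cerebrovascular data satisfy those assumptions.

```{r example, eval = FALSE}
spec <- cohort_spec(seed = 1)        # 10 F + 10 M, 3 stages, 0.05/0.10 Hz
coh <- generate_cohort(spec)
wide <- tfa_metric_table(coh$recordings, pipeline_config(cohort = spec))
fit <- fit_stage_sex_lme(metric_long(wide), metric_name = "phase",
                         vessel = "MCA", component = "mean",
                         ssm_frequency = 0.05)
```

## Processing choices

**Beat detection.** Beats are found on the BP channel: systolic peaks on
a high-passed copy (running median over ~1.5 slow beats removes the
forcing oscillation), refractory period `60/hr_max`, then the foot as the
sample-level minimum between consecutive peaks. The same boundaries are
applied to the velocity channels — one fiducial avoids inter-channel beat
mismatch. A beat spans `[onset_i, onset_{i+1})`, so every sample belongs
to exactly one beat.

**Artifact handling.** Corrupted systolic peaks are flagged by an 11-beat
rolling median ± 4 robust SDs (1.4826·MAD of the residuals) and replaced
by cubic-spline interpolation of neighbouring beats — an automated version
of the manual peak-interpolation practice; corrected beats stay flagged
and the corrected fraction is reported. If a majority of beats deviate
from the rolling median by more than 10% of the median systolic level the
function refuses to correct: that is a corrupted recording, not isolated
artifacts.

**Resampling and spectra.** Per-beat component series are cubic-spline
interpolated onto a uniform 4 Hz grid over the nominal record span (no
spline extrapolation beyond the observed beats; endpoints are held).
Welch estimation uses 80-s windows, 50% overlap, per-window linear
detrend, Hanning taper; a 240-s record yields five windows. The resulting
frequency step, 1/80 s = 0.0125 Hz, places 0.05 and 0.10 Hz on exact bins
(4 and 8), so point estimates are single-bin reads, not band averages.
The one-sided normalization `2 / (rate · Σ taper²)` makes the PSD of
unit-variance white noise integrate to 1 (verified by a Parseval test).
An optional 3-point triangular smoother over frequency can be applied to
the averaged spectra before metrics are formed; it is off by default
because results should be reproducible from the stated window settings
alone.

**Point estimates.** Coherence below the criterion 0.46 — the
recommended cut-off at α = 0.01 for five Hanning windows, treated here as
a looked-up constant, not re-derived — flags an estimate rather than
dropping it, since exclusion behaviour is an analysis-level decision.
Normalized gain divides by the *component series' own* segment mean (the
two published normalization routes, post-hoc division versus
pre-normalizing the series, agree to 1e-6 for gain and that equivalence
is tested). Phase is reported in (−π, π] without unwrapping; wraparound
is only flagged, by default over one spectral bin either side of the
point-estimate frequency — the neighbourhood where the forced oscillation
(and its taper leakage) keeps the phase spectrum interpretable. Farther
bins of a noisy recording carry no coherent energy, and their arbitrary
phases would make a broadband flag fire on essentially every recording.

**Sign convention.** `welch_spectra()` uses
$S_{xy} = \overline{\mathrm{conj}(X) Y}$, so a delayed output
$y(t) = x(t-\tau)$ yields phase $-2\pi f \tau$ and a positive phase means
the velocity leads pressure — the physiological reading of dCA phase
lead. Tests pin this convention.

## The inferential layer

Each metric × vessel × component × frequency cell is modelled separately
(no multiple-testing correction, mirroring the per-cell reporting
convention of this literature) as

$$\text{value} \sim \text{stage} + \text{sex} + (1 \mid \text{participant}),$$

with eucapnia and female as reference levels, fitted by **maximum
likelihood** (not REML — the likelihood-ratio test against the
fixed-effects-free null `value ~ 1 + (1 | participant)` is only valid
under ML). The LR statistic is referred to χ² with 3 degrees of freedom
(two stage contrasts plus one sex contrast). Coefficient intervals and
p-values are Wald.

A calibration caveat the package's own experiments expose: at this design
(20 participants × 3 stages, 60 observations) the χ²₃ reference is mildly
anticonservative — the simulated null rejection rate at α = 0.05 runs
somewhat above the nominal 5%. This is the familiar finite-sample
behaviour of likelihood-ratio tests for fixed effects in small mixed
models, not an implementation defect; the acceptance script recomputes
the realized rate from 1000 simulated null tables at every run. Exact
small-sample references (Kenward–Roger, parametric bootstrap) are
deliberately out of scope because the method under study is the plain LR
test.

`required_sample_size()` implements the a-priori computation under the
large-sample normal approximation,
$n = \lceil (z_{1-\alpha} + z_{\text{power}})^2 / f^2 \rceil$ for a
one-tailed test of a single coefficient: with Cohen's f² = 0.35,
α = 0.05 and power 0.80 it returns 18. Among the standard candidate
formulas, only this one reproduces that printed design value from the
stated inputs, which is why it is the default; an exact noncentral
alternative would give slightly different numbers.

## Numerical and degenerate-input policy

* Flat traces, records shorter than 10 s (30 s for PETCO~2~), fewer than
  8 beats, duplicate beat times, single-window coherence, frequencies
  above Nyquist, single-participant mixed models and zero-variance
  outcomes all raise classed errors (`dcatfa_*`) rather than returning
  quietly wrong numbers.
* The LR statistic is clipped at zero; optimizer noise may leave the full
  fit a hair below the null (tolerance 1e-3 before erroring).
* Pipeline failures propagate with the stage name and recording
  identifier; earlier artefacts are still written, and the manifest
  reconciles recording counts against metric-table rows so nothing is
  silently dropped.

## Problem sizes used by the shipped experiments

The test suite and acceptance script run, as the package's chosen study
sizes: a 120-recording noiseless cohort (20 participants × 3 stages ×
2 frequencies, 240 s at 100 Hz) for parameter recovery; 1000 simulated
null metric tables for LR calibration; 200 replicates for directional
recovery of the stage ordering at n = 10 + 10; and small white-noise and
32-sample instances for the spectral identities and the direct-DFT
oracle.

## Known limitations

* The generator's linearity is both its strength (exact ground truth) and
  its limitation: it cannot probe the nonlinear, frequency-dependent
  behaviour of real autoregulation.
* Beat detection is tuned to clean pressure waveforms; heavily damped or
  photoplethysmographic traces with slurred feet may need different
  peak-threshold settings (`hr_bounds`, detection threshold are
  configurable).
* The artifact rule automates what is, in practice, a visual/manual
  correction; its corrected fraction is reported per beats, and no claim
  is made that it matches any particular manual-correction rate.
* PETCO~2~ is emulated as an ideal clamp; the pipeline treats it as an
  audit channel only and does not model velocity–CO~2~ dynamics within a
  stage.
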