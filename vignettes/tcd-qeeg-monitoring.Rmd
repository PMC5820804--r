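---
title: "Multimodal TCD + quantitative EEG monitoring: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal TCD + quantitative EEG monitoring: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuromon)
```

## Scope

`neuromon` implements a bedside brain-function monitoring analysis for
severe acute supratentorial intracerebral hemorrhage (ICH): quantitative
EEG (QEEG) spectral indices, transcranial Doppler (TCD) waveform indices,
and the prognostic modelling pipeline that relates them to 90-day
mortality. Because patient-level recordings from such cohorts are not
publicly available, the package ships first-class synthetic generators
whose outputs carry the statistical structure the analysis assumes; every
stage is exercised end to end on generated data.

## Quantitative EEG indices

The EEG pathway is: zero-phase band-pass filter (0.3–30 Hz), amplitude
artifact rejection, Welch power spectrum over 1–30 Hz, band integration.

**Filtering.** Butterworth high-pass (order 2 at 0.3 Hz) and low-pass
(order 4 at 30 Hz), each applied forward–backward (`signal::filtfilt`),
so channels incur no group delay — a requirement for any symmetry index
computed across channels. Each channel is demeaned before filtering: a
large DC offset otherwise excites a long edge transient in the
very-low-frequency high-pass stage. The effective attenuation exceeds
20 dB one octave beyond each band edge.

**Artifact rejection.** The recording is cut into non-overlapping epochs
(default 2 s); any epoch in which any channel exceeds ±200 µV is masked
and excluded from spectral averaging. The criterion and threshold are
configurable; clinical practice varies, and reports typically state
only that artifact-free segments were analyzed. If every epoch is masked the
package raises an explicit "no analyzable data" error rather than
returning a spectrum of nothing.

**Spectrum.** Averaged modified periodograms (Welch), Hann window,
default 2 s epochs with 50% overlap, restricted to 1–30 Hz. Two seconds
gives 0.5 Hz resolution, enough to respect the 1 Hz lower band edge;
the scaling is such that band-integrated density equals in-band signal
variance (exact for a bin-centred sinusoid). No Welch estimator is
available in the installed R ecosystem, so the averaging is implemented
directly on `stats::mvfft`.

**Bands.** Delta 1–3, theta 4–7, alpha 8–13, beta 14–30 Hz by the
conventional integer labels. Those labels leave the gap frequencies
(3–4, 7–8, 13–14 Hz) unassigned; the package closes the gaps upward,
giving half-open intervals [1,4), [4,8), [8,14), [14,30], and assigns a
spectral bin to the band containing its centre frequency. The convention
is recorded in the output metadata.

**Relative powers and ratios.** Per channel, relative power is band
power divided by total 1–30 Hz power; the global value is the unweighted
mean across channels (the channel-pooled power ratio is available via
`global = "pooled"`; the two coincide when channels share total power).
DAR = RDP/RAP and DTABR = (RDP+RTP)/(RAP+RBP) with explicit errors on
zero denominators. These ratios are invariant to any common gain, so the
arbitrary microvolt scale of synthetic data is immaterial.

**Brain symmetry index.** BSI is the frequency-averaged absolute value
of the channel-averaged left/right spectral asymmetry over N homologous
bipolar pairs: `mean_j | mean_i (R_ij − L_ij)/(R_ij + L_ij) |`, in [0, 1].
A typographic ambiguity in common statements of the formula (the 1/N
factor sometimes appears outside the norm) is immaterial: a positive constant moves freely through
the absolute value. The eight bipolar derivations per hemisphere follow
the anterior–posterior parasagittal and temporal chains of the
16-electrode 10–20 montage and are explicit configuration
(`bipolar_chains_16()`), never inferred from labels at analysis time.
Bins where a pair's power sum falls below 1e-12 of the median pairwise
power sum are skipped (M reduced) to avoid 0/0 without biasing the index
toward ±1.

## TCD indices

Inputs are velocity envelopes (cm/s), not raw Doppler spectra — bedside
devices export the envelope. Beats are delimited by diastolic minima;
systolic peaks are found on a 5-point running-median-smoothed copy of the
envelope, with a minimum inter-peak distance of 60/`max_rate` seconds and
a mid-range prominence threshold. Per beat, Vs and Vd are read as short
raw-sample medians (3 and 5 samples) centred on the smoothed peak and
minimum: localizing on the smoothed trace and reading values from small
raw medians is exact on clean waveforms yet carries no extreme-value bias
under additive noise, unlike a plain per-beat min/max, which inflates
Vs − Vd by roughly one noise standard deviation. Beats failing Vs > Vd or
falling outside 40–150 beats/min (physiologic range; also suppresses
double-peak miscounts) are dropped and counted.

Vm = (Vs − Vd)/3 + Vd and PI = (Vs − Vd)/Vm are evaluated exactly as
printed. Summaries default to the per-beat-first convention — compute Vm
and PI per beat, then average — because a mean of ratios is the clinical
convention and differs from the ratio of means whenever beats vary;
`convention = "ratio_of_means"` provides the alternative, under which the
summary itself satisfies PI = (Vs − Vd)/Vm identically. Side labels
follow the hematoma: affected (A) is the clot-bearing hemisphere,
unaffected (U) contralateral; a missing side yields a flagged unilateral
result rather than silent imputation.

## Synthetic data: what it emulates, and what it does not

**EEG.** Each channel is a sum of four independent Gaussian processes,
one per clinical band, synthesized in the frequency domain with an ideal
brick-wall mask (a frequency-sampling filter; the family is recorded in
the recording metadata). Raw target fractions are not used as component
variances directly: the Hann window of the downstream Welch analysis
leaks power across band edges (delta, at ~75% of total power in severe
ICH mixtures, leaks into theta and below the 1 Hz analysis edge), which
would bias the recovered delta/alpha ratio by roughly 10%. The generator
therefore solves a small linear system — the closed-form band-to-band
leakage matrix of the analysis window — for component variances whose
*measured* fractions equal the targets in expectation. The compensation
assumes the analysis epoch length declared in the generator
specification (default 2 s) and can be disabled. Right-hemisphere channels are scaled per band by the
square root of the requested right/left power ratio, so a ratio of r
yields a BSI of |(r−1)/(r+1)| up to estimation noise.

What generated EEG does *not* contain: 1/f background structure, spectral
peaks, artifacts, non-stationarity, or inter-channel correlation. Passing
round-trip tests therefore demonstrates correctness of the spectral
pipeline, not robustness to real-world contamination — that is what the
configurable artifact rejection is for, and it is tested separately on
constructed spikes.

**TCD.** Beats are a piecewise-smooth template: sinusoidal upstroke over
the first 15% of the cycle, a 3-sample systolic plateau (the rounded
peak), a shifted-exponential decay (rate constant 3/beat) reaching
exactly Vd, and a late-diastolic rest at Vd over the last ~8% of the
cycle. The template reproduces the semantics of per-beat Vs/Vd without
modelling hemodynamics; the plateaus make the extremes well defined so
that noiseless round-trips are exact. Optional additive Gaussian noise
models envelope jitter.

**Cohort.** Each clinical, Doppler and EEG variable is sampled
independently within outcome group from a calibrated marginal: normal for
variables summarized as mean (SD); log-normal solved from the printed
median and quartiles for right-skewed variables (non-negative,
right-skewed, matches a median/IQR summary); Bernoulli for binary rows;
and a quantile-matched rounded normal clamped to the admissible range for
the coma score. Independence within group is a deliberate simplification
— no joint covariance is published — so multivariable results on
synthetic cohorts show qualitative behaviour (e.g., that combining an
independent Doppler and an EEG predictor beats either alone), not
reproductions of the original fitted coefficients. Two published summary
rows report per-group counts inconsistent with the group sizes
(hematoma side, intraventricular extension); the calibration uses
group-plausible counts consistent with the printed overall column, and
those rows are not used in any quantitative check. One published summary
reports age as "median … ± SD"; age is treated as normal. The
calcium/sodium rows are carried exactly as printed even though their
values appear transposed relative to physiologic ranges; the column
dictionary flags this.

**Screening roster.** `gen_screening_roster()` reproduces an enrollment
funnel exactly: one exclusion flag per excluded pseudo-record in protocol
order, zero flags for enrolled records. `apply_eligibility()` is
idempotent, itemizes losses per criterion (a multi-flag record counts
once, under its first-listed criterion — the printed funnel reports 29
exclusions among 76 with no double counting), and enrollment plus tally
always sums to roster size.

## Statistical pipeline

**Univariate screen.** Binary variables: Pearson chi-squared *without*
continuity correction — this choice reproduces the published two-decimal
baseline-table p-values the calibration is checked against, and Yates
correction is available behind a flag. Continuous variables: Shapiro–Wilk
at α = 0.05 in each outcome group decides between Student's t (equal
variances) and the Wilcoxon rank-sum test. Clinical reports often
describe this test battery ambiguously; the package follows the
conventional reading (parametric when normal, nonparametric otherwise).
Variables at p ≤ 0.001 (configurable) enter the multivariable stage;
zero-variance variables are flagged and skipped, not silently dropped.

**Backward stepwise logistic regression.** Binomial GLM on the screen
survivors; repeatedly remove the variable with the largest Wald p above
0.10 and refit, logging each step. When a procedure is described only
as "backward stepwise", the removal threshold and the Wald (vs
likelihood-ratio) criterion are conventions; both are parameters here. Wald 95%
intervals on odds ratios match the one-line OR/CI/p reporting style of
clinical papers; boundary behaviour is contractual: `removal_alpha = 1`
returns the full model, `0` the intercept-only model. Non-convergence or
separation raises an error naming the worst-offending variable; the
pipeline orchestrator reacts by dropping that variable and refitting,
with a warning, because quasi-separation is routine at enrollment-scale
n with several strong correlated predictors. A sensitivity refit
excluding any variable (e.g. coma score and hematoma volume) is just a
call with a reduced candidate set.

**ROC and DeLong.** AUC is the Mann–Whitney estimator (ties ½), computed
via midranks and verified in tests against exhaustive pair enumeration up
to n = 200. Confidence intervals and paired comparisons use the DeLong
placement-value covariance estimator with a two-sided normal reference;
identical score vectors give a degenerate zero-variance comparison
reported as p = 1 rather than 0/0. Scores whose low values indicate the
event (the coma score) are auto-oriented so every reported AUC is ≥ 0.5,
and the orientation is recorded. The five compared models are the four
single variables (GCS, hematoma volume, unaffected-side PI, delta/alpha
ratio) and a combined model whose score is the in-sample fitted
probability of a logistic regression on UPI + DAR — in-sample, as is
common in clinical prognostic reports; honest out-of-sample evaluation would
need cross-validation, which is out of scope here and flagged as a
limitation. DeLong comparisons are reported unadjusted for multiplicity,
as is conventional for a single figure of five curves.

## Numerical choices and degenerate inputs

- Log-normal calibration: `sdlog = log(q75/q25) / (2 Φ⁻¹(0.75))`,
  `meanlog = log(median)`; requires 0 < q25 ≤ median ≤ q75.
- BSI zero-power floor: 1e-12 of the median pairwise power sum.
- Beat detection needs ≥ 3 valid beats, else "unreadable waveform".
- `eeg_spectrum` refuses recordings shorter than one epoch and fully
  masked recordings; `band_powers` errors on zero total power.
- All generators are deterministic given their seed; the caller's RNG
  state is saved and restored around every seeded computation.
- Pipeline outputs embed an MD5 hash of the analysis-relevant
  configuration (the output directory is excluded); identical
  configurations reproduce byte-identical CSVs.

## Problem sizes in the shipped tests

The test-suite defaults are chosen to settle each stochastic check well
inside its tolerance while keeping a full run around ten seconds: 60 s of
16-channel EEG at 128 Hz for spectral round-trips (band-power tolerance
0.02 absolute, DAR 5% relative), 30 s envelopes at 100 Hz for beat
analysis, cohorts of 2000 per group for closed-form AUC checks (±0.02),
2000 bootstrap replicates against the DeLong standard error at n = 30
(±15%), and 200 replicates of n = 500 for stepwise recovery (CI coverage
≥ 90%; a truly null variable survives the p > 0.10 removal rule about 10%
of the time by construction, so the expected drop rate is 0.9, tested
as ≥ 0.8).

## Known limitations

- Synthetic EEG is stationary band-limited noise; no claim is made about
  artifact robustness on real recordings beyond the amplitude criterion.
- Cohort variables are independent within group; fitted coefficients on
  synthetic cohorts are not comparable to the original study's odds
  ratios (patient-level data unpublished), only qualitative structure is.
- The combined model is evaluated in-sample; no cross-validation.
- The beta band extends to the 30 Hz low-pass edge, so the full filtered
  pipeline attenuates a sliver of beta power; ratios of the lower bands
  (DAR, DTABR) are unaffected.
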