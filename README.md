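# neuromon

Multimodal bedside brain-function monitoring analysis for **severe acute
supratentorial intracerebral hemorrhage (ICH)**, combining transcranial
Doppler (TCD) and quantitative EEG (QEEG). The package is aimed at
clinical neurophysiology researchers who want a tested, reproducible
implementation of the full analysis chain — from raw signals to
prognostic model comparison — together with calibrated synthetic
generators, since patient-level recordings from such cohorts are not
publicly available.

## What it computes

**QEEG indices** from a 16-channel 10–20 recording (0.3–30 Hz zero-phase
band-pass, amplitude artifact rejection, Welch spectrum over 1–30 Hz):

- relative band powers RDP, RTP, RAP, RBP over delta [1,4), theta [4,8),
  alpha [8,14), beta [14,30] Hz;
- the delta/alpha ratio **DAR = RDP/RAP** and the slowing ratio
  **DTABR = (RDP+RTP)/(RAP+RBP)**;
- the **brain symmetry index**
  `BSI = (1/M) Σ_j | (1/N) Σ_i (R_ij − L_ij)/(R_ij + L_ij) |`
  over N = 8 homologous bipolar channel pairs and M in-band frequency
  bins: 0 = perfect hemispheric symmetry, 1 = one-sided silence.

**TCD indices** per hemisphere from middle-cerebral-artery velocity
envelopes: per-beat systolic and end-diastolic velocity (Vs, Vd), mean
velocity **Vm = (Vs − Vd)/3 + Vd**, pulsatility index
**PI = (Vs − Vd)/Vm**, labelled by hematoma side (affected API /
unaffected UPI).

**Prognostic pipeline**: eligibility screening with an itemized exclusion
funnel; univariate screen (chi-squared without continuity correction,
Student's t or Wilcoxon by a Shapiro–Wilk gate) selecting variables at
p ≤ 0.001; backward stepwise logistic regression (Wald p > 0.10 removal)
for death at 90 days; ROC curves with DeLong confidence intervals; and
DeLong paired comparisons of five candidate models (GCS, hematoma volume,
UPI, DAR, and the combined UPI+DAR logistic score).

**Synthetic generators** for all three data kinds: band-limited Gaussian
EEG whose measured relative powers hit prescribed targets (the component
variances are pre-compensated for the analysis window's spectral
leakage), pulsatile Doppler envelopes with exact per-beat Vs/Vd, and
cohorts sampled from the published group marginals.

## Worked example

```r
library(neuromon)

## synthetic EEG calibrated to a severe-ICH band mix, re-measured
tgt <- c(delta = 0.744, theta = 0.084, alpha = 0.095, beta = 0.064) / 0.987
eeg <- gen_eeg(eeg_gen_spec(tgt, duration = 60, seed = 42))
qeeg_summary(eeg)
#> <qeeg_summary>
#>   RDP 0.758  RTP 0.091  RAP 0.097  RBP 0.055
#>   DAR 7.800  DTABR 5.587  BSI 0.045
```

The measured fractions land on the targets (DAR 7.80 vs the target ratio
0.744/0.095 = 7.83); BSI is near 0 because the generated hemispheres are
symmetric.

```r
## bilateral Doppler at group-mean velocities, left-sided hematoma
env_l <- gen_tcd(tcd_gen_spec(vs = 85.6, vd = 23.6), side = "left")
env_r <- gen_tcd(tcd_gen_spec(vs = 91.2, vd = 26.6), side = "right")
hemisphere_summary(detect_beats(env_l), detect_beats(env_r),
                   hematoma_side = "left")
#> <tcd_indices> affected side: left
#>    AVs    AVd    AVm    API    UVs    UVd    UVm    UPI
#> 85.600 23.600 44.267  1.401 91.200 26.600 48.133  1.342
```

Per-beat extraction is exact on clean envelopes: UVm and UPI equal the
printed formulas evaluated at (91.2, 26.6).

```r
## the full pipeline on synthetic data
report <- run_pipeline(run_config(seed = 1, n_signal_patients = 0))
report
#> <pipeline_report>
#>   screened 76, excluded 29, enrolled 47; 90-day mortality 55.3%
#>   univariate screen: 6 of 39 variables selected (p <= 0.001)
#>   logistic model retained: male, hematoma_volume, dar, dtabr
#> <model_comparison>
#>     model   auc ci_lo ci_hi
#>       gcs 0.693 0.543 0.843
#>    volume 0.885 0.781 0.988
#>       upi 0.886 0.793 0.980
#>       dar 0.793 0.665 0.921
#>  combined 0.938 0.875 1.000
#> DeLong tests, combined vs single:
#>   model_a model_b auc_a auc_b  delta     z        p
#>  combined     gcs 0.938 0.693 0.2450 3.290 0.000997
#>  combined  volume 0.938 0.885 0.0531 0.843 0.399000
#>  combined     upi 0.938 0.886 0.0513 1.650 0.099500
#>  combined     dar 0.938 0.793 0.1450 2.270 0.023500
```

The screening funnel (76 screened, 29 excluded across seven criteria, 47
enrolled) and the 55.3% mortality are structural; the univariate
selection, the retained model and the AUCs vary with the seed because the
cohort is resampled — at n = 47 the combined model's advantage is real
but not always individually significant, which is the expected behaviour
at that sample size. A thin command-line wrapper over the same function
lives at `inst/scripts/neuromon.R`.

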