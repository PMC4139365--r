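# holterchaos

Linear and nonlinear heart-rate-variability (HRV) analysis of 24-hour
Holter beat streams, with arrhythmia quantitation, time-of-day
statistics, and a seeded synthetic-recording generator.

## The problem

Healthy mammals show strong diurnal structure in cardiac dynamics: heart
rate and sympathovagal balance (LF/HF) rise in the morning, and
beat-to-beat variability is fractal and complex. Chronic heart failure
attenuates the morning rise, blunts autonomic oscillation, reduces
nonlinear "chaos" indices, and is accompanied by a morning surge of
ventricular arrhythmias (PVCs and ventricular tachycardia). Quantifying
these phenomena from 24-hour ambulatory recordings takes a chain of
steps — ectopic-beat exclusion, windowing, time- and frequency-domain
HRV, nonlinear dynamics, event timing statistics, rhythm testing — each
with fiddly conventions. `holterchaos` packages the whole chain for
anyone analyzing beat-annotation streams (beat time + `N`/`V`/`A`/`X`
label), and includes a generator of realistic synthetic recordings so
every stage is testable end to end without clinical data.

## What it computes

* **NN series** (`build_nn`): intervals bounded by two normal beats,
  within 200–3000 ms; both intervals adjacent to every ectopic beat are
  excluded, with an exclusion log.
* **Time domain** (`time_domain`): mean HR/RR, SDNN, CV = SDNN/meanRR ×
  100, rMSSD over unbroken successive pairs.
* **Spectra** (`resample_tachogram`, `ar_psd`, `window_spectral`):
  4-Hz cubic-spline tachogram, Burg autoregressive spectrum (order 16),
  LF (0.04–0.15 Hz) and HF (0.15–0.40 Hz) band powers and LF/HF, with
  5-minute sub-segment averaging per window.
* **Nonlinear dynamics** (`dfa`, `correlation_dimension`,
  `shannon_entropy`): detrended fluctuation exponents α1 (boxes 4–16)
  and α2 (16–64) with an exact finite-size correction; the
  Grassberger–Procaccia correlation dimension, slope of log C(r) vs
  log r in a delay embedding (m = 10, τ = 1, Theiler window);
  Shannon entropy (bits) of recurrence diagonal line lengths at radius
  √m · SD.
* **Arrhythmias** (`classify_ventricular`, `chi2_uniformity`,
  `fold_change`): PVCs vs VT episodes (runs of ≥ 3 consecutive `V`
  beats) and VT beats as disjoint totals; chi-square goodness-of-fit on
  the four quartiles of the day; morning fold (6 AM–noon vs
  midnight–6 AM).
* **Rhythms** (`cosinor_fit`, `delta_metric`, `group_compare`,
  `fractional_shortening`): single-component cosinor
  y(t) = M + A·cos(2π(t − φ)/24) with the zero-amplitude F test;
  morning-minus-night deltas; unpaired t / one-way ANOVA with
  mean ± SEM; the echocardiographic FS = (LVEDD − LVESD)/LVEDD × 100.
* **Simulator** (`sim_config`, `simulate_holter`): integral pulse
  frequency modulation with circadian, LF/HF-modulated, fractal
  (spectral-synthesis) rate components; inhomogeneous-Poisson PVC/VT
  injection with a half-wave-cosine morning-surge profile; 1/125-s
  timestamp quantization; CSV round trip (`write_beats`/`read_beats`).
* **Pipeline** (`holter_metrics`, `run_pipeline`, `cohort_configs`):
  per-3-h-window metric tables, delta and cosinor tables, pooled timing
  tests, a run manifest, and frozen "baseline" vs "chf" study
  conditions.

The numbered scripts under `analysis/` run the workflow as a study:
`01_simulate_cohorts.R` (two cohorts of 24-h recordings),
`02_hrv_metrics.R` (full per-window metric tables per cohort),
`03_contrast_stats.R` (cohort contrast and the fractional-shortening
worked example), writing tables under `results/`.

## Worked example

Simulate one 24-hour recording with a diurnal HR rhythm (mesor 90 bpm,
amplitude 10, afternoon acrophase), fractal variability, and ectopy
peaking mid-morning, then analyze it:

```r
library(holterchaos)

cfg <- sim_config(hr_mesor = 90, hr_circ_amplitude = 10, hr_acrophase = 15,
                  fractal_alpha = 0.8, fractal_sd = 3,
                  pvc_base_rate = 12, pvc_morning_fold = 2.5, pvc_acrophase = 9,
                  vt_rate = 1, seed = 42)
rec <- simulate_holter(cfg)
rec
#> <beat_stream 'sim-seed42'> 129600 beats over 24.0 h (start clock 00:00)
#>   labels: N=128979 V=621 A=0 X=0

arr <- classify_ventricular(rec)
arr
#> <arrhythmia_counts> 432 PVCs, 36 VT episodes (189 VT beats)
chi2_uniformity(arr$by_window$pvc)
#> <timing_test> chi2 = 62.093 (dof 3), p = 2.099e-13
#>   morning fold (6-12h vs 0-6h): 1.87

m <- holter_metrics(rec)          # 8 windows x {HR, SDNN, LF/HF, a1, CD, SE, ...}
cosinor_fit(m$window_start_h + 1.5, m$mean_hr)
#> <cosinor_fit> mesor 90, amplitude 9.499, acrophase 15.05 h (period 24 h)
#>   zero-amplitude test: p = 3.317e-08 -> rhythmic
delta_metric(data.frame(start_clock_h = m$window_start_h, value = m$mean_hr))$delta
#> [1] 8.34
```

The chi-square test flags the non-uniform PVC timing (counts peak in
the 6 AM–noon quartile, 1.87-fold the preceding quartile); the cosinor
fit recovers the configured heart-rate rhythm (amplitude ≈ 9.5 of 10,
acrophase ≈ 15 h) and the morning HR rise is 8.3 bpm for this
configuration.

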