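---
title: "Methods: linear and nonlinear HRV analysis of 24-hour beat streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linear and nonlinear HRV analysis of 24-hour beat streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`holterchaos` analyzes 24-hour ambulatory (Holter) beat-annotation
streams — timestamped beats labeled normal (`N`), ventricular (`V`),
atrial (`A`) or artifact (`X`) — the export format of clinical Holter
systems after beat classification. The scientific setting is the study
of diurnal (time-of-day) structure in heart-rate dynamics: healthy
mammals show a morning rise in heart rate and in sympathovagal balance,
and fractal/complex beat-to-beat variability; chronic heart failure
(CHF) attenuates the morning rise, blunts autonomic oscillation,
reduces nonlinear "chaos" indices, and brings a morning surge of
ventricular arrhythmias. The package implements every stage needed to
quantify these phenomena, plus a seeded generator of synthetic 24-hour
recordings so the whole pipeline is testable without animal data.

This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic tests do and do
not establish about real recordings.

## 1. From beat annotations to NN intervals

All heart-rate-variability (HRV) mathematics operates on
*normal-to-normal* (NN) intervals: intervals bounded by two sinus
beats. `build_nn()` retains an interval iff both bounding beats are
labeled `N` **and** its duration lies within physiological bounds
(default 200–3000 ms, configurable). Consequently both intervals
adjacent to every ectopic or artifact beat are removed. Two design
points:

* **Both neighbors are dropped, not one.** An ectopic beat corrupts the
  interval into it and the interval out of it (the compensatory pause);
  excluding both is standard HRV practice.
* **Dropped, never interpolated.** Time-domain and nonlinear metrics
  see only genuine sinus intervals; successive-difference statistics
  (rMSSD) skip pairs broken by an exclusion. Spectral analysis, which
  needs an evenly sampled signal, performs its own resampling (below)
  and flags windows with gaps over 10 s as unusable rather than
  bridging them.

Recordings are segmented into clock-aligned, half-open windows
`[start, end)` tiling the 24-hour day: 3-h windows for metric tables
(eight per day) and 6-h windows for the four "quartiles of the day"
used in arrhythmia timing (midnight–6 AM, 6 AM–noon, noon–6 PM,
6 PM–midnight). An interval whose onset falls exactly on a boundary
belongs to the later window.

## 2. Arrhythmia quantitation

`classify_ventricular()` scans maximal runs of consecutive `V` beats:
runs of ≥ 3 beats are ventricular-tachycardia (VT) episodes (all their
beats counted as VT beats); `V` beats in runs of 1 or 2 are premature
ventricular complexes (PVCs, a couplet counting as two). The three
totals are therefore disjoint. An episode is timed and binned by its
first beat. A run interrupted by even one `N` beat ends — strict
maximal-run semantics.

Non-uniform timing over the day is tested with the chi-square
goodness-of-fit statistic on the four quartile counts (expected `N/4`
each, 3 degrees of freedom), alongside the *morning fold*: the count in
6 AM–noon divided by the count in the preceding quartile. A zero
denominator yields a flagged undefined fold, never an error; expected
counts below 2 attach a low-count flag because the asymptotic test is
then unreliable. Enumerating all 4-bin compositions of small totals
shows the chi-square ordering agrees closely with the exact multinomial
likelihood-ratio ordering (Spearman ρ > 0.97 at totals 12–20), though
not identically — a known property of the two statistics.

## 3. Linear HRV

Time-domain markers are the classical ones: mean RR, mean HR, SDNN,
CV = SDNN/meanRR × 100, and rMSSD. SDNN uses the population form of the
standard deviation so closed-form fixtures (e.g. a perfectly
alternating series) evaluate exactly.

Frequency-domain analysis follows standard tachogram practice:

1. cubic-spline resampling of `(onset, nn_ms)` onto a uniform 4-Hz grid
   (Nyquist 2 Hz comfortably covers the high-frequency band), mean
   removed;
2. autoregressive model fitted by Burg's method, order 16 by default
   (both exposed in the API) — the order is in the range conventional
   HRV software defaults to;
3. the parametric one-sided spectrum evaluated on a ≥ 512-point grid
   over `[0, fs/2]` and integrated over the low-frequency band
   0.04–0.15 Hz and the high-frequency band 0.15–0.40 Hz, half-open so
   0.15 Hz is counted once. LF/HF is the band-power ratio.

Within each 3-h window, spectra are computed per 5-minute sub-segment
and averaged before band integration (`window_spectral()`); multi-hour
windows are far from stationary, and averaging short-segment spectra is
the usual remedy. The AR fit is checked for pole stability and the
integrated spectrum reproduces the signal variance within ~10% for
well-conditioned (noise-like) inputs; heavily line-spectral inputs
concentrate power into peaks narrower than the frequency grid, which is
why band *ratios*, not absolute band powers, are the robust output.

## 4. Nonlinear dynamics

### Detrended fluctuation analysis

The interval series is mean-centered and integrated; the profile is cut
into non-overlapping boxes of size `n` (partial tail boxes discarded),
linearly detrended per box, and the RMS fluctuation `F(n)` is regressed
on `log n`: α1 over boxes 4–16 beats, α2 over 16–64 — the conventional
short- and long-range windows for beat data. One refinement: for
uncorrelated input the exact expectation of the raw fluctuation is
`E[F²(n)] = σ²(n² − 4)/(15n)`, not `σ²n/15`, so plain DFA is biased
upward at the small scales α1 uses (white noise reads ≈ 0.59 over
4–16). The implementation divides `F²(n)` by the finite-size factor
`(1 − 4/n²)`, which makes uncorrelated input scale as exactly `n^1/2`
at every box size. With the correction, simulated white noise gives
α1 ≈ 0.50 and integrated white noise ≈ 1.42 (the residual deficit from
1.5 is the Brownian small-scale bias, which the white-noise factor does
not target). Degenerate (constant) input raises an error rather than
returning a slope of nothing.

### Correlation dimension

The Grassberger–Procaccia estimator on a delay embedding: vectors
`(x_i, x_{i+τ}, …, x_{i+(m−1)τ})` with m = 10, τ = 1 by default (the
defaults of widely used HRV software; both exposed). The correlation
integral `C(r)` counts pairs closer than `r` (Euclidean), excluding
pairs within a Theiler window of `m·τ` samples to suppress trivial
temporal neighbors. The dimension is the slope of `log C(r)` vs
`log r` over the small-`r` scaling region; the automatic threshold grid
spans the 0.1%–50% quantiles of the pairwise-distance distribution
(estimated on a bounded random pair sample, fixed internal seed) and
the fit uses grid points with `C(r) ≤ 0.2` and ≥ 10 pairs. Fits with
fewer than 3 usable points are flagged unreliable. The estimator
recovers dimension ≈ 1 for an incommensurately sampled sinusoid (a
limit cycle) and ≥ 2.5 for iid noise embedded at m = 3; an exactly
periodic *resampling* of a sinusoid (rational frequency ratio) visits
finitely many phase points and is deliberately not a valid test signal.

### Shannon entropy of recurrence diagonal lines

The recurrence plot of the same embedding at a single radius — default
`√m · SD(series)`, the convention of standard RQA tooling — is scanned
for maximal diagonal line segments of length ≥ 2 (off the main
diagonal, beyond the Theiler window). The entropy of the line-length
histogram, `−Σ p(ℓ) log₂ p(ℓ)`, is reported in bits. Zero lines yield a
flagged missing value, not 0 (which would mean "one line length", a
different statement). The compiled kernel agrees exactly with a
brute-force recurrence-matrix enumeration on series up to 1000 points
(tested), and closed forms hold by construction: a histogram
concentrated on one length has 0 bits; uniform over 8 lengths, 3 bits.

Both O(N²) kernels are implemented in C++ (Rcpp). Per 3-h window the
nonlinear metrics use at most 5000 NN intervals (uniform subsample
beyond that), bounding the pair count at ~12.5 million — the choice
that keeps a full 24-hour recording's metric table near five seconds on
one core.

## 5. Rhythm statistics

`cosinor_fit()` fits `y(t) = M + A·cos(2π(t − φ)/P)` by the standard
linearization (`M`, `β₁cos ωt`, `β₂sin ωt`), giving closed-form
MESOR `M`, amplitude `A = √(β₁²+β₂²)` and acrophase `φ` via `atan2` —
no iterative optimization, hence no convergence ambiguity. The period
is fixed at 24 h for the rhythmicity decision; the zero-amplitude F
test (2 numerator dof against the constant model) declares a metric
rhythmic at p < 0.05. An optional profiled fit reports the
least-squares period over 20–28 h, but the decision rule deliberately
stays at the fixed period so the test statistic has a determinate null
distribution; its empirical size under Gaussian noise is 0.05 within
Monte-Carlo error (tested). Shifting all times shifts the acrophase
equivariantly; adding a constant moves only the MESOR.

Morning-vs-night contrast: `delta_metric()` averages the 3-h-bin means
covering 6 AM–noon and subtracts the average over midnight–6 AM,
computed per subject and then compared across groups —
`group_compare()` uses the unpaired pooled-variance t test for two
groups and one-way ANOVA for three or more, reporting mean ± SEM per
group. `fractional_shortening()` evaluates the echocardiographic
formula FS = (LVEDD − LVESD)/LVEDD × 100 with a physiology check
(0 < LVESD < LVEDD).

## 6. The synthetic Holter generator

### Beat timing

Beats are emitted by integral pulse frequency modulation (IPFM): a beat
each time `∫ m(t) dt` crosses an integer, with instantaneous rate
(beats/s)

    m(t) = [ M + A·cos(2π(t_clock − φ)/24) + x_frac(t) ] / 60
           × [ 1 + d_LF(t_clock)·sin(2π f_LF t) + d_HF·sin(2π f_HF t) ]

IPFM is the standard generative link between modulation frequencies and
tachogram spectral peaks, which is exactly what the downstream AR
spectra must detect. The integral is accumulated on a 40-ms grid,
crossings located by linear interpolation within a step, and timestamps
snapped to the 1/125-s grid of a 125-Hz digitizer. Quantization is done
as `round(125 t)/125` so that the 3-decimal CSV representation parses
back bit-identically. The generator refuses configurations whose rate
ever becomes non-positive.

The fractal component `x_frac` (bpm) is synthesized spectrally: Fourier
amplitudes shaped as `f^(−β/2)` with `β = 2α − 1`, uniform random
phases, inverse transform, rescaled to the requested SD — so DFA of the
noise itself recovers α (α = 0.5 white, 1.0 pink, 1.5 Brownian). It is
sampled at 2 Hz and linearly interpolated onto the integration grid;
with 4-bpm noise, the measured α1 of the resulting NN series tracks the
configured α monotonically over α ∈ [0.4, 1.2]. Above ≈ 1.2 the
fine-scale fluctuation of such smooth noise falls below the 1/125-s
quantization floor and α1 saturates — a faithful property of digitized
recordings, and the reason the monotonicity test sweeps only the
physiological range.

The LF depth can optionally carry its own diurnal modulation
(`lf_circ_frac`, default 0 — constant depth): the effective depth is
`d_LF·(1 + lf_circ_frac·cos(2π(t_clock − lf_circ_acrophase)/24))`. This
is what lets a healthy arm show a *morning rise in LF/HF* while a
failing arm shows none; with the default 0 the rate law reduces to the
fixed-depth form.

### Ectopy

PVC and VT event times follow an inhomogeneous Poisson process (by
thinning) with the half-wave-rectified cosine rate profile

    r(t) = r₀ · (1 + (F − 1)·max(0, cos(2π(t_clock − φ_e)/24)))

— smooth, integrable, and with a single fold parameter `F`. Note that
`F` is the *peak rate* fold; the implied quartile *count* ratio is the
ratio of the profile's integrals over 6 AM–noon and midnight–6 AM
(`ectopy_rate_integral()`), e.g. ≈ 1.84 for F = 2.5 at acrophase 9 h.
A PVC replaces one sinus beat with a `V` beat at 60% of the local RR (a
realistic shortened coupling interval) followed by a compensatory pause
— precisely the signature the NN exclusion logic must catch; a VT
episode relabels a run of consecutive beats, length uniform on
`[vt_len_min, vt_len_max]`. Injection never reorders timestamps, never
changes duration, and refuses configurations denser than half the
underlying beats.

### Study-condition cohorts

`cohort_configs()` freezes the two conditions used across the tests,
the analysis scripts, and the acceptance script:

| parameter | baseline | chf | rationale |
|---|---|---|---|
| HR mesor (bpm) | 104 | 87 | reported 24-h means |
| circadian amplitude (bpm) | 14 | 6 | yields morning ΔHR ≈ 11.7 vs ≈ 5.4 bpm (reported: 12.47 vs ~6) |
| acrophase (h) | 15 | 15 | afternoon HR peak, diurnal mammal |
| LF depth / diurnal frac | 0.04 / 0.5 | 0.015 / 0 | sympathetic predominance with waking-hours rise; LF variability largely lost in CHF |
| HF depth | 0.025 | 0.02 | respiratory modulation, mildly reduced |
| fractal α / SD (bpm) | 0.9 / 4 | 0.45 / 1 | near-1/f healthy scaling vs whiter, low-power variability (reported CHF α1 ≈ 0.456); total SDNN roughly halves |
| PVC, VT rates (/h) | 0 | 20, 1.5 | essentially arrhythmia-free healthy arm; frequent ectopy in CHF |
| morning fold / acrophase | — | 2.5 / 9 h | morning-surge profile peaking mid-morning |

Within this generator family the small-radius correlation dimension is
governed mainly by the fine-scale noise amplitude (noise fills the
embedding space) while recurrence-line entropy is governed by
large-scale smoothness; the failing-heart arm therefore expresses
"reduced chaos" through *low-amplitude, whiter* noise together with
weakened modulation, which lowers α1, CD and SE simultaneously — the
direction pattern of the modeled disease. The generator emulates the
*statistical* structure the analyses assume (diurnal rhythm, LF/HF
modulation, fractal scaling, morning-surge ectopy); it does not emulate
deterministic cardiac chaos, actigraphy-driven nonstationarity, sleep
stages, or annotation noise, so passing tests validate the estimators
and pipeline — not any biological claim about real recordings.

## 7. Problem sizes, determinism, degenerate inputs

* Default analysis sizes: 24-h recordings at ~90–105 bpm (≈ 125–150k
  beats), 3-h metric windows, ≤ 5000 NN intervals per window for the
  quadratic kernels, 5-min spectral sub-segments. The test suite and
  the acceptance script use 4–5 subjects per cohort arm; oracle
  simulations use n = 8192 series over 20 seeds.
* Every stochastic component draws from an explicit seed; the master
  seed is split per sub-process (fractal noise, PVC placement, VT
  placement) so enabling ectopy does not perturb the underlying sinus
  stream. Internal helper draws save and restore the caller's RNG
  state. Identical configurations produce byte-identical tables.
* Degenerate inputs fail loudly and specifically: constant series
  (DFA/CD/SE), unstable AR fits, non-monotone timestamps (with the
  offending row), rate ≤ 0 configurations, over-dense ectopy, empty NN
  series, cosinor designs with < 3 distinct clock times. Undefined
  quantities that are *data outcomes* — a zero night-quartile count, a
  lineless recurrence plot — are flagged `NA`, not errors.

## 8. Known limitations

* CD values on noise-dominated series sit near the embedding ceiling
  (≈ 6 at m = 10 with 5000 points) and are meaningful comparatively,
  not as absolute attractor dimensions.
* The finite-size DFA correction is exact for uncorrelated input only;
  strongly anti-correlated or integrated processes retain their own
  small-scale biases (Brownian α1 reads ≈ 1.42, not 1.50).
* The cosinor rhythmicity test assumes independent residuals; applied
  to pooled per-window metrics it is a descriptive screen, not an
  inference corrected for within-subject correlation.
* WFDB support covers plain-text annotation dumps (`rdann`-style), not
  binary `.atr` files.
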