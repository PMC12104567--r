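---
title: "Burst-suppression EEG and photometry analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Burst-suppression EEG and photometry analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsrtools)
```

## The measurement problem

Under deep volatile anesthesia (e.g. sevoflurane around 3 vol%), cortical
EEG alternates between high-amplitude *bursts* and near-isoelectric
*suppression* periods. The fraction of time spent suppressed — the burst
suppression ratio (BSR) — is a standard depth-of-anesthesia readout, and in
aging studies it separates cohorts: aged animals suppress longer and
emerge later at equal anesthetic concentration. Alongside the EEG, fiber
photometry of an ATP sensor gives a slow fluorescence trace whose decline
during anesthesia quantifies cortical energy state, and qPCR/densitometry
provide per-animal scalar molecular measures. `bsrtools` implements this
whole analysis chain, plus a generative model of the data so every
estimator can be validated against ground truth.

## The suppression rule and its conventions

A suppression event is a maximal run of samples with `|x| <= threshold_uv`
lasting strictly longer than `min_duration_s`. Defaults are 15 µV and
0.2 s at 250 Hz sampling. Several boundary conventions are deliberate and
tested:

* the amplitude comparison is **inclusive** (a sample at exactly 15 µV is
  suppressed) and the duration comparison **strict** (a run of exactly
  0.2 s — 50 samples at 250 Hz — is discarded; 51 samples are kept);
* a run of *k* samples spans *k/fs* seconds and is reported as the
  half-open interval `[onset_s, offset_s)`;
* runs are **not merged** across brief supra-threshold excursions — no
  merge rule is part of the definition, and merging would inflate
  durations;
* runs touching the record edges are kept; their observed duration is a
  lower bound on the true one;
* detection runs on the 0.5–70 Hz filtered signal by default (the
  recording band), with `filter = FALSE` to analyze raw input.

Cumulative suppression time sums event–window intersections over the
anesthesia window `[onset, cessation)`; BSR is that sum divided by the
window length, in percent. The windowed BSR time course uses 60-s windows
stepped by 10 s — the window must smooth over individual burst/suppression
cycles (seconds to tens of seconds) while following slow drift; with
step = win the windowed values average exactly back to the global BSR.

## Filtering

The recording band is 0.5–70 Hz. The filter family and phase behavior are
an implementation choice: a 4th-order Butterworth applied
forward–backward (`signal::filtfilt`) gives zero phase shift, which
matters because filtering feeds a *duration-threshold* rule — a causal
filter's group delay would bias event onsets and offsets. A causal
single-pass option (`zero_phase = FALSE`) is provided for comparison with
on-line hardware filtering. Tests pin the passband (10 Hz tone within 5%
RMS), stopband (≥ 20 dB at 100 Hz), DC rejection, and linearity.

## Spectral estimates

Band power uses a Welch estimator written for this package: Hamming-tapered
2-s segments with 50% overlap (75% for display spectrograms), segment means
removed, one-sided density scaling checked against Parseval. Two seconds at
250 Hz gives 0.5-Hz resolution, which places every band edge (0.5, 4, 8,
15, 25 Hz) exactly on a bin boundary.

Band power is the rectangle-rule sum of the PSD over bins in the half-open
band `[lo, hi)`. Half-open edges prevent double counting at the shared
edges (4, 8, 15 Hz), and the rectangle rule makes the four band powers sum
*exactly* to the 0.5–25 Hz total, so the reported fractions are a true
composition (they sum to 1 to machine precision, and are invariant to
rescaling the trace). The denominator is the union of the four reported
bands, 0.5–25 Hz, rather than the full 0.5–70 Hz recording band; this is
configurable (`total_range`) since published "relative power" bars rarely
state their denominator.

Band power is computed over the full anesthesia window, suppression
epochs included — no epoch exclusion is applied anywhere.

## Photometry ΔF/F

ΔF/F is `(F − F0)/F0` with `F0` the mean fluorescence over a 100-s control
window. The placement of the control window is a choice: the 100 s
immediately *preceding* anesthesia onset, so that the during-anesthesia
change is measured against the awake baseline; both the window and its
length are arguments. A guard refuses non-positive baselines. No
detrending or isosbestic (405-nm reference) correction is applied — no
such correction procedure is part of the analysis being implemented, and
silently applying one would change the estimand; bleaching is instead part
of the simulator, so its effect on the estimators is quantified in tests
(a 0.002 a.u./s drift on F0 = 100 biases the young-preset change by about
−1%, visible in the demo output). The pre/during change is
`mean(ΔF/F during) − mean(ΔF/F pre)`; group traces are aligned at
anesthesia onset, truncated to common support, and summarized as mean ±
SD/√n.

## Molecular quantification

Relative expression uses the 2^(−ΔΔCt) method: ΔCt = Ct(target) −
Ct(reference gene), ΔΔCt = ΔCt − baseline, expression = 2^(−ΔΔCt). The
baseline is the **arithmetic mean ΔCt of the calibrator group** (the usual
convention when no explicit pairing exists), which makes the calibrator
group's *geometric* mean expression exactly 1; a per-position paired
baseline is available (`baseline = "paired"`). ΔΔCt is invariant to adding
a constant to all reference Cts, and log2(expression) = −ΔΔCt exactly —
both are tested. Densitometry is the per-lane ratio of target to internal
loading-control intensity. No amplification-efficiency correction is
applied (Ct tables, not standard curves, are the input).

## Group statistics

The decision path mirrors common practice in this literature: each group
is tested for normality — Shapiro–Wilk for n ≤ 50, the Lilliefors variant
of Kolmogorov–Smirnov above (Shapiro–Wilk's reference implementation is
sample-size-limited, and Lilliefors handles the estimated-parameter null
correctly) — at α = 0.05. If both groups pass, an unpaired two-sided
Student's *t*-test is used (equal variances by default, Welch by flag);
otherwise a two-sided Mann–Whitney test. Three or more groups use one- or
two-way ANOVA followed by Tukey's HSD. All reported dispersions are
SEM = SD/√n. A constant (zero-variance) sample is routed to the rank test,
which handles ties. The whole trail — tests chosen, normality p-values —
is recorded in the result object, so a reader can audit every decision.

Calibration is tested, not assumed: the type-I error of the *complete*
two-group path (gate plus test) stays within [0.01, 0.10] at nominal 0.05
over 200 replicates, and power for the aged-vs-young BSR contrast at n = 6
per group exceeds 0.95.

## The synthetic-data model

The generator is phenomenological: it reproduces the statistical structure
the estimators assume, not biophysics.

* **States.** Within the anesthesia window, burst and suppression states
  alternate with i.i.d. durations, exponential or gamma(k = 2), from a
  configured mean each; the window opens with a burst. By the
  renewal-reward theorem the long-run BSR is
  `mean_supp / (mean_supp + mean_burst)`.
* **Waveforms.** Suppression is zero-mean Gaussian noise at 4 µV SD —
  below a third of the 15 µV criterion, so suppression samples satisfy it
  with per-sample probability > 0.999. Bursts are a weighted sum of
  band-limited noise (one component per EEG band, Butterworth-filtered
  white noise, combined as √weight so band power fractions equal the
  weights) rescaled to 40 µV RMS, which breaks the threshold essentially
  always within 0.2 s. Awake segments use the same carrier at 25 µV RMS.
* **Transitions.** 50-ms raised-cosine amplitude ramps avoid spectral
  splatter from step edges. The ramps are placed entirely *inside* the
  non-suppression segments: suppression-labeled samples therefore contain
  only suppression-state noise, so the per-sample amplitude criterion
  holds on exactly the samples labeled suppressed, at the cost of slightly
  tapered burst edges (which can only lengthen detected suppressions by a
  fraction of the ramp). With ramps centered on the boundary instead,
  roughly 0.3% of suppression-labeled samples would carry half-amplitude
  burst signal and violate the criterion.
* **Presets.** The aged preset uses gamma(k = 2) durations with means
  6 s/4 s (target BSR 60%) and a delta-dominant band mix
  (0.60/0.20/0.12/0.08); the young preset 4 s/16 s (target 20%) with a
  flatter mix (0.30/0.25/0.25/0.20). Gamma(k = 2) was chosen for the
  presets because its duration CV of 1/√2 puts the 20-min ground-truth BSR
  at ≈ 2.2 percentage points SD (delta method:
  `sd ≈ 100·µ_s·µ_b/(µ_s+µ_b)² · √((CV_s²+CV_b²)/n_cycles)`), so the
  simulated cohorts sit reliably near their targets; the exponential law
  remains the config default since its many sub-0.2-s suppressions
  exercise the detector's discard rule. Photometry presets: young flat,
  aged 20% saturating decline (τ = 60 s) locked to anesthesia onset, both
  with 1 a.u. noise on F0 = 100 and mild bleaching. Emergence times are
  lognormal (young ~120 s, aged ~300 s, σ_log = 0.2); tissue ATP and qPCR
  ΔCt are Gaussian scalars with group means ordered as in the aging
  phenotype.
* **Seeding.** Every generator is a pure function of (config, seed); the
  global RNG state is saved and restored. Cohort per-subject seeds are
  `master + 1000·group + subject`, recorded in the manifest for exact
  replay.

**What the simulator does not emulate** — and hence what passing tests do
*not* show about real data: no biophysical burst waveforms (real bursts
have stereotyped morphology, not band-limited noise), no EMG or movement
artifacts, no electrode drift or line noise, no within-subject
non-stationarity of state statistics (real BSR deepens over an exposure),
no isosbestic channel, and Gaussian rather than heavy-tailed noise.
Ground-truth recovery here validates the *estimators' arithmetic and
boundary logic*, not their robustness to artifacts.

## Numerical choices and degenerate inputs

* TSV timebases must be uniform within 1 ppm; the rate is the reciprocal
  median step. TSV round-trips are exact to double precision; EDF (16-bit,
  symmetric physical range over the observed amplitudes) round-trips
  within one quantization step. Empty recordings are refused.
* Time is seconds from record start; all windows are half-open
  `[start, end)`; ground-truth labels assign each sample by its start
  time.
* A 20-min white-noise check places the four band fractions within ±0.02
  of the bandwidth ratios (0.143, 0.163, 0.286, 0.408); tone fixtures
  place ≥ 99% of power in the containing band.
* Tie/degenerate cases: identical samples give p = 1 on the rank path;
  zero-length windows, overlapping epoch windows, non-positive baselines,
  unsorted or overlapping event tables all raise classed errors naming
  the offending quantity.

## Problem sizes

The validation suite runs at the study's own scale where that is cheap —
20-min, 250 Hz recordings for ground-truth recovery (100 seeds via the
state-level generator, full waveforms where detection is exercised), the
demonstration cohort at 2 groups × 4 subjects — and at reduced but
statistically adequate sizes elsewhere (50–1,000 random traces for oracle
equivalence, 100–200 replicates for calibration), chosen so the whole
suite completes in a few minutes on one core.

## Known limitations

* The BSR window parameters of commercial scoring software are not public;
  our 60 s/10 s time-course choice is documented but not comparable
  bit-for-bit with vendor output.
* Whether the published ±15 µV criterion applies to raw or re-referenced
  signal is unstated in the sources that use it; both paths are exposed
  (`filter` flag) with the filtered path as default.
* The EDF writer emits standard EDF with a single data record and sidecar
  JSON annotations, not EDF+ embedded annotations.
* No artifact rejection beyond the band-pass; recordings with movement
  artifacts inside the anesthesia window will bias suppression metrics.
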