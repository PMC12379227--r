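---
title: "Methods and design choices in somnoflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in somnoflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnoflow)
```

somnoflow chains four analyses that usually live in separate tools: sleep
scoring and architecture from EEG/EMG, infraslow norepinephrine (NE)
oscillation metrics from two-channel fiber photometry, differential
statistics for label-free (LFQ) proteomics, and two histology
quantifications. This vignette explains the models behind each stage, the
parameters that matter, the choices we made where the methodology is
genuinely open, and what the synthetic-data generators do and do not
emulate.

## Sleep scoring and architecture

Vigilance states are defined by joint EEG/EMG signatures: WAKE has high
muscle tone with low-amplitude, high-frequency EEG; NREM is atonic with
high-amplitude slow (delta, 1–4 Hz) EEG; REM is atonic with theta-band
(4–8 Hz), low-amplitude EEG. Scoring in practice is often manual;
somnoflow implements a deliberately transparent automated stand-in so
that pipelines can run unattended: per epoch (5 s by default, 1 s when
photometry-aligned) we compute delta and theta band power from the raw
periodogram, the EMG root-mean-square, and apply a three-rule tree —
EMG above threshold is WAKE; otherwise delta/theta above threshold is
NREM; the remainder is REM. Externally scored hypnograms in the package's
TSV layout can be ingested verbatim instead.

When thresholds are not supplied, each is calibrated as the midpoint of
the two 1-d k-means cluster centres of the relevant feature on a log
scale (EMG RMS over all epochs; delta/theta over the atonic epochs).
k-means rather than a fixed quantile because the threshold then does not
depend on the unknown prevalence of wakefulness in the session. A third
threshold slot (`theta_ratio_hi`) is accepted for interface compatibility
with rule variants but the default tree never consults it: the REM rule
is the fall-through branch, so forcing all thresholds to `+Inf` labels
everything REM by construction.

Band intervals are half-open `[lo, hi)` so the shared 4 Hz edge between
delta and theta is counted exactly once. Trailing partial epochs are
dropped, never padded. Bouts are maximal same-state runs; with a minimum
bout duration, sub-threshold runs are merged into the longer neighbour
(ties to the preceding one), shortest offenders first. State latencies in
`architecture_stats()` are measured from the start of the recording — a
convention, since a sleep-onset reference is equally defensible; the bout
table makes either computable.

Welch spectra of state-restricted EEG default to 4 s Hann windows with
50% overlap, resolving 0.25 Hz bins so the 1–4 Hz delta band spans
integer bins; no installed package provides a Welch estimator, so the
package carries its own, normalised as a one-sided density (its integral
is checked against the series variance in the tests). The slow-wave
activity (SWA) time course reports, per time bin, mean per-epoch NREM
delta power as a percentage of a baseline value or baseline interval.
Power scales with amplitude squared: a 1.5-fold delta amplitude rebound
reads out as 225% SWA, which the tests confirm on synthetic recordings.
Bins without NREM epochs are missing, not zero.

## Isosbestic correction and infraslow NE metrics

The 405 nm excitation is isosbestic for the NE biosensor: its
fluorescence shares bleaching and movement artefacts with the 465 nm
signal but is insensitive to ligand binding. We fit
`scaled405 = a*F405 + b` by ordinary least squares on the whole session
and compute `dF/F(%) = (F465 - scaled405) * 100 / scaled405`; a
self-median variant (`(F465 - median)/median`) is available when the
isosbestic channel is unusable. A scaled channel that touches zero is an
error (reported with the first offending sample), not a silent Inf.

For oscillation metrics, each NREM bout is detrended with a least-squares
polynomial (order 2 by default, configurable 0–5) — centring it and
removing residual bleach curvature — and a Welch PSD computed per bout;
bout PSDs are averaged with bout-duration weights (unweighted averaging
is one switch away). Welch parameters for the infraslow band are not
standardised anywhere; we default to 120 s Hann segments with 50%
overlap and a 120 s minimum qualifying bout, giving ~0.008 Hz bins
around the ~0.02 Hz NREM phenomenon. Four summary numbers are emitted
because the field reports them inconsistently: the maximum of the
averaged PSD ("amplitude"), its argmax frequency, the trapezoid integral
over a configurable 0.005–0.1 Hz band ("power"), and the NE peak rate.
Emitting both amplitude and integral sidesteps the ambiguity rather than
guessing.

Peak detection mirrors common findpeaks usage: local maxima within NREM
bouts, a minimum amplitude of 0.5 %dF/F, and a 10 s minimum inter-peak
interval where the taller peak survives (ties to the earlier). Because
detection runs on detrended bouts, "amplitude" is interpreted as
topographic prominence above the local detrended baseline rather than
absolute height — the two coincide on a flat baseline, and prominence is
the interpretation that survives drift. Bout edges are hard: the interval
constraint is not enforced across bouts. The suppression rule is verified
against a brute-force oracle on every test trace with up to 12
candidates.

## LFQ differential analysis

Filtering follows standard LFQ practice: samples must detect at least
half the median per-sample protein count; proteins must be observed in at
least a configurable fraction (0.7 for small extracellular-fluid panels,
0.9 for deep CSF data) of the members of at least one group, with the
fraction converted to whole samples by ceiling.

Missingness in LFQ is intensity-dependent (MNAR): low-abundance proteins
drop out preferentially. The mixed imputation therefore splits on
detection fraction at `knn_cutoff = 0.6`: mostly-observed proteins are
treated as missing-at-random and imputed by k-nearest-neighbour
regression (neighbours = most Pearson-correlated proteins over shared
samples, k = 3 by default, imputed value = mean of neighbour values at
that sample); sparse proteins are treated as left-censored and imputed by
per-sample Gaussian draws with mean `sample_mean - 1.8 * sample_SD` and
SD `0.3 * sample_SD`. The exact hybrid rule and KNN metric of upstream
pipelines are not published; fraction-valid split with
correlation-neighbour means is the common reading of that cutoff, and
both branch parameters are exposed. Observed cells are never altered,
and draws are seed-deterministic.

The test statistic is `t = (mean1 - mean2) / (pooled_se + s0)` with
`s0 = 0.5`: the offset damps proteins whose tiny variance would otherwise
make trivial fold changes significant. A pooled-variance (Student) SE is
the default since s0 moderation presumes one; Welch is available. The
null distribution pools the statistic over 250 distinct group-label
splits (all splits enumerated when fewer exist, e.g. 20 for 3 vs 3,
checked against hand enumeration in the tests); the SAM-style q-value is
the expected number of permuted exceedances divided by the observed
count, clipped at 1 and made monotone in |t|. Under a pure-null
simulation (1,000 proteins, 6 vs 6, 100 repetitions) the mean
false-discovery proportion stays at or below the nominal 0.05 within
Monte-Carlo error — the estimator is conservative, as expected without a
pi0 correction.

Enrichment is a two-sided Fisher exact test per gene set against the
detection universe with Benjamini–Hochberg adjustment; sets that do not
intersect the background are skipped and reported. CVs are computed on
linear-scale intensities (CVs on log scale are not CVs), correlations on
pairwise-complete observations, PCA by SVD of the centred imputed matrix.

## Histology quantification

Particle analysis labels connected components (8-connectivity by
default, matching the particle tools this emulates; 4-connectivity
available) and bins physical areas: below 5 µm² excluded, [5, 30) µm²
counted as microglial ramifications, [30, 90] µm² as microglial cells.
What happens above 90 µm² is unspecified in common protocols, so
oversize components are tallied separately rather than silently dropped,
and the four bins always partition the component count. Densities are
per mm². Labeling is implemented over the pixel-adjacency graph
(igraph components) and verified against an independent flood-fill
oracle on hundreds of random images, plus EBImage's 4-connected labeller
for the 4-connectivity configuration.

The AQP4 polarization index takes each vessel's line profile, finds the
intensity peak (the vessel-wall AQP4 ring), and subtracts the background
measured 5 µm from the peak. "5 µm of background" is ambiguous between a
point and a band; the default reads it as the mean of the two linearly
interpolated intensities exactly ±5 µm from the peak (one-sided if the
profile only extends that far on one side), with a band alternative
(mean of all samples at least 5 µm away) behind a switch. Profiles too
short for either side are skipped with a warning. Per-image indices are
vessel means; the normalized index divides by the cohort maximum, so
exactly one image scores 1 and constant intensity offsets cancel.

## Synthetic data: what it emulates, what it does not

Each generator reproduces the statistical structure its consumer assumes,
with ground truth returned alongside:

* `sim_hypnogram()` — first-order Markov state sequences; the default
  transition matrix gives mouse-like inactive-phase architecture
  (consolidated NREM, brief REM entered from NREM).
* `sim_eeg_emg()` — per-epoch band-limited tones (delta tone drawn from
  1.5–3.5 Hz, theta from 4.5–7.5 Hz, kept inside their bands because the
  0.2 Hz periodogram grid of a 5 s epoch would otherwise leak boundary
  tones across the shared 4 Hz edge) plus white noise, with
  state-dependent amplitudes and EMG RMS; a `delta_gain` vector emulates
  SWA rebound.
* `sim_photometry()` — shared exponential bleach and slow motion artefact
  on the isosbestic channel; the signal channel is the affine image of
  the shared baseline scaled multiplicatively by the NE component (a
  state-gated sinusoid during NREM, a plateau in WAKE). Motion enters
  both channels before the gain, so isosbestic regression can cancel it
  exactly — which the tests exploit as an invariance check. No SNR
  figures exist for these sensors in the sources we emulate; the default
  noise is set low enough that the 0.5 %dF/F peak threshold separates
  signal from noise, a testability choice rather than a realism claim.
* `sim_lfq()` — protein baselines around 25 log2 units with 2 SD
  between-protein spread, cell noise 0.5 SD, alternating-sign group
  shifts for a configurable regulated fraction, and logistic
  intensity-dependent censoring (midpoint 21.5, slope 0.8, i.e. the
  MNAR mechanism that motivates downshifted imputation).
* `sim_particle_image()` / `sim_vessel_profiles()` — non-touching compact
  blobs with exact pixel areas; Gaussian vessel-wall bumps (sigma 1 µm)
  on flat background whose corrected peak is analytic.

What passing tests show is therefore that each estimator recovers the
parameters of the process it assumes, at realistic problem sizes; they do
not show robustness to the things real data add — EEG artefacts and
state transitions inside epochs, hemodynamic contamination and sensor
kinetics in photometry, correlated protein blocks and batch effects in
LFQ, or anisotropic staining in histology. The scorer in particular is a
threshold tree, not a replacement for manual scoring on noisy recordings.

## Numerical choices and problem sizes

NE dynamics are simulated as a state-gated sinusoid plus plateau rather
than a biophysical model of the locus coeruleus: parameter recovery, not
biology, is what downstream estimators need to be tested against.
Simulated photometry in the tests and the verification script runs at
5 Hz — two orders of magnitude above the infraslow Nyquist requirement —
for sessions of ~3,200 s, sizes chosen so the whole verification suite
runs on a laptop core in minutes. Welch segments are Hann-tapered and
per-segment demeaned. All generators draw from a single seeded RNG
stream (`withr::with_seed`), making every fixture a pure function of its
spec; the pipeline writers stamp a package version, seed and parameter
hash into every artefact header, and re-runs with equal configuration
are byte-identical.

Known limitations: no EDF ingest (TSV/CSV only); no artefact rejection
or notch filtering (inputs are assumed pre-filtered); no demodulation of
lock-in carriers (inputs are the demodulated streams); REM/wake
oscillation metrics are intentionally absent (the infraslow analysis is
NREM-specific); and the exhaustive-table Fisher verification is bounded
(all tables to total n = 16, sampled tables beyond) because full
enumeration at larger margins is combinatorial.
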