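# somnoflow

Multimodal analysis toolkit for rodent sleep-neuroscience studies that
combine EEG/EMG sleep recordings, fiber-photometry norepinephrine (NE)
sensing, label-free quantification (LFQ) proteomics and histology. It is
aimed at labs that record sleep together with a fluorescent NE biosensor
(e.g. GRAB-NE) and need a reproducible, scriptable path from raw channels
to the quantities usually reported in figures: sleep architecture, NE
infraslow-oscillation metrics during NREM sleep, differential protein
tables, and microglia / AQP4 morphometry.

Every analysis stage has a matching synthetic-data generator with known
ground truth, so the full pipeline is testable without animal data.

## What it computes

**Sleep.** Per-epoch EEG band powers (delta 1–4 Hz, theta 4–8 Hz, half-open
bands) and EMG RMS; a transparent threshold-tree scorer (high EMG → WAKE;
atonic + delta-dominant → NREM; remainder → REM) with auto-calibrated
thresholds; bout extraction; architecture statistics; Welch state spectra;
and a slow-wave-activity (SWA) time course as % of a baseline delta power.

**Photometry.** The isosbestic correction fits the 405 nm channel to the
465 nm channel by least squares, `scaled405 = a·F405 + b`, and

```
ΔF/F(%) = (F465 − scaled405) · 100 / scaled405
```

NREM bouts are polynomial-detrended and their Welch power spectral
densities averaged (duration-weighted); the module reports the PSD
amplitude (maximum of the averaged PSD), its peak frequency, the infraslow
band power (integral over 0.005–0.1 Hz by default), and the NE peak rate
from prominence-based peak detection with a 10 s minimum interval and a
0.5 %ΔF/F minimum amplitude.

**Proteomics.** Sample QC (≥ 50% of the median detected-protein count),
group-completeness filtering (e.g. ≥ 70% or ≥ 90% of members in at least
one group), mixed imputation (KNN above a 0.6 detection-fraction cutoff,
otherwise per-sample downshifted Gaussian draws with downshift 1.8 SD and
width 0.3 SD), an s0-moderated t-statistic
`t = (m₁ − m₂)/(se_pooled + s0)` with `s0 = 0.5` and a SAM-style
permutation FDR (250 label permutations, q < 0.05), plus Fisher/BH
gene-set enrichment and CV / correlation / PCA QC summaries.

**Imaging.** 8-connected particle analysis with area bins — cells
30–90 µm², ramifications [5, 30) µm², < 5 µm² excluded — and the AQP4
vascular polarization index: line-profile peak minus the background 5 µm
from the peak, averaged per image and normalized to the cohort maximum.

## Worked example

```r
library(somnoflow)

# a 3-h NREM-rich session with a 0.02 Hz NE oscillation injected
hyp <- sim_hypnogram(3200, epoch_length_s = 1,
                     transition_matrix = matrix(
                       c(0.98, 0.02, 0.00,
                         0.003, 0.994, 0.003,
                         0.02, 0.02, 0.96), 3, byrow = TRUE),
                     initial_state = "NREM", seed = 1)
rec <- sim_photometry(hyp, sample_rate_hz = 5, osc_freq_hz = 0.02, seed = 2)

dff <- compute_dff(rec)                     # isosbestic-corrected %dF/F
metrics <- ne_metrics(dff, hyp)
glance(metrics)
#> # A tibble: 1 × 5
#>   psd_amplitude psd_peak_freq_hz infraslow_power peak_rate_hz n_bouts_used
#>           <dbl>            <dbl>           <dbl>        <dbl>        <int>
#> 1          131.           0.0167            1.96       0.0186            9
```

The PSD argmax lands on the Welch frequency bin nearest the injected
0.02 Hz (bin spacing 1/120 s ≈ 0.0083 Hz), and the detected peak rate
(0.0186 Hz over nine qualifying NREM bouts) recovers the oscillation
frequency to within 10%. `autoplot(attr(metrics,
"psd"))` draws the averaged spectrum, `autoplot(dff, peaks =
attr(metrics, "peaks"))` the trace with detected NE peaks.

Differential proteomics on synthetic data with 10% regulated proteins:

```r
sim <- sim_lfq(600, c(sleep = 6, sd24 = 6), seed = 3)
de <- sim$data |>
  filter_sample_qc() |>
  filter_group_completeness(sim$design, 0.7) |>
  impute_mixed(seed = 4) |>
  permutation_ttest(sim$design, seed = 5)
glance(de)
#> # A tibble: 1 × 8
#>   n_proteins n_significant  n_up n_down    s0 fdr_threshold n_permutations_used
#>        <int>         <int> <int>  <int> <dbl>         <dbl>               <int>
#> 1        530            13     5      8   0.5          0.05                 250
#> # i 1 more variable: exhaustive <lgl>
autoplot(de)   # volcano plot
```

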