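---
title: "Methods: quantifying cortical responses to FVS and NMES in EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying cortical responses to FVS and NMES in EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegstim)
```

## The problem

Peripheral somatosensory stimulation — focal vibration of a muscle belly
(FVS) or transcutaneous neuromuscular electrical stimulation (NMES) — evokes
measurable cortical responses in the EEG: a stimulus-locked P300 potential
over the midline, a transient theta-band power increase (ERS) at
stimulation onset, and a sustained alpha/beta-band power decrease (ERD)
over the sensorimotor cortex contralateral to the stimulated arm. After
stroke, these responses are attenuated and their lateralization shifts.
`eegstim` implements the full quantification pipeline for such studies —
preprocessing, four feature families, and the statistical battery — plus a
synthetic-data generator that emulates the factorial study design with
known ground truth, so every stage is testable end to end without access
to human recordings.

## Study design emulated by the generator

The default `design_spec()` encodes a two-group factorial protocol:

* two groups (stroke, control), 15 participants each;
* two target arms (dominant, nondominant) and two forearm muscle unions
  (ECU–ED, FCR–FD) per participant;
* eight stimulation schemes: five FVS intensities, 1.9 G (FVS-1) down to
  0.7 G (FVS-5), and three NMES intensities anchored at the motor
  threshold (NMES-1), the median of perceptual and motor thresholds
  (NMES-2), and the perceptual threshold (NMES-3);
* one 4-min trial per scheme containing six 10-s stimulation blocks;
* 62 analyzed channels on the 10-10 layout at 1000 Hz.

Enumerating participants × arms × unions × schemes × blocks × channels
gives 178,560 episode records per group — the bookkeeping unit every
downstream table is keyed on.

The montage constant (`montage_1010()`) is a 10-10 cap with the FCz
reference excluded. The exact channel list is a documented default, not a
claim about any particular amplifier: it is overridable through
`design_spec(analyzed_channels = ...)`, and only the midline (Fz/Cz/Pz),
C3/C4, and the two sensorimotor sets are load-bearing for the pipeline's
defaults.

### Block schedule

Blocks are placed at a fixed 35-s spacing (10 s on, 25 s quiet), the first
at 20 s. Any schedule with at least 20 s of quiet between blocks is valid;
the fixed spacing is a reproducibility choice, not an inference about how
the acquisitions were actually scheduled. Constructors reject schedules
violating the quiet-gap or trial-duration invariants.

## Signal model

Each channel is a sum of

* 1/f background noise (flat below 1 Hz, 8 µV RMS by default), and
* four band-limited Gaussian oscillators (theta 4–8, alpha 8–12, beta
  13–30, gamma 30–100 Hz) with unit-mean envelopes and default RMS
  amplitudes of 3/5/3/1.5 µV.

Noise and oscillators are synthesized in the frequency domain: complex
Gaussian amplitudes are drawn on the in-band FFT bins, Hermitian-mirrored,
and inverse-transformed. This makes the oscillators exactly band-limited
(the PSD concentration test demands ≥ 90 % of power in the nominal band)
and is considerably faster than time-domain filtering at the 240,000
samples of a full-scale trial.

Injected, block-locked effects (all parameters in `default_effects()`):

* **P300** — a positive half-cosine of amplitude `p300_amp`, width 0.30 s,
  centered `p300_latency` after block onset, added to Fz/Cz/Pz with
  weights 0.8/1.0/0.9.
* **Alpha/beta ERD** — the oscillator envelope is multiplied by
  `1 − depth · exp(−(t − onset)/tau)` on sensorimotor channels: maximal
  desynchronization at onset, exponential return toward baseline
  (adaptation, `tau` = 4 s by default).
* **Theta ERS** — envelope multiplied by `theta_ers_gain` over the first
  0.5 s of each block.
* **Laterality** — sensorimotor effects are split between hemispheres:
  a fraction `laterality_weight` (0.80) on the hemisphere contralateral to
  the stimulated arm, the remainder ipsilateral. The generator assumes the
  dominant arm is the right arm.

Effect scaling across conditions is monotone in a normalized stimulus
drive (FVS: amplitude relative to 1.9 G; NMES: 1/0.75/0.5 for
motor/median/perceptual): higher drive gives a larger and earlier P300 and
deeper ERD. At matched rank, FVS latencies (0.34–0.50 s) are shorter than
NMES latencies (0.45–0.60 s). The stroke group scales P300 amplitude,
theta gain, and ERD depths by 0.6 and moves `laterality_weight` to 0.65 —
a shift of sensorimotor activation toward the contralesional hemisphere.
These numbers are calibrated to produce the qualitative contrasts the
statistics must detect (amplitude ordering, latency ordering, group
attenuation) at realistic single-trial signal-to-noise; they are the fixed
study conditions for all tests, not tuning knobs.

What the generator does **not** emulate: ocular/muscular artifacts beyond
broadband noise, volume conduction and channel covariance, biophysical
head geometry, nonstationary background (drowsiness, drift), or
inter-subject amplitude variability. Passing tests therefore demonstrate
correctness of the computations and recoverability of effects under this
model — not robustness to every pathology of real EEG.

## Preprocessing

`bandpass_notch()` applies a fourth-order Butterworth band-pass (1–100 Hz)
and band-stop (49–51 Hz), both **forward–backward**. Zero-phase filtering
is essential because the pipeline measures P300 latency; the cost is that
each stage's magnitude response is applied twice, so effective attenuation
doubles (the 50 Hz test tone loses > 50 dB rather than ~26 dB).

`flip_montage()` mirrors the data of left-lesion participants across the
mid-sagittal plane (C3↔C4, FC1↔FC2, …) so the affected hemisphere is on
the right for every stroke participant; midline channels and everyone else
pass through unchanged. The operation is an involution and errors on
montages with unpaired lateral channels.

`segment_epochs()` cuts one 15-s epoch per event marker with half-open
spans: baseline `[−5, 0)` s, stimulation block `[0, 10)` s; the onset
sample belongs to the block. Events with insufficient record context are
skipped with a warning and logged, not silently dropped.

`reject_artifacts()` replaces operator screening with a deterministic
rule: drop an epoch iff any channel's peak-to-peak amplitude exceeds
200 µV or any sample is non-finite. This is a reproducible stand-in, not a
reconstruction of what a human operator would have removed; ICA is out of
scope by design.

## Features

**ERP / P300.** Per channel, `ERP(t) = p_block(t) − mean(p_baseline)`. The
midline P300 is the unweighted Fz/Cz/Pz average. Per participant and
condition, the six block ERPs are averaged *before* peak extraction (the
reading-unit convention). The peak is the maximum inside 0.25–0.80 s with
earliest-time tie-breaking; no smoothing is applied because the peak (not
a local mean) is the declared estimand.

**Relative spectral power.** `RSP = block-band fraction − baseline-band
fraction`, each fraction relative to total 1–100 Hz power. The block
spectrum uses a Hann periodogram of the 0.30–0.75 s period of interest,
zero-padded to a ≤ 1 Hz grid; the baseline uses Welch's method (2-s
segments, 50 % overlap) over the full 5-s baseline. A duration-matched
baseline slice is available behind `matched_baseline = TRUE`; the
full-baseline default trades bias for much lower variance. The bias is
visible under the null: the short block window leaks low-frequency (1/f)
power upward, so beta/gamma RSP values sit slightly above zero even with
no effect present. Comparisons against a zero-effect reference (or
between conditions sharing the estimator pair) cancel this bias;
absolute RSP values in the higher bands should be read with it in mind. The 12–13 Hz
gap between alpha and beta follows the band table verbatim. Regional
aggregates average channels first, then blocks; the contralateral
sensorimotor set defaults to {FC5, FC3, FC1, C5, C3, C1, CP5, CP3, CP1}
(or its mirror), overridable like the montage.

**ERSP.** Morlet wavelet power (frequencies in 1-Hz steps, cycles
`max(3, f/2)`), z-normalized per frequency by the mean and SD over the
epoch's own baseline time bins. Normalizing within the epoch (rather than
across trials) matches a per-episode pipeline in which the baseline
statistics are indexed by frequency only. Edge-contaminated bins — wavelet
support (3 temporal SDs) crossing the epoch boundary — are excluded from
the baseline statistics and flagged invalid. The significance mask pools
the z-scored baseline bins of all contributing blocks per frequency, draws
2000 surrogate block-sized means, computes two-sided empirical p values
`(b+1)/(n_perm+1)` per bin, and applies Benjamini–Hochberg FDR at 0.05.
This pooled-baseline resampling is a declared stand-in for toolbox
baseline-permutation routines whose exact scheme is not published; count
and correction match common practice.

**ERD/ERS.** The per-channel topography value is the plain mean of ERSP
over a band × latency-window rectangle (`K` bins). The latency window
defaults to the full 10-s block; a `stat = "peak"` variant (signed
extremum) is provided because figure conventions in this literature
sometimes report peak values instead of window means.

## Statistics

The cluster-based permutation test forms per-bin t statistics (paired or
independent), thresholds them at the two-sided critical t for
`cluster_alpha = 0.05`, clusters same-sign supra-threshold bins
(consecutive bins over time, the montage neighbor graph over channels,
4-connectivity over time–frequency grids), and refers each cluster's mass
(sum of t) to the permutation distribution of the maximum absolute
cluster mass. p values use `(b+1)/(n_perm+1)`; for paired designs with
`2^n ≤ n_perm` all sign assignments are enumerated and p is exact. The
cluster-forming threshold and mass statistic are the conventional toolbox
defaults, exposed as arguments.

Spatial adjacency derives from the montage's 2-D coordinates with a
deterministic distance rule: neighbors are channels within 1.5× the median
nearest-neighbour distance. A triangulation-based adjacency was
considered; the distance rule was chosen because it needs no
computational-geometry dependency, behaves identically on subset montages,
and satisfies the same symmetry/no-self-loop invariants (asserted at build
time).

The parametric battery operates on reading units (block means per
subject × scheme cell): a two-way mixed ANOVA (between: group; within:
scheme), a one-way repeated-measures ANOVA across schemes with
Greenhouse–Geisser correction when ε < 0.75 and Bonferroni-adjusted
pairwise paired t-tests, paired t-tests of FVS vs NMES within subjects,
and independent t-tests between groups. Effect sizes are partial η² for
ANOVA terms and Cohen's d for t-tests. The nonparametric battery provides
Mann–Whitney U and Wilcoxon signed-rank tests (exact p where the sample
permits) with rank-biserial effect sizes; all-tied input returns p = 1
with a warning rather than an error.

`normality_check()` routes features between the batteries using the
Lilliefors-corrected Kolmogorov–Smirnov test for n ≥ 5 (Shapiro–Wilk for
n = 4); a constant sample is declared non-normal with p = 0 and a warning.

## Numerical choices and degenerate inputs

* Monte-Carlo p values can never be 0 (`(b+1)/(n_perm+1)`), exact
  enumeration can never be below `2/2^n`.
* Permutation RNG is seedable everywhere; the pipeline derives all seeds
  from one master seed by counter-based mixing (`mix_seed()`), so trials
  are order-independent and reruns are bit-identical.
* Half-open interval conventions throughout: epoch spans, band edges,
  period of interest.
* Zero baseline variance at a frequency, empty aggregation regions, empty
  ERD/ERS windows, unpaired lateral channels, and too-short PSD segments
  are all hard errors naming the offending element.
* EDF+ output quantizes to 16 bits over per-channel physical ranges
  (round-trip error ≤ one step); BrainVision defaults to IEEE float 32
  (round-trip exact to single precision).

## Problem sizes used in tests and the acceptance script

The study conditions (effect defaults, 6 blocks, 10-s blocks, 5-s
baselines) are never scaled, but the montage, sampling rate, subject
count, and permutation count are reduced where a check does not need
them: most simulation-backed tests run 3–10 subjects on a 5–21-channel
montage at 250 Hz, null-calibration runs use 200 simulations with 500
permutations, and the topographic recovery uses the 28 fronto-central/
central/centro-parietal channels at 250 Hz with 10 subjects per group.
One segmentation check runs a full-scale trial (62 channels, 1000 Hz,
4 min) to exercise acquisition-scale bookkeeping. These sizes are stated
here as the package's own reproducibility choices.

## Known limitations

* The generator's independence across channels understates the spatial
  correlation of real EEG; topographic cluster tests on synthetic data are
  therefore somewhat conservative spatially.
* The ERSP mask pools baseline bins as if exchangeable within frequency;
  wavelet smoothing induces serial correlation the surrogate ignores, so
  the mask is conservative for few blocks (empty per-subject masks with
  only 6 blocks are expected; group-level masks pool subjects × blocks).
* The exact operator decisions of visual artifact screening and the
  authors' toolbox-internal permutation scheme are not reconstructable;
  both are replaced by declared deterministic procedures.
* No source-space analysis, inter-trial phase coherence, re-referencing,
  or bad-channel interpolation.
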