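---
title: "Alpha-band gating indexes and robust neural-behavioral correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alpha-band gating indexes and robust neural-behavioral correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(alphagate)
library(dplyr)
```

## The model

Alpha-band (8–12 Hz) oscillations are widely read as a gating signal:
regions showing high alpha power are functionally inhibited, and regions
released from alpha are available for processing. Under this
gating-by-inhibition view, efficient motor production around a key-press
response shows a characteristic topography — an alpha *surge* over
bilateral temporal sites just before and around response onset (inhibition
of non-motor interference) together with alpha *suppression* over
central-frontal motor sites after onset (release of motor cortex). In a
stroke-rehabilitation setting, individual differences in how strongly this
pattern changes over a course of therapy may track recovery of activities
of daily living (ADL) better than behavioral measures alone.

The package reduces response-locked EEG to three indexes per
subject-session:

* **temporal alpha** — mean median-scaled dB alpha power over
  T7, F7, CP5, T8, F8, CP6 in a pre-onset window (default −65–0 ms);
* **central-frontal alpha** — the same quantity over
  F3, Fz, F4, C3, CP1, C4, CP2 in a post-onset window (default 0–127 ms);
* **alpha ratio** — temporal divided by central-frontal alpha; higher
  values are read as better psychomotor efficiency.

Post-minus-pre change scores of these indexes are then correlated with
change scores of five clinical measures (SIS-ADL, FIM, NEADL, WMFT-Time,
WMFT-Strength) within each intervention group (PMC, M1, Sham), using a
*skipped* correlation, and the group-level screen is a 3 × 2 mixed ANOVA.

## Pipeline stages and their assumptions

`run_pipeline()` executes a fixed stage order:

1. **Band-pass filter** (0.5–40 Hz). Zero-phase by construction: a real,
   non-negative frequency response with raised-cosine transitions is
   applied to the FFT of the reflection-padded recording. This is exactly
   equivalent to convolution with a long linear-phase FIR filter applied
   forward-backward, protects response-locked latencies, and meets the
   stated contracts (mid-band gain within 1%, ≥ 20 dB attenuation at half
   the low edge and twice the high edge).
2. **Line-noise removal** by sliding-window sinusoid regression at the
   line frequency (4 s Hann windows, 50% overlap-add). Unlike a fixed
   notch, only the line component is estimated and subtracted, so spectral
   neighbours are essentially untouched.
3. **Epoch extraction**: only events whose response hand is *contralateral
   to the lesioned hemisphere* are epoched (−1.0 to +1.0 s, half-open
   sampling convention with a sample at exactly t = 0). The convention
   lives in one named constant, `contralesional_hand()`, and is flippable
   there alone.
4. **Linked-mastoid re-referencing** (TP9/TP10 by default, the mastoid
   labels of a 32-channel actiCAP layout).
5. **Ocular-artifact removal** through a pluggable linear unmixing.
   The default backend rotates the scalp channels into principal
   components — blinks are high-variance, spatially stereotyped, and load
   onto few components — and removes every component whose time course
   correlates with any EOG channel at |r| > 0.7. Any decomposition
   returning sources and mixing topographies can be injected; on backend
   failure the stage falls back to regressing the EOG channels out of each
   scalp channel, with a logged warning.
6. **Artifact gate**: epochs with peak-to-peak amplitude above 150 µV on
   any scalp channel are flagged, and a subject-session enters the power
   analysis only with at least 50 artifact-free epochs. The amplitude
   criterion is our own addition (the qualification rule itself says
   nothing about how epochs are flagged); both numbers are configuration.

## Time–frequency choices

Alpha power is computed by frequency-domain Morlet convolution on epochs
zero-padded to 4× their length, at 8, 9, …, 12 Hz. The complex amplitudes
are doubled (one-sided spectrum convention), squared into power, averaged
over epochs, converted to dB against the participant-session median of
each channel × frequency (`10·log10(power/median)`, no pre-stimulus
baseline), and finally averaged across the closed 8–12 Hz band.

Two numerical choices deserve comment:

* **Constant spectral bandwidth.** The wavelets share one Gaussian
  spectral width, band-centre/cycles = 2 Hz for the default 5 cycles at
  10 Hz, rather than scaling bandwidth with frequency. With
  frequency-proportional bandwidth, white noise would show a power slope
  of 12/8 across the band for purely methodological reasons; with a
  common bandwidth the noise response is flat and a sinusoid at any
  analysis frequency still recovers its amplitude exactly. Cycle counts
  are configuration, not a data-derived fact.
* **Edge invalidation.** Samples within three wavelet temporal SDs
  (~0.24 s) of either epoch edge are marked invalid and excluded from all
  windows; the analysis windows near onset are far inside the valid
  region.

Median scaling makes the dB map invariant to any overall gain applied to
the raw signal; the `scale-invariance` test asserts this exactly. Because
the median is taken per channel × frequency over the whole epoch, window
values are interpretable as dB relative to that channel's typical alpha
level.

The analysis windows default to the fixed constants −65–0 ms (temporal)
and 0–127 ms (central-frontal). They can instead be derived at run time
(`windows = "derive"`) from a paired pre-vs-post cluster permutation test
on each region's channel-average power; when no cluster survives, the
fixed defaults are used. The windows are honoured as configurable
constants rather than reproducible outputs, since deriving them requires
the original cohort.

## Cluster-based permutation testing

`cluster_permutation_test()` forms pointwise paired (or two-sample) t
statistics, groups adjacent same-signed samples exceeding the two-sided
p = 0.05 critical t into clusters, and compares each cluster's summed t
against the permutation null of the *maximum* absolute cluster mass
(sign-flips for paired designs, label shuffles otherwise; default 1000
permutations, +1/(n+1) correction so p is never exactly zero). The
family-wise error of this construction is checked by simulation in the
test suite, and an exhaustive sign-flip enumeration at n = 8 serves as an
independent oracle for the Monte-Carlo p.

## Skipped correlation

For each (group × index × outcome) cell, `skipped_correlation()`:

1. estimates the bivariate location and scatter by the **minimum
   covariance determinant** with maximal-breakdown subset size
   h = ⌊(n+3)/2⌋ — *exhaustively* for n ≤ 15 (C(12, 7) = 792 subsets, so
   exactness is affordable at the design's n = 12), by concentration
   steps from many random starts beyond;
2. flags outliers by the **box-plot rule** on robust distances
   (ideal-fourths quartiles, whisker k = 1.5; the rule is applied to the
   empirical distance distribution, so any consistency scaling of the MCD
   scatter cancels); collinear scatters fall back to univariate box-plot
   screening;
3. computes Pearson's r on the retained pairs with
   t = r·√(n−2)/√(1−r²);
4. builds a **percentile bootstrap** 95% interval (2.5/97.5 percentiles)
   by resampling retained pairs with the outlier flags frozen, and calls
   the cell significant exactly when 0 lies outside the interval.

`correlation_battery()` runs the 3 × 3 × 5 = 45 cells with per-cell
derived seeds and no multiplicity correction (an optional
Benjamini–Hochberg column can be switched on). Cells with fewer than 5
subjects or zero variance are marked not estimable rather than failing.

A calibration caveat the package surfaces deliberately: at n = 12 the
plain percentile bootstrap for Pearson's r is anti-conservative, and
conditioning on box-plot outlier removal adds to that, so the null
rejection rate of the CI rule sits above the nominal 5% (the acceptance
script computes the empirical rate; the test suite asserts the nominal
band and documents the excess as a property of the printed decision rule,
not of the implementation). Users drawing inference at this sample size
should read "CI excludes 0" as evidence grading, not as a calibrated
5%-level test.

## Group-level screen

`check_assumptions()` runs the Kolmogorov–Smirnov test against a normal
with estimated parameters (the commonly run form; a Lilliefors-corrected
variant is available) and Levene's test centred at the mean, routing to
Kruskal–Wallis / Friedman when normality fails. `mixed_anova()` is the
classical sums-of-squares decomposition for one between-subject factor
(3 groups) crossed with one within-subject factor (pre/post):
subjects-within-groups is the error for Group, time-by-subjects for Time
and the interaction; with 12 subjects per group every denominator df is
33. With two within-levels sphericity cannot be violated, so no
correction is applied. `bonferroni_posthoc()` multiplies paired-t p
values by the number of comparisons, capped at 1.

## What the synthetic cohort emulates — and what it does not

`simulate_cohort()` generates, per subject: a latent temporal-alpha
change drawn around a group mean; five clinical change scores drawn from
a bivariate model with the configured correlation against that latent
change (default: 0.6 for PMC → SIS-ADL, 0 elsewhere); pre scores anchored
to published group-level means/SDs of the five instruments and clipped to
instrument ranges (SIS-ADL 0–100, FIM 18–126, NEADL 0–66, timed test
non-negative, strength 0–5; change-score SD set to half the pre SD, a
typical test-retest spread); optional bivariate outliers displaced five
robust SDs along the minor axis of the planted distribution; and,
optionally, continuous 32-channel/500 Hz EEG whose temporal surge gain
realizes the subject's planted index change
(`post gain = pre gain · 10^(Δ/20)`).

The EEG forward model is 1/f background (exponent 1, RMS 10 µV) plus
amplitude-modulated alpha-band noise (RMS 9 µV) per channel — amplitudes
chosen so that a 150 µV peak-to-peak gate rejects blink-contaminated but
not ordinary epochs — with the surge and suppression gains applied inside
their windows, stereotyped frontal-dominant blinks at a configurable
per-trial rate, and a fraction of ipsilateral-hand events for the
selection stage to reject. It deliberately omits volume conduction,
channel correlations, non-stationary background, bad channels and real
ocular dynamics; passing tests therefore demonstrate the *analysis
machinery* (selectivity, calibration, recovery of planted effects), not
performance on real recordings.

Problem sizes in the test suite are scaled to what the properties need:
structural tests run 5 subjects × 6 epochs at 250 Hz, calibration uses
200–500 table-level replicates, and gain-recovery uses a widened surge
window (±300 ms, measured over ±150 ms against a −680 to −540 ms
baseline) so that the wavelet's ~70 ms power-smoothing kernel does not
leak the surge into its own baseline.

## Degenerate inputs and tie-breaks

* dB values near zero make the alpha ratio unstable; denominators with
  magnitude below 0.1 dB are floored with a warning instead of failing
  (whether a ratio of dB values or raw powers was intended is not
  decidable from the published description; dB is the default because the
  composite is defined from the two dB measures).
* Zero-variance timepoints in the cluster test get t = 0 with a warning;
  zero-variance correlation inputs are refused as not estimable.
* Perfect correlation among retained pairs reports r with an infinite,
  flagged t.
* All-tied samples give a Kruskal–Wallis statistic of 0 and p = 1 rather
  than a 0/0 tie correction.
* Bit-identical reproducibility under a fixed seed is a tested contract
  of every stochastic stage (simulation, permutation, bootstrap).

## Known limitations

* The published analysis windows and group-level F statistics cannot be
  reproduced without the original cohort (available only on request);
  they are honoured as configurable constants and design-cardinality
  checks instead.
* The bootstrap CI calibration issue at n = 12 described above.
* With one planted ρ = 0.6 cell among eight null SIS-ADL competitor
  cells at n = 12, order statistics cap the probability that the planted
  cell tops |r| near 55–65%; the acceptance script reports the measured
  rate.
* The PCA ocular backend assumes blinks dominate variance; recordings
  where that fails should inject a stronger decomposition through the
  `backend` argument.
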