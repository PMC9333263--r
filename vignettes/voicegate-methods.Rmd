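---
title: "voicegate: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{voicegate: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## What the package computes

`voicegate` analyses intracerebral (sEEG) recordings of human auditory
cortex during presentation of vocal and nonvocal sounds. The scientific
question it serves is whether, and where, cortical responses encode the
*category* "voice" beyond what the acoustics of vocal sounds explain. The
pipeline has five stages:

1. **Preprocessing** — raw multichannel voltage at 1 kHz is re-referenced
   to the common average (CAR), epoched around stimulus onsets, z-scored
   against the pooled prestimulus period, and transformed into broadband
   high-gamma activity (HGA, 70–150 Hz): eight zero-phase Butterworth
   bandpass filters with log-spaced centers (70–150 Hz) and bandwidths
   (16–64 Hz), Hilbert analytic amplitude per band, per-band baseline
   z-scoring, band averaging, downsampling to 100 Hz, and clipping to
   900 ms around the stimulus.
2. **Channel selection** — a two-sample t-test of mean HGA in the
   post-onset window [0, 500) ms against the silent baseline
   [−600, −100) ms, Benjamini–Hochberg FDR-corrected across channels at
   0.05.
3. **Single-channel statistics** — vocal/nonvocal (V–NV) *separability* is
   the sum of significant (p < 0.001) cluster masses of the time-resolved
   two-sample t-statistic under a cluster-based permutation test;
   *category preference strength* is the HGA ratio
   r = (V − NV)/(V + NV) of window-mean responses, with negative means
   clipped to zero, computed in the onset [0, 500) and sustained
   [500, 2000) ms windows.
4. **Decoding** — L1-regularized logistic regression on channel × window
   mean-HGA features, full-window and sliding-window variants, nested
   cross-validation (5 outer folds, 10 inner folds over a 20-value
   regularization path), inverse-prevalence observation weights, balanced
   accuracy, and permutation significance (cluster-corrected for sliding
   models).
5. **Encoding** — per channel, linear models of window-mean HGA from
   standardized acoustic features reduced by PCA to the components holding
   99.99% of variance, with a binary vocal-category regressor; model fit is
   leave-one-out cross-validated R², the category contribution is the
   likelihood-ratio statistic χ² = n·ln(RSS_nested/RSS_full) against the
   acoustic-only nested model, χ²(1) under the null.

A synthetic-data generator produces voltage recordings, trial schedules and
acoustic feature tables with known ground truth, so every stage is testable
without any patient data.

## Conventions

All sample indices are 0-based and all analysis windows are half-open
`[start, end)` in milliseconds relative to stimulus onset; one rule is
applied everywhere. Epochs span [−1000, offset + 1450) ms for VL (550-ms
stimuli) and [−1000, offset + 1000) ms for NatS (2000-ms stimuli). The
100-Hz HGA series labels each 10-ms bin by its start and keeps bins
starting in [−900, offset + 900] *inclusive* of the last bin: the
printed sliding-window grids (centers −50…1500 ms for VL, −50…2450 ms for
NatS) require that final bin, since the last VL window [1450, 1550) would
otherwise be empty.

## Tunable parameters

All tunables live in `voice_config()` with their defaults: epoch bounds,
the baseline window (−600 to −100 ms), filter-bank shape (8 bands, order 6,
70–150 Hz centers, 16–64 Hz bandwidths), the 100-Hz output rate, the
onset/sustained windows, the 100-ms/50-ms sliding-window grid, permutation
counts (1,000 for decoding, 10,000 for single-channel and encoding tests),
the per-window cluster threshold percentile (0.05), the cluster
significance level entering separability (0.001), the FDR level (0.05),
the PCA variance target (0.9999), and the nested-CV geometry (5 outer and
10 inner folds, 20 log-spaced regularization values spanning three decades
below the analytic λ_max of the weighted problem).

Interpretation choices a user should know about:

* "Sixth order" Butterworth is the order of the *bandpass* design
  (`signal::butter(3, ..., type = "pass")`), applied forward-and-reverse,
  so effectively 12th order at zero phase.
* Downsampling to 100 Hz is the mean over consecutive non-overlapping
  10-sample bins: the analytic amplitude is nonnegative and slowly varying,
  and bin-averaging avoids ringing.
* Band z-normalization statistics are pooled over trials *per channel*
  (`band_norm_pool_channels = FALSE`); pooling across channels is available
  but not the default.
* Single-channel t-statistics use the pooled-variance (Student) form at the
  native 100-Hz resolution, clustered two-sided with positive and negative
  exceedances forming separate clusters and critical values at
  α/2 per tail. Decoding-accuracy clustering is one-sided (upper 95th
  percentile). Cluster mass is the sum of the statistic values in the run,
  not the exceedances.
* The HGA ratio defines 0/0 as 0 (a silent channel has no preference), and
  clips negative window means to zero first, which bounds it in [−1, 1].
* Separability onset of a channel is the start of its earliest significant
  cluster; the ROI-level estimate is the median over the top 50% of
  channels by separability (`ceiling(n/2)`, ties broken by channel id),
  because weakly separable channels cross the threshold late.
* Cross-task decoding restricts features to windows fully contained in the
  first 550 ms (centers ≤ 500 ms) and applies training-set z-scoring
  statistics to the test task.
* The LRT uses the Gaussian likelihood with the variance profiled out,
  giving χ² = n·ln(RSS_nested/RSS_full) with 1 degree of freedom for the
  single added indicator. LOOCV residuals use the closed-form leverage
  identity e_i/(1 − h_ii).
* Balanced accuracy is pooled over outer folds (aggregate confusion
  counts), not averaged per fold.
* The stimulus-metadata rules are explicit operations: voice-localizer
  class balancing keeps the first `min(n_nonvocal, n_vocal)` nonvocal clips
  in canonical order, and the natural-sounds vocal→nonvocal
  reclassification takes an explicit id list (which crowd-generated or
  no-vocal-fold exemplars to move depends on the stimulus-set release, so
  the list is configurable rather than hard-coded).
* Acoustic-feature outlier exclusion is likewise an explicit id list, not
  an automatic rule.

## The synthetic generator

`synthesize_recording()` builds each channel as

* a 1/f background (spectrally shaped white noise) of designed SD;
* an optional shared common-mode 1/f component, which exercises the CAR;
* an optional line-frequency sinusoid;
* a high-gamma carrier: 70–150 Hz bandpass-filtered white noise whose
  amplitude envelope rises multiplicatively by the channel's designed gain
  during the onset and sustained windows of each trial,
  category-dependently, with 50-ms linear ramps (mirroring stimulus
  ramping practice) and a per-channel latency. Channels with acoustic
  weights shift their per-trial gain by the dot product with the stimulus's
  latent acoustic factors.

Trial schedules present every stimulus at least `n_presentations` times
with uniform 1–2 s inter-stimulus intervals and insert flagged immediate
(1-back) repeats at a target fraction of about 16% of trials. Acoustic
feature tables are low-rank latent-factor products (default 88 observed
columns, mirroring standard acoustic "functionals" summaries) whose latent
means differ between categories by a configurable shift, so category is
partially — not fully — recoverable from acoustics, as in natural sound
sets.

Designed gains translate linearly into baseline-z HGA, so the ground-truth
HGA ratio implied by a channel's gains follows the same clipped-ratio
formula as the estimator; rank order and near-exclusive preferences are
recoverable, which is what the recovery tests assert.

What the generator does **not** emulate: epileptiform artifacts,
biophysically detailed field potentials, channel-to-channel correlation
structure beyond the single common-mode component, non-stationary
background statistics, and any perceptual voice-likeness continuum.
Passing recovery tests therefore show that the estimators invert the
generative model they were designed for at realistic SNR — not that the
pipeline is robust to every pathology of clinical recordings.

A note on the CAR at small montage sizes: with only a handful of channels
the common average contains an appreciable share of the responsive
channels' high-gamma, which leaks (sign-inverted) into every channel and
biases category ratios toward zero; real montages have 100+ contacts.
Synthetic cohorts therefore include a majority of nonresponsive channels
(16 channels, half nonresponsive, in the bundled recovery suite), which
keeps the leak at realistic levels.

## Numerical and degenerate-input choices

* Constant (zero-variance) channels and constant feature columns are hard
  errors, not silent drops.
* Probability-0.5 decoder outputs classify as vocal (`>= 0.5`); with the
  regularization at its maximum all coefficients are zero and balanced
  accuracy is exactly 0.5 under inverse-prevalence weights.
* Cluster p-values are the fraction of permutation maximum-cluster-masses
  reaching the observed mass; permutations with no suprathreshold window
  contribute mass 0. With identical seeds, identical p-values are
  reproduced bit-for-bit.
* Full-model permutation and R² permutation p-values use the
  add-one estimator (1 + #{null ≥ obs})/(1 + n_perm), so they can never be
  exactly zero.
* The profile-likelihood LRT is slightly anticonservative when the design
  dimension is non-negligible relative to the stimulus count (measured
  ≈0.08 empirical size at nominal 0.05 with k ≈ 9 components and n = 150);
  its χ²(1) reference is asymptotic. The calibration suite runs in a
  regime (n = 440, k = 8) where the asymptotic size holds; users fitting
  many components to few stimuli should expect the same inflation the
  underlying statistic always has.

## Problem sizes in the bundled suites

The test and acceptance suites run everything at desk scale, chosen as the
package's own trade-off between fidelity and turnaround: synthetic cohorts
of 16 channels, 48 stimuli and 2 presentations (~112 trials); separability
with 500 permutations; encoding significance with 1,000 permutations;
cluster-test calibration over 200 null simulations of 200 permutations
each; LRT calibration over 500 null fits; and sliding-window decoding on a
reduced grid (centers −50…700 ms) with 200 permutations, an 8-value
regularization path and 5 inner folds. The statistical machinery is
identical at full scale; only counts change.

## Known limitations

* No notch filtering (the targeted amplifiers apply it in hardware) and no
  bipolar re-referencing; no anatomical localization — ROI labels are
  consumed as channel metadata.
* Acoustic features are consumed as tables; extraction from audio is out
  of scope (the synthetic generator stands in for the external extractor).
* Only the vocal/nonvocal contrast is implemented: no multiclass decoding,
  no spectrotemporal receptive fields, no time-resolved encoding beyond
  the onset/sustained window means.
* The cluster engine is temporal only; it does not pool across channels
  (no spatiotemporal clustering, no TFCE).
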