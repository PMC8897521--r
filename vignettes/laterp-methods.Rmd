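---
title: "Lateralized ERP analysis: models, measures and design choices"
author: "laterp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lateralized ERP analysis: models, measures and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laterp)
```

## The scientific setting

The package implements the analysis of a visual-search paradigm in which
every trial has two phases.  A *pattern phase* shows two simultaneous
streams of nonsense symbols, one per screen side: one side carries a
structured stream built from three fixed triplets of symbols (the
*patterned* location, constant per participant), the other an unstructured
stream with back-to-back repeats forbidden.  A *search phase* then flashes
a two-item array; the participant reports whether the exact target object
is present.  Trials are Exemplar Match (target present), Foil (a
same-category non-target present) or Target Absent.  Each block mixes 28
Exemplar Match, 28 Foil and 4 Target Absent trials, with the item-present
types split 14/14 between left and right.

The neural quantity of interest is the N2pc: an enhanced negativity at
posterior electrodes (PO7/PO8) contralateral to an attended item, usually
200–300 ms after array onset.  If the irrelevant symbol patterns attract
covert attention, item selection should differ between the patterned and
random locations — in amplitude, in onset latency, or in the decodability
of the item's side from the scalp topography.

## The estimator

For a trial with the item on the left, the contralateral electrode is PO8
and the ipsilateral one PO7 (and vice versa); Target Absent trials carry
no reference object and are excluded.  Condition averages of the
contralateral and ipsilateral traces are subtracted into a difference wave
$D(t)$, averaged unweighted across participants into grand averages.  All
scalar measures operate on $D(t)$:

* **Mean amplitude**: arithmetic mean over the closed 200–300 ms window.
* **Signed negative area**: $A = -\int \min(D(t), 0)\,dt$ over 150–300 ms,
  reported as a non-negative magnitude in µV·ms (larger = more negative).
  The sampled wave is treated as piecewise linear and zero crossings are
  resolved analytically, so the value does not depend on where samples
  fall relative to a crossing.  The broad window captures components whose
  latency varies across participants.
* **Fractional-area latency**: the time at which the cumulative negative
  area reaches 50% of the window total, interpolating the cumulative
  curve linearly between samples.  When a wave has no negative area the
  measure is *undefined* — flagged, never silently zero — and that
  participant/condition is excluded from comparisons.
* **Onset latency**: the first crossing of a −0.75 µV threshold,
  interpolated linearly between the bracketing samples; undefined when the
  threshold is never reached.  Latency interpolation matters because the
  2 ms sampling step would otherwise quantize jackknife statistics.

### Jackknife latency inference

Onset latencies of single-participant waves are noisy, so onsets are
measured on leave-one-participant-out grand averages.  Per-participant
scores are retrieved with the standard back-transformation
$\hat\ell_i = n L_{\mathrm{all}} - (n-1) L_{(-i)}$, and test statistics
computed on the subsample values are divided by $n-1$ (t; $F$ by
$(n-1)^2$) to undo the variance shrinkage the jackknife induces.  If any
subsample wave of a condition fails to reach the threshold, that condition
is excluded from pairwise contrasts — mirroring how participants whose
data do not meet the threshold are dropped rather than imputed.

### Resampling inference

*Signed-area permutation test.*  Area magnitudes are positively biased
under noise, so each condition's observed grand-average area is compared
with a null built by shuffling the patterned/random labels across trials
*within participant and within trial type*, rebuilding condition averages,
difference waves, grand average and area per shuffle (500 by default).
Significance uses the 95th percentile of the null (nearest-rank) and the
add-one estimator $p = (b+1)/(N+1)$, which is never exactly zero and
matches the granularity of a permutation null.  Whether the original
study shuffled symbol-position labels only, or jointly with trial type,
is not fully specified; we shuffle within trial type (the reading
consistent with shuffling "separately" per trial type) and the stratum
argument exposes the alternative.

*Cluster-mass correction for decoding.*  Per time point a one-sample t
test compares participants' decoding accuracies to chance (one-tailed);
maximal runs of significant points form clusters scored by the sum of
their t values.  The observed masses are compared with a permutation null
of maximal cluster masses.  A source text internally conflates the
"top 95%" criterion with $p < 10^{-4}$; we implement the 95th-percentile
criterion and report exact add-one permutation p-values per cluster.  Two
null generators exist: re-running the decoder with permuted class labels
(exact, expensive), and a binomial Monte-Carlo surrogate that draws each
participant's chance accuracy as $\mathrm{Bin}(60, 0.5)/60$ — the exact
sampling distribution of an accuracy estimated from 60 attempts under the
null.  The surrogate is the desk-scale default and is validated against
nominal type-I error in the test suite.

*Bootstrapped standardized measurement error.*  Per participant and
condition, trials are resampled with replacement (same size), averaged,
and the measure recomputed; the bSME is the standard deviation of the
bootstrap values (10,000 iterations at full scale; 2,000 at desk scale).
Iterations in which a latency measure is undefined are dropped and
counted.  Group data quality is the root mean square of the
per-participant bSMEs, which for non-negative inputs lies between their
mean and their maximum.

### Decoding

A linear support vector machine (unit cost) is trained at each time point
to separate the scalp topographies of items in the patterned vs random
location, separately per trial type, excluding EOG and reference channels.
Trials are randomly split into three blocks per class and block-averaged
to raise signal-to-noise; each block serves once as the test set
(a full 3-fold rotation — the only reading consistent with the bookkeeping
of 2 classes × 3 cross-validations × 10 iterations = 60 attempts per time
point), and the block assignment is redrawn on each of the 10 iterations.
Classes are equated by random subsampling before blocking.  Features are
standardized per time point with training-block statistics only, so no
test information leaks into the fit; whether the original analysis
standardized is unstated, and the choice is confined to one helper.

## The synthetic-experiment generator

Because no recordings are distributed with the design, the generator is a
first-class module: it reproduces the trial structure exactly (block
composition, side splits, per-trial pattern-phase length of 1–3 triplets
of 400 ms symbols, 1600 ms response deadline) and injects a known
component so that every downstream estimate has a recoverable target.

Choices a real dataset would fix, and what we chose:

* **Component waveform**: a raised-cosine pulse
  $\frac{a}{2}(1 - \cos 2\pi (t - t_0)/w)$ — smooth, compactly supported,
  and analytically integrable, so closed-form oracles exist for every
  measure.  Defaults $a = -2$ µV, $t_0 = 180$ ms, $w = 120$ ms place a
  realistic N2pc-sized deflection inside the 150–300 ms analysis window;
  the 120 ms width is a typical N2pc duration.
* **Noise**: an equal-power sum of white and 1/f-shaped Gaussian noise,
  independent per channel and trial, sd 10 µV by default — single-trial
  EEG-like spectra while staying seedable and fast.  Spatial correlation
  across channels and trial-to-trial amplitude structure of real EEG are
  *not* modeled, so passing tests demonstrate correctness of the
  estimators under the stated noise model, not robustness to every
  property of real recordings.
* **Artifacts**: with a configurable per-trial probability, a ±40 µV
  square HEOG excursion at 100–250 ms — beyond the ±25 µV criterion —
  is injected and flagged, so rejection can be validated exactly
  (with zero noise the rejected set equals the injected set).
* **Triplet order** within a patterned phase is drawn uniformly with
  replacement: the triplets are consistent units, but their order forms
  no super-pattern.  The random stream draws from the nine symbols not
  used in triplets (disjoint alphabets).  Foil identities are sampled
  with replacement per trial; without-replacement sampling within block
  is exposed as an option since the original procedure does not say.
* **Behavior**: log-normal reaction times per trial type (defaults 616 ms
  Exemplar Match, 660 ms Foil — echoing the faster-target pattern — with
  near-ceiling accuracy); samples beyond the 1600 ms deadline become
  omissions.  Target Absent trials are generated solely so their
  exclusion paths are exercised.

## Preprocessing conventions

The chain is re-reference (averaged earlobes) → zero-phase filtering →
baseline correction (−100–0 ms) → artifact rejection → trial selection.
"Exceeding ± X µV" is read as absolute instantaneous amplitude $|v| > X$
anywhere in the criterion's closed window — the common ERP-toolbox
convention — with peak-to-peak alternatives out of scope.  The filter
roll-offs (48 and 12 dB/octave) map to Butterworth orders 8 and 2 per
pass; filters are applied forward–backward (`signal::filtfilt`), so a
symmetric pulse keeps its extremum sample.  The notch half-width defaults
to 2.5 Hz.  Filtering operates on epochs; with a −100–500 ms epoch the
0.1 Hz high-pass acts essentially as an offset remover, and the test suite
verifies passband fidelity (5 Hz within 1%) and notch attenuation
(≥ 20× at 60 Hz) on synthetic tones.

## Numerical and degenerate-input policy

Undefined measures (no negative area; threshold never reached) are flagged
results carrying `NA`, never zeros, and propagate into exclusions exactly
where a real analysis would exclude participants.  Zero-variance
situations are reported as such: identical subsample latencies give an
undefined corrected t; decoding accuracies all at chance give $t = 0$,
all above chance at zero variance are flagged rather than scored
infinite.  All resampling is bit-reproducible under a fixed seed and
participant order, with child seeds derived deterministically from one
master seed.

## Problem sizes used in validation

The test suite validates at sizes chosen to exercise the full design while
remaining desk-scale: chance-level decoding calibration uses 98 trials per
class, 30 channels and 76 time points over 20 seeds; permutation type-I
calibration uses 200 simulated datasets at 200 permutations; cluster
type-I calibration uses 200 datasets at 500 permutations with the binomial
surrogate; parameter recovery uses 19 participants × 98 trials/condition
at −2 µV injected amplitude in 10 µV noise, matching the generator
defaults.  Full-scale constants (10,000 cluster permutations and
bootstrap iterations) remain one argument away in `analysis_config()`.

## Known limitations

* The generator's noise model omits spatial channel correlations,
  non-stationarity within a session, and real ocular artifact morphology.
* Only the PO7/PO8 electrode pair enters the lateralized measures; no
  topographic mapping or source analysis is provided.
* The decoder is a binary linear SVM; multiclass decoding and temporal
  generalization are out of scope.
* Group-level parametric statistics (t, within-subject ANOVA, effect
  sizes) are standard reporting utilities, not the package's contribution.
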