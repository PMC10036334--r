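---
title: "Detecting multi-day rhythms in touchscreen dynamics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting multi-day rhythms in touchscreen dynamics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multidien)
```

## The problem and the pipeline

Smartphone touchscreen interactions form a dense behavioral time series:
every tap or swipe has a millisecond timestamp, and screen on/off events
delimit usage sessions. Multi-day ("multidien") rhythms — periodicities
slower than circadian, on the order of a week to two months — are of
interest in chronobiology and in clinical monitoring (epilepsy, mood
disorders), but any single summary statistic (daily counts, mean speed)
can miss a rhythm that lives in only part of the behavioral repertoire.

`multidien` therefore resolves behavior before asking about rhythms.
Within each session, consecutive inter-touch intervals (ITIs) are paired:
interval *k* against interval *k*+1, both log10-transformed. The joint
density of these pairs — the joint-interval distribution (JID) — separates
fast repetitive input from slow deliberate interaction and the transitions
between them. Estimated hour by hour, it yields a 50 × 50 × D tensor of
hourly behavioral densities, and every one of the 2500 two-dimensional
bins carries its own hourly time series.

The stages, each exposed as ordinary functions on S4 containers:

1. **JID** (`buildJID`): Gaussian-kernel density of log10 ITI pairs,
   bandwidth 0.1, on a 50-step grid per axis over [10^1.5, 10^5] ms.
2. **Spectral** (`jidPeriodograms`): per-bin continuous-wavelet
   periodogram. For each period the power is P = sqrt(mean |S|), the
   temporal mean of the wavelet coefficient modulus outside the cone of
   influence, on a geometric period grid (default 40 voices/octave, 2
   hours to 80 days; 396 periods).
3. **Null statistics** (`bootstrapPeriodograms`, `aperiodicAdjust`,
   `clusterCorrect`): 24-hour block bootstrap of the hourly tensor; the
   ensemble mean is the aperiodic component, subtracted to give the
   "power index"; pointwise two-tailed α = 0.05 against ensemble
   quantiles; family-wise correction by cluster mass on the (bin-row,
   bin-column, period) lattice against the per-bootstrap maximum cluster
   size (97.5th percentile), keeping only clusters of ≥ 5 bins.
4. **Factorization** (`sliceReshape`, `selectRank`, `starNNMF`): the
   adjusted tensor, sliced to a multiday band and shifted non-negative,
   is a T′ × 2500 matrix decomposed as W H. Columns of W are
   *meta-rhythms* (periodogram shapes), rows of H the matching
   *meta-behaviors* (loadings over the JID). Rank is chosen by masked
   cross-validation; stability by many random restarts scored on median
   pairwise component correlation.
5. **Population** (`clusterMetaRhythms`, `prevalenceTable`): pooled
   meta-rhythms are z-scored, mapped to Daubechies-4 wavelet
   coefficients, k-means clustered with silhouette-selected k; each
   family gets a peak period, a 95th-percentile period range, and
   prevalence counts (optionally "confirmed" against each subject's
   significant clusters).
6. **Coherence** (`cohortCoherence`): for a rhythm band, each subject
   contributes the hourly density of a reference bin (maximum power index
   inside the largest band-overlapping significant cluster); pairwise
   wavelet magnitude-squared coherence is averaged over the band and
   tested one-tailed against a block-bootstrap null.

## The synthetic generator: what it emulates, and what it does not

Real raw event streams of this kind are rarely shareable, so the package
carries a generator (`generateSubject`, `generateCohort`) whose defaults
define the study conditions used throughout the tests:

- **Sessions**: screen-on sessions start as an inhomogeneous Poisson
  process with a circadian rate profile (near-zero at night, ~3/h during
  the day, ~40 sessions/day). Touch counts per session are geometric with
  mean 20; a screen-off follows 1 s after the last touch.
- **Intervals**: ITIs are a two-component log-normal mixture in log10 ms —
  fast component N(2.5, 0.35) (~300 ms), slow N(4.3, 0.36) (~20 s),
  baseline fast weight w0 = 0.6. With these values about 1% of intervals
  exceed 10^5 ms, matching the convention that the JID's upper bound is
  the empirical 99th percentile. The mixture reproduces the fast/slow
  structure of real JIDs inside the estimation window; it does *not*
  model full power-law tails, which the truncated window never sees.
- **Rhythms**: a multi-day rhythm is injected by sinusoidal modulation of
  the fast-component weight, w(t) = w0 + a sin(2πt/period + φ) — i.e. a
  periodic shift of probability mass across the JID, which is where the
  real phenomenon lives — or, optionally, of the session rate. Validity
  checking rejects amplitudes that push w(t) out of [0, 1].
- **Gaps**: recording gaps are honest missing data (no events of any
  kind), exercising the zero-density path of the JID stage.

What passing tests on this generator shows: parameter recovery — that an
injected period, amplitude and phase structure survives the full pipeline
and comes out where it was put, and that nothing comes out when nothing
was put in. What it cannot show: robustness to device-specific
missingness, app-driven regime changes, non-sinusoidal rhythm shapes, or
power-law interval tails; conclusions about real cohorts still require
real data.

## Numerical and design choices

Choices the method description leaves open were resolved once, as
follows.

**Pair-to-hour assignment.** A pair (ITI_k, ITI_{k+1}) belongs to the
hour containing the onset of interval *k*, so each pair lands in exactly
one hour.

**Hours without pairs** carry an all-zero density, flagged invalid, and
the zeros are fed to the wavelet stage. This keeps the hourly sampling
grid regular — a requirement of the transform — at the cost of treating
silence as zero activity; it is a documented bias source for subjects
with very sparse nights.

**KDE normalization.** The kernel estimate is normalized as a probability
density *before* grid evaluation; mass leaking past the truncation window
is not renormalized. Valid hours whose pairs are interior integrate to
~1 on the grid (midpoint quadrature overshoots by up to ~1%); hours whose
few pairs sit near the bound legitimately integrate to less. Duplicate
timestamps (zero intervals) are dropped and counted, not clamped.

**Wavelet.** Analytic Morlet with center frequency ω0 = 6 (the common
default; the Fourier factor is 1.033, so scale ≈ period). Implemented in
the frequency domain with zero-padding to a fast FFT length after
demeaning (a zero-mean wavelet annihilates constants; demeaning also
avoids a spurious edge step from padding a nonzero offset). The cone of
influence is the e-folding time sqrt(2)·s; samples inside it are excluded
from the temporal mean, and periods whose cone covers the whole recording
return NaN and are excluded downstream. Power uses the modulus, not its
square: P = sqrt(mean |S|).

**Block bootstrap.** The periodogram null resamples day-aligned,
non-overlapping 24-h blocks with replacement (final block truncated).
Aligned blocks preserve time-of-day structure, so circadian power appears
in the null and cancels in the aperiodic adjustment, while multi-day
phase is destroyed — exactly the null wanted for multiday inference. The
*coherence* null instead uses moving (unaligned-start) 24-h blocks on one
member of each pair: aligned blocks would preserve diurnal phase and
could never break 1-day alignment, making the diurnal positive control
meaningless. Resampling one member suffices to destroy cross-subject
alignment.

**Cluster adjacency** is face (6-)connectivity on the 3-D (JID row, JID
column, period) lattice — the conservative neuroimaging default. The
"5 neighboring bins" rule is implemented as minimum cluster size 5 under
that adjacency, applied identically to real and bootstrap masks before
the maximum-size null is tallied.

**NNMF.** Weighted multiplicative updates minimizing the Frobenius error
with zero weight on held-out entries implement masked fitting.
Cross-validation fits start from a deterministic non-negative double-SVD
(NNDSVD) initialization: random starts frequently stall in local minima
at exactly the planted rank, which inverts the CV curve; NNDSVD makes
each rank's fit close to its best achievable error so the curve's
minimum is meaningful. The same 10% holdout is reused across candidate
ranks within a repetition (paired comparison). Ties break toward the
smallest rank. The stability procedure uses random initializations by
design; pairwise similarity of two decompositions is the mean of
greedily matched component correlations (zero-variance components
correlate as 0) — symmetric and permutation-invariant, penalizing lost
components; a max-only variant is available
(`decompositionSimilarity(..., method = "max")`). The scale gauge is
fixed by normalizing each meta-rhythm to unit maximum, compensating in H,
and ordering components by peak period.

**Period slices** follow two duration profiles: subjects with ≥ 90 days
are factorized on 2.2–27.7 days; subjects with ≥ 180 days on 2.2–70.5
days. T′ is derived from the actual period grid and cone-of-influence
survival, not fixed constants. With 180-day recordings the longest slice
periods can have empty cones and are dropped from the slice.

**Meta-rhythm clustering** uses all Daubechies-4 (8-tap) coefficients of
a full-depth periodized pyramid decomposition, after reflecting each
z-scored curve to the next power-of-two length; the decomposition depth
is not specified by the method description, so full depth is used.
k-means (20 restarts) runs on the coefficients for k = 2..12 and the
mean silhouette picks k. Constant curves are excluded with a warning.
A family whose over-threshold range abuts the period axis edge is
flagged `incomplete` and should not be interpreted as a peak.

**Coherence smoothing**: boxcar in time over ~one period per scale and a
boxcar across ~0.6 octave of adjacent scales (both knobs). Smoothing is
what makes magnitude-squared coherence take values below 1; identical
smoothing in numerator and denominator makes self-coherence exactly 1.

## Problem sizes

The package's own test and demonstration runs use a reduced profile
chosen for a single workstation: 20 × 20 JID grid (10 × 10 for the
null-calibration cohort), 8 voices/octave over a multiday period grid,
~100 bootstraps and restarts, and synthetic subjects of 90–180 days.
The full-resolution preset (`runConfig(scale = "full")`) restores the full
50 × 50 × 396 geometry and ~1000 bootstraps/restarts, sized for a
compute cluster. The reduced profile changes resolution and statistical
sharpness, not the method: every stage runs identically at both scales.

**Coherence and strictly periodic synthetic rhythms.** Wavelet coherence
detects a *stable phase relation*, not an in-phase one. The generator's
injected rhythms are strictly periodic sinusoids, so two subjects with
independent but fixed phases are genuinely phase-locked at the rhythm
period and are correctly flagged coherent there — free-running biological
rhythms decohere because their instantaneous period wanders, which the
generator deliberately does not model. Consequently the nominal-rate
calibration of the coherence test is evaluated in a multiday band free of
deterministic components (8–11 days by default): the injected 25-day
rhythm occupies 23–27 days, and the mildly nonlinear mapping from mixture
weight to bin density places a weak second harmonic near 12.5 days.

## Known limitations

- Zeros for empty hours bias power at periods commensurate with strong
  on/off usage patterns; subjects with long silent stretches should be
  interpreted with care.
- The aperiodic adjustment subtracts only the bootstrap mean; slow
  non-stationarities (e.g. secular trends in usage) can masquerade as
  very long periods, which the cone of influence only partly removes.
- Masked CV for NNMF rank is well behaved at moderate noise but, like
  all such criteria, flattens as noise grows; the CV curve is returned
  so flat minima can be inspected.
- The coherence stage assumes a common calendar window; it does not
  align or impute across partially overlapping recordings beyond
  intersecting their hour axes.
- Printed population results from the original cohort study (family
  prevalence percentages, coherence rates) depend on that private
  cohort and are not reproduction targets for the synthetic conditions.
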