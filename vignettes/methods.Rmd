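---
title: "Models and methods behind matecalcium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind matecalcium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(matecalcium)
```

This vignette is the package's own account of its models, the parameters
that matter, the numerical choices made where the design was genuinely
open, and what the synthetic-data generator does and does not establish.

## The measurement model

Each neuron is imaged in two channels: green fluorescence proportional to
calcium-bound indicator, red fluorescence from a calcium-insensitive
reference. Both channels of a neuron share the same optical path through a
moving animal, so focus drift, partial occlusion, and tracking error act as
a common multiplicative factor $m(t)$:

$$G(t) = c_g\,\bigl(1 + a(t)\bigr)\,m(t) + o + \varepsilon_G(t), \qquad
  R(t) = c_r\,m(t) + o + \varepsilon_R(t),$$

where $a(t) \ge 0$ is the calcium activity, $o$ the camera offset, and
$\varepsilon$ additive sensor noise. After offset subtraction the ratio
$(G-o)/(R-o) = (c_g/c_r)(1+a)$ is algebraically free of $m(t)$ **only if
the ratio is taken per sample, before any temporal averaging**. Averaging
the channels first and dividing afterwards leaves a residual of order
$\mathrm{cov}(a, m)$ within each averaging block. The pipeline therefore
runs **ratio → block-mean downsample (10 → 5 samples/s) → Savitzky–Golay
smoothing (order 1, frame 13)**. This ordering is the one deliberate
deviation from a channels-first description of the processing: the
ratiometric rationale (motion-artifact rejection) is exact only this way,
and the package's common-mode acceptance test asserts invariance to
$m(t)$ at relative error below $10^{-10}$.

An order-1 Savitzky–Golay filter with a centered window is identical to the
centered moving average (uniform weights $1/13$); the implementation
computes the least-squares weights for any order and reflect-pads
$(w-1)/2$ samples at each boundary so output length equals input length.
Boundary samples are excluded from acceptance checks. A series shorter than
the window is an error, never a silently shrunken window.

ROI extraction averages each channel over the axis-aligned box of voxels
whose centers lie within the ROI extent (default 2.25 × 2.25 × 3.5 μm) of
the nucleus center. At 0.45 μm pixels and 1.75 μm slices this is 5 × 5
pixels × 3 slices; a voxel center exactly on the ROI face is included
(symmetric box, ties inward). Boxes are clipped at image borders with a
warning; a neuron absent from a required volume is an error naming the
neuron and volume.

## Event-triggered analysis

Activity windows span −7 s to +13 s around each motif onset (101 samples at
5 samples/s), the onset snapped to the nearest sample. Instances whose full
window does not fit in the recording are excluded and counted — padding
would bias window edges. Dataset-averaged curves are min–max normalized to
$[0,1]$; the per-sample standard deviation (the gray band) is computed
before normalization and rescaled by the same affine map, so a constant
average is flagged rather than divided by zero.

Cross-correlation uses per-instance Pearson correlation between the
activity row and the instance's binarized behavior row (indicator over the
motif's intervals; a single-sample impulse for point motifs) shifted by
each lag in −5…+5 samples, on the overlapping support. The selected lag
maximizes the absolute mean correlation across instances (ties resolve
toward lag 0); the sign convention is **positive lag = activity follows
behavior**, recorded in the result to prevent drift. The one-sample t-test
at the selected lag is one-sided (mean correlation greater than zero),
matching how such screens are reported. Per-instance correlations, not the
dataset average, feed the t-test — the test needs per-instance values.

Two caveats are deliberate and documented:

* **Lag selection inflates the test.** Selecting the best of 11 lags and
  then testing at that lag raises the type-I rate above the nominal 5%;
  the package's null-calibration test asserts only a 10% bound.
* **Overlapping windows share noise.** When consecutive onsets are closer
  than the window length, their windows overlap and the per-instance
  correlations are not independent; measured null rejection roughly doubles.
  `thin_onsets()` enforces a minimum spacing (window length plus the
  smoothing-filter width, 23 s for the defaults) and is used in the
  calibration and recovery tests. Analyses of densely repeated motifs
  should either thin onsets or treat the p-value as anticonservative.

Peak latencies are per-instance times of the maximum sample in the search
range, ties toward the earliest sample (so constant rows peak at the search
start and are counted); groups are compared with a two-sided Wilcoxon
rank-sum test (exact for small untied samples, normal approximation with
tie correction otherwise).

## Ethogram scoring

The eight performance measures and the mating success index are computed
from validated ethograms (interval bounds, same-type non-overlap,
vulva-contact nesting inside ventral contact, at most one ejaculation).
Conventions:

* All timestamps are seconds from recording start; intervals are half-open
  $[{\rm onset}, {\rm offset})$; sample $i$ at rate $f$ covers
  $[i/f, (i+1)/f)$.
* Rates are per minute of the relevant interval duration.
* **Courtship duration** is first ventral-contact onset to ejaculation, or
  to recording end when no ejaculation occurred (recordings cap at the
  assay length, emulating the 15-minute assay that stops at sperm release).
* A measure with a zero denominator is **undefined (`NA`), not 0** — a male
  who never contacted the vulva has no spurious-pause ratio. Undefined
  values are dropped from rank-sum comparisons and their counts reported,
  never imputed.
* Cohort percentages are `floor(100 * k / n)`. The floor convention
  reproduces the printed fractions for 5/19 (26%), 5/10 (50%), 13/15 (86%)
  and 1/10 (10%); the one published "2 of 24 (9%)" is neither floor nor
  round of 8.33% and is not reproduced — the package reports 8%.
* "Vulva passes per ventral-contact duration" mixes a count and a duration;
  it is implemented as a rate (events/min), flagged here rather than
  silently reinterpreted elsewhere.

## Spurious-activation screening

The published screen for vulva-circuit activation away from the vulva was
visual; the detector here is its explicit operationalization, with every
parameter exposed and reported alongside each call: per-recording min–max
normalization (matching how such traces are displayed), threshold 0.5 of
the normalized range, minimum duration 1 s, and a ±2 s guard around
vulva-contact intervals. Runs partially overlapping the dilated intervals
are truncated and kept only if the remainder still meets the minimum
duration. Pulse counts are monotone: raising the threshold or minimum
duration, or enlarging the guard, never adds pulses. A male is
spurious-positive iff any designated circuit neuron (PCB, PCC, HOA, HOB,
R2B by default) has at least one pulse; the per-male criterion in the
source material is unstated, so this any-pulse rule is a documented
substitute, and classification is invariant to affine rescaling of the raw
trace.

## The synthetic world

The generator emulates the recordings the analysis was designed for; its
defaults were chosen once, as a plausible control-like male, and are not
estimates of real data (no inter-event timing distributions or coupling
magnitudes were published):

* **Behavior** is semi-Markov with exponential dwells: off-contact episodes
  (mean 20 s) alternate with ventral-contact episodes (mean 60 s). Within
  contact, backward slides (mean 6 s) end in turn attempts
  (Bernoulli success, default 0.9); successes continue with forward slides
  (mean 3 s) and occasional pauses; failures end contact. Vulva encounters
  arrive at 2/min of scanning and become passes (p = 0.3) or nested
  vulva-contact intervals (mean 8 s), which may end in spicule insertion
  and ejaculation (p = 0.3), terminating the recording — at most once.
* **Calcium kernel**: difference of exponentials (rise 0.2 s, decay 1.5 s),
  mimicking GCaMP6s-like dynamics. Interval motifs drive a boxcar convolved
  with the kernel normalized to unit DC gain; point motifs drive unit-peak
  impulse responses.
* **Latency conventions.** The coupling latency is defined as the quantity
  the analysis estimates, because the published statements ("peaks 1.2 s
  after turn onset") are statements about measured traces. For point
  motifs the kernel is shifted so the *pipeline-processed* response peaks
  exactly `latency` seconds after the onset (the deterministic smoothing
  shift of the asymmetric kernel, ≈0.8 s at the defaults, is
  pre-subtracted). For interval motifs the kernel is advanced by its
  half-rise time so the response's half-rise — the feature lagged
  cross-correlation locks onto — follows the onset by `latency`. Both
  shifts make the kernel mildly anticipatory, as real pre-motor activity
  can be; the raw ground-truth argmax therefore sits earlier than the
  nominal latency by the documented shift.
* **Spurious pulses** are boxcar-driven kernel events (default 2 s),
  scaled so the ground-truth peak equals the configured amplitude, placed
  uniformly outside vulva-contact intervals at the configured rate, and
  recorded in the ground truth.
* **Emissions**: shared log-AR(1) motion factor per neuron
  (coefficient 0.95, stationary log-sd 0.05), channel gains 100, additive
  Gaussian sensor noise, scalar camera offset (default 0). A channel noise
  sd of 10 on the gain-100 baseline yields ratio-sample noise of about 0.1
  at the analysis rate — the unit in which signal-to-noise statements in
  the tests are phrased.
* **Rendering**: anisotropic Gaussian nuclei (σ = 0.9, 0.9, 1.2 μm) on a
  reduced 64 × 32 × 10 grid with the native 0.45 μm / 1.75 μm / 10 Hz
  constants; blob amplitude equals the offset-subtracted channel signal, so
  ROI ratios round-trip exactly. Tracks are reflected random walks in the
  volume interior.

Everything is a pure function of (config, seed); reruns are byte-identical.

**What a green test establishes — and what it does not.** The generator
contains no body deformation, no optical PSF, no registration failures, no
segmentation error, no bleaching, and no hermaphrodite side. Passing tests
establish that the analysis correctly recovers what the stated emission
model injects (couplings, latencies, pulse events, performance statistics),
not that it is robust to every artifact of real recordings. Fixture
durations in the test suite (typically 300–600 s instead of full 15-minute
assays) were scaled to keep the suite within its runtime budget; rates and
probabilities were not changed.

## Numerical choices and degenerate inputs

* Downsampling uses non-overlapping block means (photon statistics of ROI
  means are preserved; decimation would discard signal); trailing partial
  blocks are dropped.
* Min–max normalization of a constant curve or trace is degenerate: the
  response curve returns all zeros with a flag and warning; the pulse
  detector returns no pulses with a warning.
* Non-positive red signal after offset subtraction is an error naming the
  neuron and time — it indicates tracking or offset failure, and a ratio
  against it would be meaningless.
* Correlation of a constant segment is undefined; such instances are
  dropped and counted, and it is an error if none remain.
* Exact-tie handling: earliest maximum for peaks, lag nearest zero for
  tied mean correlations.
* The acceptance script derives all sub-seeds from `--seed` and keeps them
  below $2^{31}$.

## Known limitations

* The behavioral generator's dwell distributions are exponential by fiat;
  real motif durations are likely heavy-tailed.
* The t-test calibration bound (10%) applies to independently spaced
  instances; densely repeated motifs require `thin_onsets()`.
* The spurious-positive rule (any pulse in any designated neuron) is one
  defensible reading of an unstated criterion; cohort fractions depend
  on it.
* HDF5 I/O requires the optional `rhdf5` package; without it the volume
  container falls back to RDS. No TIFF reader is bundled.
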