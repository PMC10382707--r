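---
title: "Methods: evoked-potential audiometry, central gain, and cortical cell densities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evoked-potential audiometry, central gain, and cortical cell densities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(audiogain)
```

## The problem this package addresses

Mouse models of hearing disorders often show *bimodal* hearing ability: some
ears of mutant animals have normal auditory brainstem response (ABR)
thresholds while others are substantially elevated, frequently in one ear
only. Relating that peripheral impairment to central consequences requires a
chain of quantitative steps — per-ear threshold detection, classification of
animals against a wild-type reference, extraction of short-latency (ABR wave
I) and cortical (AEP P1/N1/P2) evoked components, the central auditory gain
ratio between them, and planar cell-density and laminar-depth measurements
in cortical sections. `audiogain` implements that chain as tested, reusable
components, together with a synthetic-cohort generator so every stage can be
validated against known ground truth without animal data.

## Signal model and preprocessing

ABR sweeps are band-pass filtered at 100–3000 Hz with a 5th-order
Butterworth design before trial averaging; AEP sweeps are analyzed with only
their (simulated) hardware filtering. Two implementation points deserve
explicit statement:

* **Zero-phase filtering.** The default applies the filter forward and then
  time-reversed (`sosfiltfilt()`), so component latencies are not shifted by
  the filter's group delay. The effective magnitude response is the
  *square* of the designed 5th-order response; a causal single-pass mode is
  available (`filter_mode = "causal"`). Which convention the original
  analyses used is not stated in the source material; latencies extracted
  under the two modes differ by the group delay, so the mode is recorded in
  the sweep-set metadata.
* **Second-order sections.** The band-pass transform doubles the designed
  order to 10. The expanded order-10 polynomial form is numerically fragile
  near $z = 1$ (pole radii ≈ 0.9996 at a 25 kHz sampling rate), so filtering
  uses a cascade of biquad sections. During development the design was
  cross-checked against an independent reference implementation
  (coefficients to 10 digits, zero-phase output to ~1e-13); the test suite
  relies only on the analytic magnitude response as its oracle.

## Feature extraction

*Wave I* amplitude is the difference between the signal at stimulus onset
(t = 0; a literal single-sample baseline, with a mean-of-prestimulus option)
and the first qualifying peak: the earliest local maximum in a configurable
0.5–3 ms window rising at least `prominence_mult` (default 2) prestimulus
noise SDs above baseline **and** at least `rel_height` (default 0.2) of the
window's maximum rise (the half-height convention, `rel_height = 0.5`).
The relative floor is a standard peak-picker guard, and unlike a floor tied
to the noise SD it is SNR-invariant: on noisy traces the earliest-peak rule
alone occasionally (≈1% of synthetic recordings) latches onto sub-ripple
local maxima — filter ringing or noise bumps a fraction of the true wave I
height riding 0.5–1 ms ahead of it — which inflates downstream gain ratios
by an order of magnitude, worst on low-SNR near-threshold recordings. Both
floors are configurable; `rel_height = 0` restores the bare rule. If no peak qualifies the feature is *absent*, which is
distinct from an amplitude of zero and excludes the recording from gain
analyses with a logged reason.

*AEP components* are window extrema with inclusive edges and earliest-sample
tie-breaks: P1 = maximum on [15, 30] ms, N1 = minimum on [25, 60] ms,
P2 = maximum on [60, 110] ms; complex amplitudes are P1−N1 and P2−N1.

*Central auditory gain* is the AEP complex amplitude divided by the ABR wave
I amplitude from the same stimulated ear at the same 80 dB SPL click; it is
undefined (error, or NA with a reason under `on_invalid = "na"`) when wave I
is absent or non-positive.

## Threshold detection

The source material defers its threshold criterion to earlier work without
restating it, so the implemented criterion is this package's own documented
judgment call: a level is response-positive when the peak-to-peak amplitude
in a 1–10 ms post-stimulus window exceeds `k` times the prestimulus noise
SD, and the threshold is the lowest level that is positive together with all
higher tested levels (otherwise "above max tested"). Two calibration
decisions:

* The noise SD is pooled across all levels of the series. A per-trace SD
  from ~125 correlated samples is itself so variable that the peak-to-peak
  statistic of pure noise exceeds 4×SD on most levels.
* `k = 6.5` by default. This was set from a noise-only calculation (3000
  simulated noise series) to hold the false-alarm probability of an entire
  10-level series below ~1%; at `k = 4` pure noise "detects" on 63% of
  levels, which would contradict both the sentinel behavior on unresponsive
  ears and ±1-step threshold recovery. `k` and the window are configurable,
  and this criterion must not be interpreted as a numerical replication of
  the original study's criterion.

## Classification and summary measures

The upper bound of normal hearing is `mean + 2.5 SD` over all wild-type ear
thresholds (ears pooled across animals and sexes, sample SD); an ear is
impaired iff its threshold *strictly* exceeds the cutoff, and "above max
tested" counts as impaired. Animals are normal / monaural HI / binaural HI
from their ear flags; a single-eared animal is classified on that ear and
flagged partial rather than excluded. Hearing loss in dB HL is the animal's
maximum across-ear threshold minus the wild-type mean of that same
per-animal maximum. Longitudinal audiograms are averaged per ear within age
windows [3, 6) and [6, 14] weeks, with sentinel sessions excluded and
counted.

## Histology

PV+ density is counted over the full region polygon (even-odd rule;
on-boundary centroids count as inside, a deterministic convention). NeuN+
density uses a pia-to-white-matter rectangular strip through the region
centroid, oriented along the local pia→white-matter axis, whose width is
solved numerically so the strip∩region area is 5% of the region area
(relative tolerance 1e-3) — the strip construction is otherwise unspecified
in the source material and is configurable. Laminar depth of a centroid is
its projection onto the line from its nearest pial point along the local
inward pia normal to the first white-matter intersection, normalized by that
pia-to-white-matter span and clipped to [0, 1]; when the normal misses the
white matter the nearest-distance ratio $d_{pia}/(d_{pia}+d_{wm})$ is used
and flagged. The "perpendicular to pia *and* white matter" phrasing is
geometrically overdetermined for non-parallel curves; the pia normal is
primary. Counts are binned into 5 (also 10 or 20) equal-depth bins,
half-open except the last. No section-thickness or stereological correction
is applied (planar counts from single-plane images; thickness is metadata).

## Statistics

All tests are two-tailed at α = 0.05. Branch points: Wilcoxon rank-sum uses
full enumeration when min(n) ≤ 8 without ties, otherwise a tie- and
continuity-corrected normal approximation; signed-rank drops zero
differences (Pratt's treatment is a flag), uses midranks on |d|, and
enumerates 2^n sign patterns for n ≤ 12; Spearman's ρ is the Pearson
correlation of midranks with the full n! permutation null for n ≤ 10
(enumerated in chunks at n = 10) and the t approximation above; t tests use
the pooled-variance form, consistent with the classical one-way ANOVA /
Fisher's LSD machinery; LSD p values are unadjusted pairwise t tests on the
ANOVA's pooled within-group mean square, and are only emitted when the
omnibus F is significant (an `"always"` override exists). Degenerate cases
(all-zero differences, zero variance with equal means) return p = 1 with a
warning rather than an error. Ears and hemispheres are treated as
independent sample units by the pipeline's data layout, not by the tests.

## The synthetic cohort: what it emulates, and what it does not

The generator states a world with the structure the analysis assumes:

* Unimpaired ear thresholds ~ Normal(30, 4.35) dB SPL truncated at the
  0 dB instrument floor — the SD is calibrated so mean + 2.5 SD equals the
  40.88 dB SPL cutoff the emulated study prints; mutant ears are impaired
  independently with probability 0.46, monaural cases re-sided to the left
  with probability 0.7, and impaired ears add a Normal(30, 10) shift
  truncated below at 15 dB. The truncation floor keeps every
  flagged-impaired ear above the classification cutoff: in the emulated
  study impairment is *defined* by a supra-cutoff threshold (its published
  impaired ears all sit at 45 dB SPL and above, and its observed 46% per-ear
  rate is taken as the generative rate), so a generator emitting "impaired"
  ears that classify as normal would state an internally inconsistent world
  — its spurious gain-elevated "unimpaired" animals would also contaminate
  the NHI comparison group. Set `impaired_shift_floor = 0` for an
  unconstrained positive shift. The study's per-ear raw data are not
  deposited, so all of this is calibrated only to printed medians, the
  printed cutoff, and the printed figure ranges.
* Evoked responses are sums of Gaussian bumps (the simplest parametric
  waveform with controllable latency and amplitude; the source gives only
  figure exemplars). The common amplitude scale grows linearly as
  `growth × (level − threshold + 10 dB)` for levels at or above threshold
  and is exactly zero below. The 10 dB offset — one level step — makes the
  response non-zero *at* threshold, i.e. the generator's threshold is the
  lowest level with a detectable response; a pure hinge would make
  "detected = true threshold" impossible even without noise.
* The central-gain factor (default 2) multiplies the AEP bump amplitudes of
  impaired animals. Because both the ABR and AEP scales share the same
  level dependence, the AEP/ABR ratio is threshold-independent by
  construction and the HI/NHI gain ratio recovers the factor exactly in the
  zero-noise limit — this is what makes gain recovery a sharp test.
* PV+ density declines as 150 − 2 × dB HL cells/mm² in mutant auditory
  cortex (floored at 0), stays at 150 in wild types and in the control
  area; NeuN+ density is 2500 cells/mm² everywhere. Centroids are placed by
  homogeneous spatial Poisson processes, so laminar profiles are flat by
  construction.
* Trial counts default to 100 with single-trial noise SDs of 2.5 µV (ABR)
  and 15 µV (AEP) — chosen once as a realistic averaged-noise floor while
  keeping simulation budgets tractable; real systems often average several
  hundred sweeps.
* Noise color matters. ABR trial noise is white (broadband; the analysis
  chain band-pass filters it anyway). AEP trial noise is band-limited
  (white noise smoothed by a Gaussian kernel of SD `noise_kernel_ms = 8`
  ms, rescaled to `noise_sd`), emulating the low-frequency-dominated
  residual of averaged cortical EEG. This is not cosmetic: with noise that
  is iid at the sample level, the window-extremum definition of P1/N1/P2
  acquires an additive `E[max]` bias of several µV, and because
  hearing-impaired recordings have ~2× smaller amplitudes than wild-type
  ones, the bias manifests as a spurious relative "gain elevation" even in
  a null world with no gain effect — a behavior never seen in real AEP
  analyses, precisely because real residual noise is smooth at the
  15–50 ms window scale. Extremum extraction on smooth-noise traces is
  unbiased to first order (measured spurious null effect −0.7% vs +19.8%
  for white noise of the same SD).

Features of real data that are *not* emulated: myogenic artifacts, wave
II–V latency shifts, non-uniform laminar distributions, staining dropout,
and between-ear threshold correlation within an animal. A green test therefore establishes
that the analysis chain recovers the stated world's parameters — not that
it would reproduce any particular animal dataset.

Reproducibility: every random quantity derives from a single master seed
through per-unit hashed child streams (`derive_seed()`), so identical seeds
give bit-identical cohorts and output files, and enlarging a cohort does not
perturb existing animals.

## Pipeline conventions

Group labels (WT / mutant-NHI / mutant-HI) are assigned once, by the
classification stage, and joined into every downstream table. Classification
uses each ear's latest session; age-window summaries use all sessions.
Sample units follow the emulated design: recordings/ears for evoked
potentials and audiometry, hemispheres for histology, with per-comparison
accounting of exclusions (undefined gains, sentinel thresholds). The
`average_only` trial mode synthesizes trial-averaged traces directly
(template + noise/√n, distributionally identical to averaging n full
sweeps) and is used for replicate-heavy simulations; `full` mode generates
every trial.

## Known limitations

* The threshold criterion is a documented stand-in, not a replication of
  the original (unpublished) criterion.
* The strip and depth constructions are one defensible reading of a
  one-sentence description; alternatives (e.g. white-matter-anchored
  normals) would differ most where the boundaries are strongly non-parallel.
* Exact Spearman enumeration is O(n!) and capped at n = 10.
* Percentile-bootstrap confidence intervals at small per-group sizes
  (~10–16 recordings) have mild undercoverage; the gain-recovery
  acceptance tolerates this in its ≥90% coverage bound.
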