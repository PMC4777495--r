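---
title: "Measuring body-motion angularity from 2D landmark traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring body-motion angularity from 2D landmark traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(angulate)
```

## The measurement problem

Body movements can look *angular* (fast, jerky, with sharp changes of
direction) or *rounded* (slow, smooth, sweeping). angulate quantifies this
from the simplest possible recording: per-frame 2D pixel positions of a
small set of named body landmarks (forehead, throat, ears, shoulders,
elbows, hands, navel, plus two static lectern corners), in image
coordinates (origin top-left, y down). Such traces are typically encoded
at a reduced stride; `interpolate_stride()` restores the full frame rate
by per-coordinate linear interpolation between keyframes, never
extrapolating past the last keyframe.

Rather than tracking every landmark separately, overall motion is
summarised by summing a small aggregation set — by default forehead (head
motion), left shoulder (torso motion) and both hands (arm motion) — into a
single 2D time series per stimulus (`aggregate_trace()`). Summation keeps
the trace linear in the input coordinates, so distances scale with the
video resolution and angles do not depend on it at all.

## Direction-change segmentation

The core primitive is a reference-point scan (`segment_maxima()`). The
first frame is the reference; the Euclidean distance from the reference to
each successive trace point is followed until it reaches a maximum, i.e.
until the next distance is strictly smaller. That frame's distance is
recorded as one *motion unit* (an excursion away from the reference), the
frame becomes the new reference, and the scan resumes. Three boundary
rules make the procedure total and unambiguous:

* **Ties extend the scan.** A plateau of equal distances peaks at its last
  frame; only a strict decrease closes a unit.
* **Threshold.** A unit is only emitted if its peak distance exceeds
  `epsilon` (default 0 pixels). This is the documented counter-knob for
  per-frame jitter: sub-threshold wiggles produce no units.
* **Trailing units.** If the series ends while the running distance still
  exceeds `epsilon`, the unfinished excursion is emitted with
  `trailing = TRUE`. Discarding it would systematically undercount short
  clips; the flag lets a user exclude it instead.

Four measures follow (`extract_features()`):

1. **Number of maxima** — the count of motion units; more direction
   changes, more angular motion.
2. **Average velocity** — each unit's distance divided by the frames it
   took, averaged over units (pixels/frame). No frame rate is assumed;
   converting to pixels/second is left to the caller because encoded
   material rarely states fps reliably.
3. **Average turning angle** — the chain of reference points defines
   successive motion vectors; each consecutive pair subtends an unsigned
   angle computed from the clamped normalised dot product (0° = straight
   continuation, 180° = full reversal). The mean over pairs estimates
   dynamic angularity. Pairs containing a zero-length vector are skipped.
4. **Average body-part angle** — a static, per-posture measure: on each
   side, the turning angle between the shoulder segment (throat→shoulder)
   and the upper arm, and between the upper arm and the lower arm, with 0°
   meaning collinear extension. The four angles are summed per frame (range
   0–720°) and averaged over frames. The chain-turning convention is the
   one under which larger values mean more pointed articulation. The
   anchoring of the shoulder angle to the throat→shoulder segment is a
   package choice; the alternative (horizontal anchor) is not exposed
   because it breaks rotation invariance.

Measures that are undefined for a stimulus — no units, fewer than two
units, missing arm chains — are reported as `NA`, never coerced to 0, so
downstream correlations cannot be silently biased.

Invariance properties pin the implementation down: all four measures are
invariant under rigid motion (rotation/translation) of the landmark set;
distances and velocities scale linearly with the coordinates while counts
and angles are scale-free. The test suite checks these properties on
randomly generated traces, and checks the scan itself against an
independent brute-force re-scan that recomputes every distance from
scratch at each step.

## The statistical battery

`pearson_ci()` implements the product-moment correlation with the
textbook normal-theory inference (two-sided t test on n − 2 df, Fisher-z
95% interval). `icc_average()` implements the Shrout–Fleiss
average-measure intraclass correlations for complete stimulus × rater
panels: ICC(2,k) (two-way random, absolute agreement) is the default
because rater panels are samples from a population of raters; ICC(3,k)
(consistency) is selectable for sensitivity analyses. Confidence intervals
use the F-based constructions; the ICC(2,k) bounds are the Spearman–Brown
step-up of the single-rater bounds with Satterthwaite degrees of freedom.
When the residual mean square is exactly zero (noiseless panels) the
bounds collapse to their algebraic limits rather than returning NaN.

`binomial_exact()` performs the forced-choice test: a one-sided (greater)
exact binomial test against chance p₀ = 0.5 — the directional question is
whether observers score *above* chance — paired with the conventional
two-sided Clopper–Pearson interval, matching standard exact-test output.
`analyze_choices()` applies it overall and within each word condition;
`select_extremes()` builds the extreme groups (k lowest / k highest on a
chosen measure, default average velocity) with a deterministic tie-break:
the low tail is filled first in ascending (value, id) order and the high
tail from the remainder, so k = n/2 always partitions the stimulus set.

No multiple-testing correction is applied anywhere; correlation tables
report raw two-sided p-values, and reliability is reported per stimulus
subset because different raters judge different subsets.

## What the synthetic generator emulates

`generate_trace()` produces pendulum-like piecewise-linear motion: per
segment an amplitude (Gaussian, default mean 50 px, sd 15) and a duration
(Gaussian, rounded, default mean 6 frames, sd 2), and at each boundary a
heading change drawn from a folded von Mises distribution (mean angle in
degrees, concentration κ; κ = ∞ gives exactly the mean). One von Mises
concentration parameter spans the whole regime of interest: low mean
angles give smooth, "maluma-like" curving paths, means near 180° give
jerky, "takete-like" reversals. Defaults (mean 120°, κ = 4, 40 segments)
sit in between, resembling gesturing at a lectern; they were fixed once,
before any recovery experiment, and are not tuned.

Every direction change passes through a one-frame **micro-recoil**: a step
of 10⁻⁶ × mean amplitude backwards along the incoming heading. Physically
this is the deceleration–reversal–acceleration a limb undergoes at a turn,
collapsed to one frame. Geometrically it is what makes planted structure
recoverable at all: the running distance from the current reference point
keeps growing through any turn shallower than 90°, so without a momentary
retreat no distance-based detector could see such corners. With the
recoil, every planted boundary produces a strict decrease, the detected
reference points coincide with the planted corners, and the chord that
defines each recovered unit differs from the planted segment by O(10⁻⁶)
relative error. The generator reports its ground truth (segment count,
corner frames, per-segment velocities with the recoil frame included in
elapsed time, realized heading draws) as an attribute computed from its
own geometry — never by running the segmentation.

`generate_stickfigure_series()` wraps a base trajectory with the full
13-landmark skeleton: rigid head/torso offsets, static lectern corners,
and arms whose shoulder and elbow joint angles oscillate sinusoidally
around configurable means (left arm in antiphase), so the planted static
angularity is known exactly per frame. `generate_ratings()` plants a
target correlation between a feature and the stimulus-mean rating by
mixing the z-scored feature with independent noise at the configured
loading, then adding per-rater Gaussian noise and clipping to the
−100..+100 semantic-differential scale (rater noise attenuates the
realized correlation by a factor ≈ (1 + σ²/(R·s²))^−½, about 2% at the
defaults). `simulate_forced_choice()` draws word and side uniformly and
follows a logistic choice rule on the z-scored feature difference with a
planted sensitivity.

What passing these recovery tests shows — and does not show. They
demonstrate that the measurement pipeline is internally correct: planted
kinematic quantities are recovered at the stated tolerances from data that
match the pipeline's assumptions. They do not validate the measures
against real human motion: video-derived landmarks come with tracking
error that is neither i.i.d. nor Gaussian, limbs accelerate smoothly
rather than piecewise-linearly, and real direction changes are spread over
several frames. The `epsilon` threshold and the trailing-unit flag are the
two knobs provided for such data.

## Numerical and design choices

* Angles are always unsigned degrees via `acos()` of a dot product clamped
  to [−1, 1]; no `atan2` signed convention leaks into any measure.
* Maximum detection uses strict decrease; equality never closes a unit.
* All randomness flows from a single integer seed per generator config
  (`withr::with_seed`), leaving the caller's RNG stream untouched; equal
  configs give bit-identical output.
* The von Mises sampler is the Best–Fisher (1979) rejection scheme,
  implemented in the package.
* Problem sizes in the test suite — 1000 random traces up to 200 frames
  for the oracle comparison, 100 noiseless recovery replicates of
  200-segment traces, 2000 simulated datasets for interval coverage, 500
  replicate panels of 60 stimuli × 25 raters — were chosen as the smallest
  sizes at which the Monte-Carlo error is comfortably below each stated
  tolerance.
* The command-line wrapper (`inst/cli/angulate.R`) is a thin layer over
  `run_features()`, `run_experiment1()` and `run_experiment2()`; exit
  codes are 0 (success), 2 (input/format/data error), 3 (parameter error).

## Known limitations

* Velocities are in pixels per frame; cross-study comparison requires
  knowing the source frame rate and image scale.
* The body-part angle ignores wrists and legs; it measures arm/shoulder
  articulation only.
* ICC variants assume a complete panel within each subset; incomplete
  designs are rejected rather than imputed.
* The segmentation reacts to the *summed* trace: perfectly antiphase
  movements of two aggregated landmarks can cancel and produce no units.

## A minimal session

```{r example}
library(angulate)
library(dplyr)

# one synthetic speaker, measured
series <- generate_stickfigure_series(motion_config(n_segments = 12, seed = 1))
extract_features(series)

# a 60-stimulus panel with planted structure, through both experiments
feats <- tibble::tibble(stimulus_id = sprintf("s%02d", 1:60), value = rnorm(60))
ratings <- generate_ratings(feats, rater_config(loading = -0.6, seed = 2))
run_experiment1(ratings)$icc

velocities <- rename(feats, avg_velocity = value)
run_experiment2(velocities, sim = choice_config(sensitivity = 2, seed = 3))$choices
```
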