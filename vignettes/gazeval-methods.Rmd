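---
title: "Scoring infant action prediction, pupillometric action evaluation, and prospective reaching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring infant action prediction, pupillometric action evaluation, and prospective reaching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazeval)
```

## The measurement problem

gazeval scores a three-task infant individual-differences design recorded on
a 60 Hz remote eye tracker:

* **Action prediction.** The infant watches a model repeatedly spoon food
  from a bowl to her mouth. The dependent variable is the latency of the
  infant's first qualifying fixation in a mouth-sized area of interest (AOI)
  relative to the moment the spoon reaches the mouth; negative latencies mean
  the gaze arrived first — a predictive gaze shift.
* **Action evaluation.** The infant watches one actor hand a block either
  into the other actor's outstretched hand (appropriate) or onto her head
  (inappropriate). Surprise is indexed by the event-related pupil dilation:
  the change in pupil diameter from a pre-event baseline, compared between
  the two conditions.
* **Motor development.** Human coders annotate reaching trials toward a toy
  moving at constant velocity; the dependent variable is reach onset relative
  to the toy's midline crossing, again with negative = prospective.

The scientific question the design serves is whether these abilities covary
across infants — evidence that gaze predictions and outcome evaluations are
coupled, as an internal-forward-model account of social perception expects.
The package therefore ends in a statistics layer: variable orientation,
pairwise-complete Pearson correlations, t-tests, skewness screening, and
predictive/reactive/excluded classification tables.

Because no public raw dataset accompanies this design, the package carries a
first-class synthetic-cohort generator with known latent traits. Every
scoring rule is validated by parameter recovery against that ground truth,
and the low-level algorithms against independent brute-force oracles.

## Fixation filtering

Fixations are detected with a sliding-window velocity-threshold filter in the
I-VT family. The velocity at sample $i$ is the Euclidean distance between the
mean gaze position of the `window` samples before $i$ and the `window`
samples from $i$ onward, in pixels per window. The two published parameters
are a velocity threshold of 35 px/window and a 35 px centroid-distance
threshold for merging adjacent fixations. The window length is not published;
we default to 5 samples, the classic implementation's usual setting, and
expose it as a parameter.

Classification proceeds as:

1. maximal runs of samples with defined velocity below threshold become
   candidate fixations;
2. **boundary assignment**: each candidate absorbs contiguous valid-gaze
   neighbours lying within the distance threshold of its centroid;
3. consecutive candidates with centroids closer than the distance threshold
   merge, provided fewer than `window` invalid-gaze samples separate them;
4. candidates shorter than `min_duration` (default 1 sample — we impose no
   minimum the protocol does not state) are dropped.

Step 2 deserves comment, because it is the one place where a naive reading of
"runs below threshold" would misbehave. A two-window velocity estimate is
elevated for up to `window` samples on either side of every saccade and is
undefined near the recording edges, so raw below-threshold runs
systematically start late and end early — at 60 Hz, a 5-sample window would
bias every fixation onset by up to ~83 ms, an order of magnitude more than
the sample period, and the latency DV inherits that bias. Distance-bounded
boundary assignment reattaches exactly those transition samples that belong
to the fixation (they sit at the fixation's location) while never crossing a
saccade (whose samples are far from the centroid) or a tracking loss (the
extension requires valid gaze). With it, the filter recovers embedded
fixation onsets to within one sample period, which the recovery tests
enforce end-to-end. Merging across a gap is allowed only when fewer than
`window` invalid samples intervene: short blinks do not split a fixation,
long tracking losses do.

Equivalence with an independently written brute-force implementation
(naive per-sample loops) is asserted on 200 randomized traces in the test
suite, to 1e-9 px on centroids and exactly on boundaries.

## AOI latency scoring

AOIs are rectangles centered on stimulus landmarks, sized in visual degrees
(6.3° x 3.8° for both bowl and mouth) and converted to pixels through the
screen geometry: extent$_{px}$ = $2d\tan(\theta/2)$ / (mm per pixel), per
axis. The protocol names the eye tracker but not the viewing distance or
panel size, so the geometry defaults (1920 x 1080 px, 509 x 286 mm, 600 mm
viewing distance) are documented assumptions, overridable per setup.

A prediction trial is scored in three steps, following the published
inclusion rules:

1. the infant must have a bowl-AOI fixation overlapping the interval from
   food pickup until the spoon leaves the bowl — otherwise
   `no_bowl_fixation`;
2. within the scoring window from spoon-leaves-bowl until 1 s after the
   spoon reaches the mouth, a bowl-AOI fixation must be followed by a
   mouth-AOI fixation — otherwise `no_mouth_fixation`;
3. the latency is the onset of that first qualifying mouth fixation minus
   the arrival time, in ms.

Three choices here were genuinely open and are fixed as follows. AOI
membership is decided by the fixation *centroid*, because the protocol ties
AOI entry to the fixation filter rather than raw samples. A fixation that
begins before the scoring window but persists into it counts, with latency
measured from its onset — onset is the only unambiguous reading of "the time
at which the infant fixated". "Bowl then mouth" is read minimally as strict
ordering of onsets, ignoring intervening fixations elsewhere. Event times
are trusted stimulus annotations (properties of the movie), not inferred
from pixels.

Participants need at least two scored trials (the published rule); included
participants are classified predictive (mean latency < 0) or reactive.

## Pupil preprocessing and dilation scoring

The cleaning chain applies four steps strictly in this order, each with its
published parameter:

1. samples outside 2.5–5.5 mm become missing (the bounds themselves are
   physiologically possible and are retained);
2. a sample differing by more than 1 mm from the previous *retained* sample
   becomes missing. Referencing the previous retained value (rather than the
   previous raw sample) means an isolated spike is rejected once and does
   not cascade: the sample after it is compared against the pre-spike level;
3. interior missing runs shorter than 10 samples are linearly interpolated
   between flanking retained values; 10-sample and longer runs, and runs
   touching either end of the series, stay missing;
4. a 10-sample moving average. An even width cannot be centered exactly; the
   window spans 5 samples back through 4 forward and is truncated at the
   edges of each contiguous retained segment, so smoothing never bridges a
   gap that step 3 declined to fill, and output is missing exactly where
   input is.

The step order is load-bearing (smoothing before interpolation gives a
different series) and is regression-tested against a hand-computed reference
sequence. Both eyes are averaged where both are tracked, the single tracked
eye is used otherwise — standard practice where the protocol is silent.

A trial's dilation score is the mean cleaned diameter over the 3000 ms
analysis window starting at the giver's grasp minus the mean over the
1000 ms baseline immediately before it. A trial is valid when both windows
lie inside the trace and each retains at least half its samples after
cleaning (`min_valid_fraction = 0.5`; the protocol states only the trial
count rule, but some per-trial validity rule is unavoidable and this one is
explicit and tunable). Participants need three valid trials per condition;
the participant DV is the inappropriate-minus-appropriate difference of
condition means, so positive values index surprise.

## Reach scoring

Reach coding is human work; the package consumes its outputs. A trial is
valid when the infant attended at trial start and the coders judged the
movement a reach. The latency is reach onset minus midline crossing. Only
fast trials enter the DV: the slow trials showed no task demands in the
original screening and are removed. One valid fast trial suffices for
inclusion, matching the analyzed 1–2 trial range.

## Statistics layer

For the correlation analysis, variables are oriented so high performance is
positive: both latency measures are negated, the dilation difference is
already positively oriented. One-sample t-tests against zero (per measure,
raw units), dependent t-tests for age comparisons, and pooled-variance
two-sample t-tests (matching the integer degrees of freedom in the reporting
convention; Welch available by flag) are wrappers over `stats::t.test`.
Correlations use pairwise deletion, so n varies cell by cell, with two-sided
p from $t = r\sqrt{(n-2)/(1-r^2)}$. Skewness is the adjusted Fisher–Pearson
coefficient. Degenerate inputs (zero variance, too few observations) raise
errors rather than returning infinities; in particular a paired test on
exactly equal vectors errors instead of reporting t = 0. Raw p-values are
reported without multiple-testing correction, which mirrors the reporting
style this pipeline reproduces; users needing corrections can apply
`p.adjust` to the correlation table.

## The synthetic cohort

The generator emulates the statistical structure the analysis assumes, not
the physics of infant gaze. Each participant has a latent trait vector —
prediction latency (ms), dilation amplitude (mm), reach latency (ms) — drawn
from a trivariate normal. Trait correlations are configured on the
performance-oriented scale and sign-flipped internally for the raw latency
traits, so the configured prediction-evaluation correlation is exactly what
the oriented statistics layer should recover.

Defaults were chosen once, from the published group-level results, and
define the study conditions for all recovery tests:

* trait means −40 ms (prediction, 6-month group), 0.063 mm (dilation
  difference), −380 ms (reach);
* trait SDs from the published SEs times $\sqrt{n}$: 400 ms, 0.14 mm,
  350 ms;
* oriented trait correlations 0.34 (prediction–evaluation, the design's key
  cell), 0.33 (prediction–motor), 0.12 (evaluation–motor);
* per-trial timing noise 150 ms SD (a plausible infant saccade/reach timing
  jitter), per-sample pupil noise 0.05 mm, fixational jitter 2 px (below the
  velocity threshold);
* artifacts: blinks at 0.2/s with geometric mean length 5 samples, 0.05/s
  single-sample pupil spikes (out-of-range values or >1 mm steps, so the
  cleaning chain has real work to do), and per-trial dropout probabilities
  0.35 / 0.08 / 0.5 (prediction / evaluation / reach) approximating the
  per-task attrition the original cohort showed.

Trial timelines are shorter than the full stimulus movies and cover exactly
the analyzed events: prediction trials run 4.5 s (pickup at 0.4 s, spoon
leaves bowl at 1.6 s, reaches the mouth at 3.2 s), evaluation trials 5.0 s
(grasp at 1.5 s, leaving a full baseline and a full 3 s analysis window).
Six prediction trials, 6 + 6 evaluation trials, and 3 slow + 3 fast reach
trials per participant match the protocol.

The pupil response is a gamma-shaped kernel ($t^{shape-1}e^{-t/b}$, peak at
1.2 s) scaled so its *mean over the 3 s analysis window* equals one; a trial
generated with amplitude $A$ then has a noiseless window-mean change of
exactly $A$, making the latent trait directly comparable to the scored DV.
The kernel is a generator-side assumption only — the scoring side never uses
it, so recovery tests cannot be satisfied by construction.

All randomness flows from one seed: traits use it directly and each
participant's trial stream uses a seed derived deterministically from it, so
any subset of the cohort regenerates identically and written cohorts are
byte-stable.

**What the generator does not emulate** — and hence what passing recovery
tests do and do not show. Gaze is piecewise-stationary with Gaussian jitter:
no smooth pursuit, no saccade main sequence, no drift or calibration error.
Attrition is independent per trial, so participant exclusion rates are lower
and less clustered than in real infant cohorts, where attention failures
correlate within session. Pupil noise is white; real pupillometry has
autocorrelated noise and luminance responses. Traits are Gaussian
(heavy-tailed options exist in configuration for robustness exercises).
Passing tests therefore demonstrate that the *scoring rules are implemented
correctly and recover what they claim under the stated noise model* — not
that the pipeline is robust to every pathology of real infant data.

## Numerical choices and degenerate inputs

Windows are half-open (`[lo, hi)`) everywhere — AOI rectangles and pupil
scoring windows — so adjacent windows partition the grid without double
counting; window indices are resolved by integer arithmetic on the uniform
sample grid with a 1e-9 s guard against floating-point boundary error.
Velocities are computed with long-double prefix sums. An all-missing pupil
trace cleans to all-missing; an empty recording yields zero fixations; a
cohort in which everyone is excluded reports undefined included-base
percentages as missing rather than dividing by zero. Scoring failures are
statuses (`no_bowl_fixation`, `no_mouth_fixation`, `no_data`,
`window_outside_trace`, `insufficient_valid_samples`), never silent drops or
errors, so trial bookkeeping always adds up.

One reconciliation worth recording: the trait-identifiability check scores
noiseless evaluation trials both on the raw trace (where the recovered
change equals the latent amplitude times the kernel's discrete window mean
to 1e-9 mm) and through the full cleaning chain (where the moving average's
edge truncation at the grasp boundary perturbs the window means by a few
1e-4 mm, so agreement is asserted at 5e-4 per-trial and the participant
difference at 0.005 mm). The smoothing perturbation is two orders of
magnitude below the 0.063 mm effect of interest.

## Validation problem sizes

The test suite validates at sizes chosen to make the Monte Carlo bounds
sharp while keeping a full run practical on one CPU: 200 random traces for
filter-oracle equivalence; 100 trials per condition for dilation-amplitude
recovery (±0.01 mm); 500 replicates of a 78-participant cohort for recovery
of the 0.34 prediction–evaluation correlation (mean within ±0.05); 1000
replicates under a null trait correlation for type-I calibration (rejection
rate within 3–7% at α = 0.05); 10,000 participants for trait-sampling
checks. `scripts/acceptance.R` runs the full pipeline once at the original
cohort size (n = 118).

## Limitations

The filter's boundary-assignment stage means fixation boundaries can differ
at the sample level from vendor exports of the same family of filters;
analyses mixing vendor-exported and re-filtered fixations should not assume
interchangeability. The Vineland motor covariate is carried as an optional
external column, never computed. The pipeline scores one age group per run;
longitudinal comparisons are made by running each age and pairing the
summary tables (`paired_t` handles the pairwise deletion). No pupil
foreshortening or luminance correction is applied.
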