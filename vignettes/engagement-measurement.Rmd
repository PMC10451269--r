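---
title: "Measuring engagement in robot-assisted therapy sessions"
author: "engagekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring engagement in robot-assisted therapy sessions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(engagekit)
```

## The measurement problem

In robot-assisted autism therapy (RAAT), a social robot runs short,
scripted interaction tasks with a child while the session is recorded by
the robot's camera. Therapists score the child's behaviour on an
assessment sheet, but that score is subjective and coarse. The goal of
this package is an objective, frame-resolved engagement measure from the
video that can be compared against the therapist's assessment.

The measure rests on the circumplex model of affect, which places
affective states on two orthogonal axes: **valence** (pleasure vs.
displeasure) and **arousal** (activation). Engagement is identified with
the positive-valence, high-arousal quadrant. `mapVAToEngagement()`
implements this as strict inequalities — a state on either axis is *not*
engaged. The strictness is a deliberate, conservative tie-break: the
engaged quadrant is open, so no rescaling of the coordinates can move a
boundary state into it, and ambiguous (neutral) states never inflate
engagement percentages.

## The pipeline

Frame analysis proceeds in four stages, mirroring how a deployed system
would treat camera video:

1. **Frame extraction** (`extractFrames()`): a recording is an ordered
   stream of grayscale frames. The tested path is directories of still
   frames; colour input is reduced by the ITU-R BT.601 luma weights.
   Optional subsampling picks, for each target time `k/targetFps`, the
   frame with the nearest native timestamp.
2. **Face detection** (`detectFace()`): the synthetic backend thresholds
   intensity and takes the largest bright connected component; when two
   faces are present the larger area wins. Real detectors (e.g. a
   pretrained 68-landmark model) plug in behind the same contract — a
   function from a frame to a scored box — so no model file needs to be
   bundled or downloaded.
3. **Landmark extraction** (`extractLandmarks()`): 68 points in the
   iBUG-300W ordering (jaw 0–16, brows 17–26, nose 27–35, eyes 36–47,
   mouth 48–67). The synthetic backend fits the face template into the
   box for the affect-independent points and re-measures the
   affect-bearing ones (eye components, mouth component) from the image,
   so valence and arousal survive extraction. Frames where detection or
   extraction fails are flagged no-face; partial landmark sets never
   propagate.
4. **Classification** (`classifyFrames()`): landmarks are normalized
   (`normalizeLandmarks()`: inter-ocular midpoint at the origin,
   inter-ocular distance 1 — removing translation and scale), rasterized
   into a 64×64 single-channel image of Gaussian blobs
   (`rasterizeLandmarks()`), and classified by the convolutional
   network.

## The classifier

The network is fixed by specification: three convolution blocks with 32,
32 and 64 filters, all 3×3 kernels, a ReLU rectifier after every
convolution and a 2×2 max-pool after every rectifier, then a flatten and
a dense 2-way head. `classifierSpec()` enforces these constants through
S4 validity, and `classifierLayers()` audits the realized parameter
shapes rather than the declared ones.

Two representation choices were genuinely open:

* **Input tensor.** The upstream feature set is 68 saved (x, y)
  coordinates per frame, while the classifier is convolutional. We
  rasterize the normalized landmarks into a small heat-map-style image
  (one Gaussian blob per landmark in a fixed canonical window), which
  keeps the convolutional architecture meaningful while consuming
  exactly the saved coordinates. Raw face crops could be substituted
  behind the same interface.
* **Pooling placement.** A single pooling mention after the rectifier
  description is read as the standard one-pool-per-block pattern; a
  single-pool variant would be one configuration change.

Training (`trainClassifier()`) minimizes 2-class cross-entropy with
minibatch Adam (batch 32, learning rate 10⁻³) on a fixed-seed shuffled
80/20 train/validation split. No training regimen was prescribed, so
these are conventional small-network defaults. Everything is
deterministic given the seeds: weight initialization comes from the spec
seed, the split and epoch permutations from the training seed, and the
C++ core (Rcpp/RcppArmadillo, im2col + GEMM convolutions with exact
analytic backprop) is single-threaded. The backprop is verified against
central finite differences in the test suite; agreement is limited to
about 10⁻³ relative at the worst sampled coordinate by ReLU/max-pool
kinks, which is the expected behaviour for piecewise-linear networks.
Class decisions are arg-max with ties broken toward *not engaged*.

## Session-level metrics

Per task, the model-side engagement percentage is

\[
\mathrm{EPM} = 100 \cdot \frac{\#\{\text{frames classified engaged}\}}
                            {\#\{\text{frames}\}},
\]

and the therapist-side percentage is

\[
\mathrm{EPT} = 100 \cdot \frac{\text{sum of points}}
                            {\text{maximum possible points}},
\]

with 8 items on a 0–3 agreement scale, hence 24 points per task. (The
published statement of the EPT denominator is garbled in print; the
points-over-maximum reading is the only one consistent with the stated
24-point task maximum.)

Frames with no detected face are governed by an explicit policy:
`count_not_engaged` (default) keeps them in the denominator as not
engaged — a child whose face is turned away from the robot is, for this
measure, not engaged with it — while `exclude` drops them from both
numerator and denominator. The policy and the no-face count are always
recorded in the task metrics so both readings stay auditable.

Per child, the overall percentage is the **unweighted mean of the
per-task percentages, rounded half-up**. This rule was reconstructed
from the published five-child results table: it reproduces four of the
five printed overalls exactly (83.67→84, 41.33→41, 15→15, 9.33→9),
whereas frame-weighted pooling does not (e.g. 82.7 for the first child).
The remaining child prints 14 against a reconstructed 13.33→13; the
published overall was most plausibly computed from unrounded task
values. The package asserts that child within ±1 and flags it
(`reproduceTable3()$per_child$expected_within_one`) rather than guessing
an unprinted convention.

## Agreement

Each child's overall EPM and EPT are binarized at the **inclusive** 50%
threshold and compared with Cohen's kappa from the 2×2 contingency
table. With five subjects, degenerate tables are easy to hit, so they
are defined rather than raised: both raters constant and identical gives
κ = 1, both constant but different gives κ = 0, and both cases carry a
`degenerate` flag. The interpretation bands are the standard ones
(≤0 none, 0.01–0.20 slight, 0.21–0.40 fair, 0.41–0.60 moderate,
0.61–0.80 substantial, 0.81–1.00 almost perfect); the printed bands
leave (0, 0.01) unassigned and we map it to *slight* by continuity,
always interpreting the unrounded κ. On the published five-child
percentages the binarized labels coincide and κ = 1:

```{r}
rep <- reproduceTable3()
rep$per_child
rep$kappa
rep$band
```

## The synthetic generator

No clinical recordings are distributable, so the generator is the
package's source of labelled data, and its defaults encode the study
conditions it emulates: one child per session, three tasks of 2–20 s,
~10 fps face-visible video (the published per-task frame counts imply
roughly 9.5–12.5 fps; 10 is the default, configurable per task), frames
of 96×96 px.

* **Dynamics**: a two-state Markov chain over engaged/disengaged with
  stay probabilities 0.9/0.9 per frame (engagement bouts of ~1 s at
  10 fps, a plausible timescale for young children). The engaged state
  emits valence and arousal uniformly from the open positive quadrant;
  the disengaged state emits uniformly from one of the three remaining
  quadrants, chosen uniformly — the publication never says how
  non-engagement distributes, and the uniform choice keeps the null
  symmetric.
* **Faces**: schematic but metrically honest. Mouth-corner height is
  strictly monotone in valence; eye opening and mouth opening are
  strictly monotone in arousal. The 68 ground-truth landmarks and the
  bounding box are recorded exactly in the manifest.
* **Noise**: `landmarkNoisePx` has two coupled effects — it perturbs
  the face-geometry parameters used for *both* rendering and truth
  (what a camera/detector would actually see), and it adds i.i.d.
  per-point annotation jitter to the recorded landmarks. Noise
  therefore flows through the classifier's input, which is what makes
  accuracy degrade monotonically with noise in the validation suite.
  `noFaceProb` (default 0.05) emits faceless background frames,
  emulating the face leaving the camera view; the engagement flag is
  defined from valence/arousal alone, so a child can be engaged while
  the face is lost.
* **Therapist sheets**: each of the 8 items is
  `clip(round(3·(fraction + noise)), 0, 3)` with Gaussian rater noise
  (default sd 0.1 on the fraction scale), so sheet totals correlate
  strongly with true engagement without being a deterministic copy.

What the generator does **not** emulate: photographic appearance,
illumination, pose and out-of-plane rotation, occlusions other than
total face loss, detector idiosyncrasies, or several people in frame.
Passing the synthetic suites therefore demonstrates that the pipeline's
logic, statistics and learning machinery are correct — not that a
pretrained face stack would reach the same accuracy on clinical video.

## Numerical choices and degenerate inputs

* Half-up rounding (`floor(x + 0.5)`) for all printed integer
  percentages; R's banker's rounding would disagree with the published
  overalls on .5 boundaries.
* Frame counts per task are `round(duration × fps)` with the same
  half-up rule, for determinism across platforms.
* The landmark raster window is x ∈ [−1.6, 1.6], y ∈ [−1.35, 1.85]
  canonical units — the full template with margin; landmarks that fall
  outside (extreme noise) are clipped and counted.
* Undefined metrics raise errors rather than returning NA: EPM on zero
  frames (after the exclude policy), EPT with items outside {0..3},
  kappa on vectors shorter than 2, normalization with coincident eye
  centroids.
* Problem sizes in the validation suites — 2000 training frames, 5
  epochs, three-task sessions of 19/8/19 s, noise levels {0, 2, 5} px —
  are the package's reference conditions for end-to-end recovery
  (≥95% per-frame agreement and ≤5-point session EPM error on clean
  data, monotone degradation under noise).

## Known limitations

* The synthetic face detector is intensity-based and only meaningful
  for the bundled renderer; real video requires plugging a pretrained
  detector/landmarker into the backend contract.
* Video container decoding is not included; recordings must be
  pre-extracted to frame directories.
* Kappa is reported without confidence intervals (none are published
  for the endpoint being reconstructed); with five subjects the
  uncertainty is substantial, which is precisely why the degenerate
  cases are handled explicitly.
* The 50% binarization discards most of the information in the
  percentages; it is retained because the agreement endpoint is defined
  that way.
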