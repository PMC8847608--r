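---
title: "Detecting facial and body grooming from top-view mouse video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting facial and body grooming from top-view mouse video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Self-grooming is a sensitive readout of a rodent's internal state: stressors,
drugs and genetic backgrounds change how often and in what pattern mice groom,
and the *microstructure* matters — face washing (rostral) and body licking
(caudal) respond differently. Scoring grooming by eye is slow and
observer-dependent, and most automated detectors neither distinguish facial
from body grooming nor work with plain overhead video.

`ethogroom` implements a complete detection pipeline for exactly this
setting: a single mouse in a dark arena filmed from above at 60 Hz. Every
frame is classified into one of three states — `0` not grooming, `1` facial
grooming, `2` body grooming — and contiguous runs of one grooming class form
*bouts*, the unit of most downstream analyses (an ethogram).

## Pipeline

### 1. Motion images

Color and texture are nearly uninformative overhead; motion is the signal.
Consecutive frames are absolute-differenced (channel-wise, before
grayscaling), cropped to a square around the animal's centroid, resized,
grayscaled and thresholded to binary:

* **Centroid**: threshold the raw frame (default 100/255, bright-foreground
  polarity for a white mouse on a dark arena), keep the largest 8-connected
  component, take its mean pixel coordinates. If segmentation fails the
  previous frame's centroid is reused; failure on the first frames is an
  error.
* **Crop side** (default 256 px at 1080p geometry): large enough to contain
  the animal with margin; cropping around the centroid makes the
  representation translation-invariant, so the classifier sees locomotion as
  peripheral motion crescents around a centered body rather than as
  displacement.
* **Resize** (default 128×128): area averaging when the factor is an
  integer, bilinear otherwise. Area averaging is deliberate: point-sampled
  interpolation lets isolated hot pixels of sensor noise survive
  binarization, whereas averaging dilutes a single noisy pixel well below
  threshold while spatially coherent motion survives.
* **Binarize** (default 20/255): suppresses residual sensor noise; the
  result is a `BinaryDiffStack`, one binary motion map per frame pair.
  Motion map `t` (0-based) is aligned to raw frame `t + 1` — the label and
  centroid of the *later* frame, i.e. motion at the moment of frame arrival.

### 2. Grouped images

A single motion map cannot distinguish a grooming stroke from any other
twitch; the classifier therefore sees a temporal window: the stack of
`2w + 1` binary maps from `t − w` to `t + w`, labeled with frame `t`'s
label. Supported half-windows are 10–40 frames (0.33–1.33 s at 60 Hz); the
reference 3D-CNN uses `w = 40`. Windows are only formed where fully inside
the video — no padding, and evaluation is restricted to this valid range.

### 3. Classifiers

Two architectures are provided, built from scratch on an im2col + BLAS
convolution engine (no deep-learning framework is assumed):

* **3D-CNN** (primary): five convolution blocks of 3×3×3 kernels (blocks
  3–5 have two convolution layers), max pooling (1,2,2) in block 1 and
  (2,2,2) afterwards — early temporal resolution is preserved, following
  C3D practice — then three fully connected layers. ReLU activations,
  3-unit softmax head, 50% dropout after each pooling stage and between the
  first two dense layers. Default widths (64,128,256,256,512)/(512,256,3);
  learning rate 3e-5.
* **CRNN**: three 2D convolution blocks applied frame-wise, two LSTM layers,
  five dense layers, 20% dropout, learning rate 1e-4.

Training uses class-rebalanced epochs (by default 1000 not-grooming, 200
facial, 400 body windows drawn with replacement, batch 8), rotation
augmentation by multiples of 20° with nearest-neighbor resampling
(re-thresholded so inputs stay binary) plus independent horizontal/vertical
flips, categorical cross-entropy, and the AMSGrad optimizer (bias-corrected
moments, non-decreasing second-moment cap; β₁ = 0.9, β₂ = 0.999,
ε = 1e-7). One master seed fans out to weight init, epoch sampling,
augmentation and dropout, so a run is reproducible on one machine.
Prediction takes the softmax output as class probabilities and the argmax as
the hard label, ties toward the smaller class index.

### 4. Posterior filters

Raw per-frame predictions contain three implausible patterns, removed by
three rule-based filters applied serially, each in a single left-to-right
pass, with the video boundary counting as not-grooming:

1. **Sporadic** (≤ 4 frames): a short grooming run with not-grooming on both
   sides is erased.
2. **Interruption** (≤ 6 frames): a short not-grooming gap flanked by
   grooming on both sides is filled. If the flanks disagree, the longer
   flank (measured in the current, partially merged state) wins; ties go to
   the preceding run.
3. **Transition** (≤ 4 frames): a short run of one grooming class adjacent
   to the other class is absorbed into the neighbor; for a two-sided
   sandwich the longer neighbor wins, ties to the preceding. Runs touching
   the video boundary are exempt — they may be truncated bouts whose true
   length is unknown. The sweep merges as it goes: an absorbed run joins
   its neighbor and the merged run is re-examined, so alternating
   micro-patterns like `1,2,1` collapse deterministically in one pass.

The order matters and is deliberate: erasing a sporadic run can open a gap
that the interruption filter then closes. Filtering never increases the
bout count. Two conventions here are package decisions where the source
rules are silent: the disagreeing-flank resolution, and reading "grooming
run" as a *constant-class* run (so a facial run directly followed by a body
run is two runs; the transition filter, not the sporadic filter, is
responsible for that boundary). One edge case is worth knowing: an
annotation gap of exactly 6 frames is legal for ground truth yet would be
filled by filter 2; the synthetic generator therefore keeps inter-bout gaps
well above the threshold (≥ 20 frames, a realistic inter-bout interval).

### 5. Evaluation

Frame-level: 3×3 confusion matrix (rows = human, columns = predicted, order
body/face/not), per-class sensitivity and positive predictive rate as
percentages, overall accuracy, and macro F1 — the unweighted mean of the
per-class harmonic means of sensitivity and PPR *over all three classes
including not-grooming* (this three-class averaging is verified against
published benchmark matrices bundled under `inst/extdata/benchmarks/`, which
it reproduces to the printed decimal). A per-class F1 is 0 when its
denominator is 0; metrics whose defining sum is empty raise a typed
`ethogroom_undefined_metric` condition rather than returning NaN.

Bout-level: per-video bout counts per class and their Pearson correlation
between truth and prediction across videos.

Error taxonomy: every discrepant frame is exactly one of *oversight* (in a
true bout completely missed by the predictor), *false detection* (in a
predicted bout with no true grooming overlap), or *boundary* (everything
else, including class confusions inside overlapping bouts — a declared
convention; the taxonomy is grooming-centric).

## The synthetic world

The original recordings are not deposited, so the package ships a generator
that renders what the camera geometry implies: a bright ellipse ("mouse",
semi-axes 28×16 px in a 256×256 arena) on a dark background, with four
scripted behaviors:

* **still** — no motion (sensor noise only; 0.2% of pixels per frame get a
  random intensity);
* **locomote** — rigid translation at 3 px/frame with heading jitter,
  clipped at walls (with a warning);
* **facial grooming** — a small appendage blob oscillating at the anterior
  pole, amplitude 2 px, period 4 frames: fast, small, rostral;
* **body grooming** — modulation of the flank (semi-minor axis ± 6 px,
  period 10 frames): slower, larger, lateral.

These motion models are schematic, not biomechanical. Their single contract
is that motion statistics are class-separable and localized to the correct
body region — facial windows move strictly fewer pixels than body windows
(roughly 4 vs 30 at 32×32 after preprocessing, against a noise floor of
~1) — which is what makes a green scaled-down learning test meaningful. A
green test therefore establishes that the pipeline's machinery (frame
differencing, windowing, optimization, filtering, scoring) works end to
end; it does *not* establish performance on real fur, shadows, rearing, or
any behavior the generator cannot produce. Scripts are validated against
the annotation contract (bouts ≥ 5 frames, inter-bout gaps ≥ 6); generated
ground truth always passes `validate_annotation()`.

`corrupt_track()` inverts the three filters: it injects short isolated
runs, short in-bout gaps, and short class flips at bout edges, kept > 7
frames apart and placed so that bout fragments and flip remainders keep at
least 5 frames. Under those constraints a serial filter pass provably
restores the exact truth, which the test suite checks on a thousand random
tracks.

## Desk-scale configuration

The reference configuration (w = 40, 128×128 inputs, C3D widths, 3000
epochs) is GPU-scale; on one CPU this package trains a reduced model that
preserves the architecture family: 32×32 inputs, w = 10, widths
(8,16,32,32,64), dense (64,32,3). Three training choices differ from the
reference defaults, for reasons specific to desk scale:

* **learning rate 1.5e-3** (vs 3e-5): the reference budget is ~600k weight
  updates; desk scale has ~450. AMSGrad needs a proportionally larger step
  to converge at all in that budget.
* **dropout 0.1** (vs 0.5): with six dropout sites, a 0.5 rate on a
  32-times-smaller network prevents any learning within the desk budget
  (verified empirically — validation macro F1 stays at chance); 0.1 trains
  stably.
* **epoch plan 90/30/40** (vs the 5:1:2 reference ratio): the reference
  ratio mirrors the class abundance of the original recordings; the
  synthetic pool is roughly balanced, and starving the facial class to 1/8
  of each epoch makes its recall seed-dependent at this budget. The
  desk-scale run uses 25 epochs of 160 windows (about 500 weight updates).

All are ordinary training-configuration choices exposed through
`model_config()`/`epoch_plan()`; architecture defaults stay at the
reference values.

## Numerical choices and degenerate inputs

* Convolutions are "same"/stride-1; pooling windows are non-overlapping
  with floor division (a trailing odd frame is dropped).
* Binarization threshold applies as `>=`; binarization is idempotent.
* `argmax` ties break toward the smaller class index, deterministically.
* Empty videos, non-contiguous label CSVs, dimension mismatches and
  missing classes in a sampling pool all raise immediate, named errors.
* Weight init: He-scaled normal for convolution/dense (Glorot-ish for the
  softmax head), uniform for LSTM with forget-gate bias 1.
* All layer gradients (conv3d, pooling, dense, LSTM) are verified against
  central finite differences in the test suite to ~1e-6.

## Known limitations

* The renderer produces one rigid animal; no rearing, scratching,
  multi-animal scenes or photorealism.
* The CRNN is implemented and trainable but the scaled-down acceptance run
  exercises the 3D-CNN only, matching the reference architecture choice.
* Full-scale (w = 40, 128×128, C3D widths) training is out of CPU reach;
  the model builds and its geometry is tested, but no full-scale forward
  pass runs in the suite.
* Published full-scale metrics (e.g. 91.9%/81.3% sensitivity on real test
  videos) are not reproducible without the recordings; the bundled
  benchmark matrices verify the metric engine instead, and the synthetic
  recovery run stands in for end-to-end behavior.
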