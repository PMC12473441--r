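---
title: "sitsense: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sitsense: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

sitsense re-creates, end to end, the computational pipeline of a
smart-sensing chair: two 32x32 pressure mats (one on the seat, one on the
backrest, 1024 sensels each reporting integers 0-255) observe a sitter; a
classifier maps each dual-mat frame to one of 19 sitting postures; and a
scoring engine turns the stream of predicted postures into a sitting-quality
signal with actionable session analytics. Because pressure-mat recordings of
a single sitter are personal data and rarely published, the package is built
around a synthetic frame generator that plays the role of the data
collection stage, so every downstream component is fully testable.

## The synthetic frame generator

Each posture is a template: a set of 2D Gaussian pressure blobs per mat
(center, peak amplitude in raw units, spread in cells). A frame is rendered
by jittering every blob's center (sd 0.8 cells) and amplitude (sd 5%) —
emulating the small deliberate posture adjustments a participant makes
during an acquisition session — summing the blobs, adding truncated Gaussian
sensor noise (sd 4 raw units), rounding and clipping to [0, 255]. The empty
class SP0 has no blobs and a much smaller noise floor (sd 0.2), as an
unloaded mat reads essentially zero; its total pressure is orders of
magnitude below any seated frame, which is what the empty-frame filter
exploits.

The default templates are anatomically motivated: a neutral upright layout
(two ischial peaks, thigh ridges, scapular and lumbar zones) that each
posture deforms. The guiding design principle is *redundant signatures*:
every posture differs from its neighbours in several translation- and
rotation-tolerant cues at once — peak sharpness (edge sitting concentrates
pressure), number of contact islands (a figure-four ankle rest adds a shank
bar, an ankle dot and an abducted knee), amplitude balance (lateral leans
are an in-place load imbalance, not a translation), and backrest loading
profile (upper-back-only for an edge recline, full-column for a lounge).
This matters because the augmentation stage deliberately translates,
rotates and occludes frames: a class encoded only by *where* its mass sits
would be erased by the shift transform, whereas real postures reshape the
whole contact pattern. Left/right posture pairs (SP3/SP4, SP6/SP7,
SP10/SP11, SP14/SP15, SP16/SP17, SP18/SP19) are exact mirror images about
the vertical grid midline, a property the test suite asserts both on the
templates and on generated batches (mirrored centers of pressure, flipped
mean maps).

Coordinates are fixed once: row 0 is the rear of the seat and the top of
the backrest, column 0 is the sitter's left, indices are 0-based, and the
mirror axis is column 15.5.

The generator emulates: per-posture contact topographies, micro-movement
between frames, sensor noise, empty frames, and the acquisition cadence
(151 frames per posture over ~25 s, i.e. 2869 frames for 19 postures). It
does *not* emulate soft-tissue mechanics, inter-subject anthropometric
variation, sensor calibration drift, cross-talk between sensels, or
pressure saturation patterns of real hardware. Consequently, passing the
pipeline's accuracy surrogates demonstrates that the implementation is
correct and that the comparative experiment design is sound — not that any
particular accuracy would be obtained on real recordings.

## Preprocessing

Min-max normalization divides by the fixed sensor range (x/255) rather than
the per-dataset minimum and maximum, so the transform is identical at
training and deployment time and idempotence is detectable. The
empty-frame filter removes frames whose summed pressure over both mats
falls below 500 raw units; with the default generator an SP0 frame sums to
roughly 10-20 units and any seated frame to tens of thousands, so the
threshold separates them by orders of magnitude and its exact value is
uncritical (it is configurable).

## Augmentation

Five transforms, with defaults matching the conventional parameterization
of this augmentation family: Gaussian noise (level 0.5), shift (+-10 cells
on each axis), rotation (+-30 degrees), random erasing (10% of each mat),
and Simard-style elastic deformation (alpha 24, sigma 4).

Interpretation choices, where the family leaves room:

* **Noise level** has no canonical unit; it is interpreted as a multiple of
  the frame's nonzero-cell standard deviation, which makes the transform
  equally strong on raw and normalized data. The unit test checks the
  resulting perturbation against an independent Monte-Carlo oracle of the
  clipped, rounded noise model.
* **Composition**: each augmented variant applies every transform
  independently with probability 0.5 (re-drawing the inclusion mask until
  at least one fires), in the fixed order shift -> rotation -> elastic ->
  erase -> noise: geometric warps first, then occlusion, then sensor noise,
  mirroring the physical layering of the effects each transform emulates.
* **Random erasing** zeroes exactly `round(0.10 * 1024) = 102` cells per
  mat as one axis-aligned rectangle. Exact area with integer sides makes
  the aspect ratio discrete; a target aspect is drawn uniformly from
  [0.3, 3.3] and the admissible factor pair closest in log-aspect is used.
* **Elastic deformation** draws per-cell uniform displacement fields in
  [-1, 1], smooths them with a Gaussian of scale sigma (row-normalized
  separable operator, truncated at 4 sigma), scales by alpha and warps
  bilinearly with zero fill; with the defaults the displacement sd is about
  one cell, and total pressure is preserved to within 15%.

A policy seed makes the augmented dataset byte-reproducible. Default
expansion is 3 variants per original (2869 -> 11476 frames); an optional
`target_total` mode tops up to an arbitrary count by sampling originals
uniformly, for pipelines that need a non-integer expansion factor.

## Classifiers

All five model kinds sit behind one `train_model()` interface. Classical
models consume flattened normalized frames (2048 features); the CNN
consumes 2-channel 32x32 grids (seat and backrest stacked channel-wise,
preserving per-mat spatial alignment).

Hyperparameters are chosen by exhaustive grid search under stratified
5-fold cross-validated accuracy on the training split, with the validation
split reserved for the CNN's early stopping: decision-tree depths
{5, 10, 20, 30}; random-forest trees {50, 100, 200} x depths {10, 20, 30};
SVM cost C in {0.1, 1, 10}; k-NN neighbours {3, 5, 7, 9}.

Implementation notes that matter for reproducibility and speed:

* **SVM**: one-vs-one C-SVC with an RBF kernel of the common
  1/(p Var(X)) width. The Gram matrix over the training split is computed
  once with single-precision BLAS and reused across the entire C grid and
  all folds; the solver is the standard SMO algorithm (maximal-violating
  pair with second-order working-set selection, stopping when the KKT
  violation falls below 1e-3) operating directly on the precomputed
  kernel, so every iteration is a table lookup. General-purpose SVM
  packages either cannot consume a precomputed kernel or recompute
  2048-dimensional kernel entries on the fly, which is orders of
  magnitude slower at these problem sizes. The tests verify 100%
  prediction agreement with libsvm (e1071) across the whole C grid on an
  overlapping two-class problem and >= 95% agreement with both e1071 and
  kernlab on multiclass posture data.
* **k-NN**: distances are one matrix product per fold, shared across the
  whole k grid; the vote is deterministic (majority, ties resolved by the
  nearest neighbour within the tied classes). k = 1 predictions are
  checked against the reference implementation in the `class` package.
* **Random forest** (ranger): one full-depth forest of max(num_trees) per
  fold scores the entire grid. Trees grow greedily, so the top d levels of
  a depth-30 tree are exactly the depth-d tree; the in-bag samples are
  routed through each tree (compiled code) to recover node-level class
  majorities, giving the depth-truncated predictions, and the first k
  trees of a forest are themselves a valid k-tree forest. Both
  equivalences are asserted in the tests (the full-depth traversal
  reproduces ranger's own per-tree predictions exactly). The chosen cell
  is refit with ranger directly.
* **Decision tree** (rpart): fully grown within the depth cap (cp = 0,
  minimal split sizes); competing and surrogate split bookkeeping is
  disabled since no missing values exist. The depth grid is likewise
  scored by pruning one fully grown tree per fold back to each cap, which
  the tests verify to be prediction-identical to growing at that cap.
* Class weighting is deliberately not applied; classes are balanced by
  construction.

### The CNN

The network is the shallow two-block architecture: conv(32 filters, 3x3,
ReLU, 'same' padding) -> 2x2 max pool -> conv(64, 3x3, ReLU) -> 2x2 max
pool -> flatten (64 x 8 x 8 = 4096) -> dense(128, ReLU) -> dense(19,
softmax), trained with Adam on the cross-entropy loss. Kernel and pool
sizes, padding, batch size (32), learning rate (1e-3) and patience (5) are
the minimal standard completion of that layer list. Parameter counts are
asserted in the tests: 608 + 18,496 + 524,416 + 2,451 = 545,971.

The implementation is compiled (RcppArmadillo): im2col + single-precision
BLAS gemm per convolution, exact adjoint in the backward pass (verified by
central finite differences, and the forward pass against an independent
double-precision R implementation). All stochasticity — weight
initialization (He), batch shuffling — is drawn from R's RNG under the
model seed, so training is bit-reproducible on a given platform.

Early stopping runs its patience clock on validation loss (5 epochs
without a new minimum, up to 100 epochs). The *returned* weights are those
of the epoch with the best validation accuracy rather than the best
validation loss: on heavily augmented data the cross-entropy rises from
over-confident errors while accuracy is still improving, and accuracy is
the scoring metric used everywhere else in the comparison. Pooling stages
are skipped whenever the current spatial side is below 8, which lets the
same architecture run on the downsampled frames of the resolution study
(a 5x5 input flattens to 64 x 5 x 5 = 1600; at 10x10 only the first pool
fires).

## Evaluation and the resolution study

`evaluate_model()` reports the confusion matrix (rows = truth) and
accuracy, plus per-class precision/recall/F1 with macro averages over
classes with nonzero support; support-weighted averages are reported
alongside since macro-vs-weighted is a genuine choice (with balanced
classes they nearly coincide).

Bilinear downsampling uses cell-center alignment over the unit square:
target cell j of r samples the source at (j + 0.5) * 32 / r - 0.5, with
edge clamping. This convention makes r = 32 the exact identity and
preserves constants at every r; it is asserted against a brute-force
dense-resampling oracle. The resolution study augments at native
resolution first and then downsamples — emulating a lower-density sensor
observing the same physical scene — then re-splits with the shared seed
and retrains every model kind from scratch per resolution.

## Sitting-quality scoring

Each posture carries a Borg CR-10 biomechanical-risk score S (1 optimal …
10 most harmful; mirrored pairs share scores; the table is explicitly
provisional and user-editable). The quality score of a posture held T
minutes is

QS = 1 / (1 + S + D·T),

bounded in (0, 0.5], where the decay factor D implements static-sitting
penalties: upright context (default: SP1 only, configurable) is free for
30 minutes then decays at 0.005/min; any other posture is tolerated for 30
seconds (postural adjustment) then decays at 0.02/min. Boundary durations
belong to the zero-decay rule; thresholds are stored in minutes (30 and
0.5). T resets at each episode boundary — the penalty targets *maintaining*
a posture, and a posture change restarts the clock.

Episode segmentation collapses a timestamped prediction stream into
maximal constant-label runs with boundaries at sample midpoints. An
optional debounce merges runs shorter than `min_episode` into their longer
neighbour while accumulating per-label sample support, so the surviving
label is the per-sample majority of the merged span (a fully alternating
stream collapses to one episode of the majority label). Session summaries
report per-posture time shares, episode counts, the longest static episode
and the time-weighted mean QS (integrated at a 1 s step); the history
serializes canonically to a JSON array of {posture, start, end} records
with ISO-8601 timestamps, byte-stable under write -> read -> write.

## Reproducibility, sizes and numerical choices

Every stochastic component takes an explicit integer seed (generator,
augmentation policy, splits, model training); classical models are exactly
reproducible and the CNN bit-reproducible per platform (single-precision
BLAS order is fixed; across CPUs with different SIMD dispatch, accuracies
agree to well under half a percentage point). The pipeline manifest
records MD5 digests of every artifact so a rerun can be checked stage by
stage.

The test suite exercises the full study design at the sizes the package
itself uses as defaults: the headline five-model comparison runs at the
acquisition-scale dataset (151 frames/posture, augmented x4), while the
resolution study and the augmentation-benefit check run at reduced sizes
(60 and 40 frames/posture) chosen to keep the full suite comfortably
repeatable on a laptop CPU; these sizes are package defaults for those
checks, and the properties asserted (relative accuracies, monotonicity)
are size-stable in our experience.

Known limitations: the generator's realism bounds what accuracy numbers
mean (see above); the CNN has no GPU path and no convolution autotuning,
as the problem sizes do not warrant them; `rpart` deep trees on thousands
of near-continuous features remain the slowest classical grid; and the
Borg risk table encodes literature-derived defaults, not a clinical
calibration — downstream conclusions about a real sitter's health are out
of scope.
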