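---
title: "Temporal pooling and non-accidental shape sensitivity in a hierarchical model of recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal pooling and non-accidental shape sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Some shape properties survive changes of viewpoint — whether a contour is
straight or curved, whether an object's sides are parallel or tapered,
whether a cross-section is polygonal or rounded.  These *non-accidental
properties* (NAPs) contrast with *metric properties* (MPs) such as aspect
ratio, opening angle or overall size, which vary continuously as an object
rotates in depth.  Primate inferotemporal neurons, and human observers, are
more sensitive to NAP than to equally large (pixel-matched) MP changes.
Classical multiple-views hierarchies with bell-shaped template tuning are
not: a symmetric similarity measure in image space is modulated by an MP
step at least as much as by a pixel-matched NAP step.

`hmaxtp` implements a four-stage HMAX-style feedforward hierarchy together
with a minimal unsupervised extension — *temporal pooling* over short
object-transformation sequences — and the complete in-silico experiment
asking whether that extension is sufficient to produce NAP-over-MP
sensitivity and better viewpoint generalization.  The intuition: MP-like
appearance changes are exactly what an object produces while it rotates in
depth, so a unit that pools over a few hundred milliseconds of such a
transformation absorbs MP variation into its invariance range, while a
categorical NAP switch never occurs within a single smooth transformation
and remains an effective stimulus change.

## The model

Stage by stage, for an input image in $[0,1]$:

* **S1** — oriented Gabor filtering.  Kernels $g$ are zero-mean and
  unit-norm, at 4 orientations and 8 sizes (7–21 px; standard HMAX
  parameterization: $\sigma = 0.0036\,s^2 + 0.35\,s + 0.18$, $\lambda =
  \sigma/0.8$, aspect ratio 0.3, circular support).  The response is the
  absolute normalized cross-correlation
  $\bigl|\langle g, p\rangle\bigr| / \lVert p - \bar p\rVert$
  with the mean-centered local patch $p$, zeroed where the kernel window
  leaves the image.  Centering the patch norm makes the stage *exactly*
  invariant to affine intensity rescaling, and Cauchy–Schwarz bounds every
  response by 1.
* **C1** — max pooling over a local spatial neighborhood and over the two
  adjacent filter sizes of a scale band ($y = \max_{j \in \text{pool}}
  x_j$), subsampled.  Band parameters (pool 8/10/12/14, stride 4/5/6/7)
  follow the usual HMAX band table.
* **S2** — Gaussian radial-basis tuning to *imprinted* prototypes:
  $y = \exp(-\gamma \lVert \mathbf w - \mathbf x\rVert^2)$, where
  $\mathbf w$ is a stored C1 patch (all orientations, patch side $p \in
  \{4, 8, 12\}$ C1 units) and $\mathbf x$ the patch at the probed
  position/band.
* **C2** — a global max over all positions and bands per prototype.  The
  vector of C2 activities over $N$ feature columns is the model's
  population code for an image.

**Tuning sharpness.**  The sources for this architecture leave $\gamma$
free.  A fixed $\gamma$ shared across units makes the response scale hostage
to each prototype's energy: a unit whose imprinted patch happens to be weak
responds near 1 to *everything* (its squared distances are all small), and a
population of such units carries almost no stimulus information.  We
therefore make tuning *energy-relative*,
$\gamma_{\text{eff}} = \gamma_0 / \lVert \mathbf w \rVert^2$, i.e. the
distance is measured relative to the prototype's own energy.  Every unit
then responds $e^{-\gamma_0}$ to a blank input and shares one dynamic
range.  The default $\gamma_0 = 4$ puts the blank response near 0.02 and a
pattern at half the prototype's relative distance near $e^{-1}$.  The
perfect self-match property ($y = 1$ when an imprinted patch is
re-presented) holds for any $\gamma_0$.

## Temporal pooling

The extension changes only what a feature column contains.  In the original
model a column is one prototype replicated over positions and scales; here
a column holds `views_per_column = 5` prototypes, imprinted at the *same*
retinotopic position and band but at frames evenly spaced across a
`window_ms = 300` ms window of one video sequence (9 frames at 30 Hz).
The column response is the max over its views — the same pooling operation
the architecture already uses for position and scale, extended to temporally
contiguous views of the same feature.

Two design points deserve note:

* **Fixed retinotopic anchor.**  By default the patch location does not
  track the feature across the window.  The camera motion is slow relative
  to the C2 spatial pooling range, so the feature drifts within the
  invariance region of the column; fixing the anchor is the simplest
  reading of "different views of the same feature".  A greedy local-search
  tracking mode (`tracking = "local"` in `learn_columns()`) is available;
  at the default motion magnitudes the object drifts by less than one C1
  stride per window, the search never moves the anchor, and the two modes
  produce identical columns.
* **Matched baseline.**  The "original model" used in every comparison is
  the first view of each extended column, learned from the same seeds.
  With `views_per_column = 1` the extended code path reduces *bit-exactly*
  to the original model, so every original-vs-extended contrast isolates
  the effect of temporal pooling and nothing else.

Patches whose C1 standard deviation falls below 0.02 are redrawn during
learning: a near-constant patch (blank background) yields a prototype that
responds indiscriminately.

## Synthetic stimuli

The NAP/MP probe set cannot be redistributed, so the package re-creates its
*structure* parametrically: 36 families, each a shaded geon-style primitive
(brick, cylinder, cone, wedge) rendered orthographically on a mid-gray
background (canvas default 128×128; the experiment driver renders probes
at the video profile's frame scale so that the model sees probes and
training frames through one input scale), with

* four MP variants of strictly increasing amplitude along one continuous
  axis — opening angle, aspect ratio, or size (amplitudes 0.25, 0.5, 0.75,
  1 of the axis range); and
* one NAP variant flipping a categorical property — straight↔curved axis,
  parallel↔tapered sides, or polygonal↔curved cross-section.

Because the front end is contrast-normalized and edge-based, a categorical
switch must be a *contour* change to be comparable with the metric axes;
a switch whose pixel budget is spent on luminance mass would be nearly
invisible to the model while "using up" its calibrated distance.  Three
renderer choices follow from this: the axis bend is a mean-zero arc (the
whole axis curves and the ends swing sideways, as in a genuinely
curved-axis geon, rather than a mid-body bulge that leaves the ends
untouched); taper is an area-preserving tilt of the sides about
mid-height; and the polygonal/curved shading profiles share approximately
one mean luminance, so the cross-section switch reads out from gradient
shape, cap geometry and limb darkening at the contours.  With these
choices every switch's C1-space displacement per unit pixel distance sits
near parity (within ~0.8–1.1×) with the metric axes of its primitive
kind, which is what makes the pixel-space calibration meaningful one
representational stage up.

The NAP variant is then *calibrated in pixel space*: bisection on the
switch magnitude until the Euclidean pixel distance from the base is as
close as possible to, but not above, the MP2 distance (1% relative
tolerance).  A categorical floor — 25% of the largest MP amplitude —
prevents the calibration from shrinking the switch below a qualitative
change; a family that cannot satisfy the bound above the floor fails
loudly.  Both invariants (`d(base, NAP) <= d(base, MP2)`, `d(base, MPk)`
non-decreasing) are re-measured on every emitted family.

The allocation of the 36 families across primitive kinds and axes is a free
choice (the original enumeration is not published): each of the four kinds
contributes nine families spanning the three MP axes; kinds whose base is
already tapered take the curvature switch on a rotated base variant in
place of the taper switch.

## Synthetic video database

The transformation-sequence corpus is likewise regenerated, not
downloaded.  Each of 12 categories is a fixed composition of 1–3 shaded,
textured primitives stationed on a circle around a vertical axis.  A
sequence renders this object while the viewpoint changes smoothly:
in-depth rotation (30–90° over the clip) moves parts around the axis,
foreshortens their widths and reorders their occlusion; translation (2–6
px) and scaling (10–30%) are superimposed, plus per-frame Gaussian pose
jitter (sd 0.3 px/deg) mimicking handheld shake.  Backgrounds are seeded
smooth clutter fields, different for every sequence; initial viewpoint and
rotation magnitude also vary per sequence.  Frames are 64×64 grayscale at
30 Hz.

What this emulates is the *experimental logic* — one object identity per
category seen under many smooth view changes over clutter.  What it does
not emulate: real textures and lighting, perspective, camera blur,
self-shadowing, or the full appearance complexity of household objects.
Passing results therefore show that the mechanism behaves as claimed under
controlled view dynamics, not that it survives natural-video nuisance
structure.

Problem sizes: the default (`video_profile("full")`) matches the full study
conditions (12 × 20+ sequences, 3–5 s).  Routine runs and the shipped
analyses use `video_profile("desk")` — 12 × 5 sequences × 30 frames (1 s),
with every 3rd frame used for classifier features — chosen so the complete
pipeline (both generators, learning, both evaluations) runs in minutes on
one CPU.

## The two experiments

**Modulation analysis.**  All 216 stimulus images are encoded by both model
variants in one shared C2 pass.  Each unit contributes one comparison, at
its *preferred stimulus* — the family whose base image drives it most —
and only if that response exceeds half of the maximal attainable response
(0.5 on a scale where a blank input scores ~0.02 and a perfect match 1).
Probing at the preferred stimulus is what makes percent modulation
interpretable: away from it, a "variant" of a family that barely drives
the unit routinely excites it *more* than the base, and the statistic
collapses into noise around zero.  For each kept pair the percent
modulation $(r_\text{base} - r_\text{variant}) / r_\text{base} \times 100$
is computed for NAP and MP1–MP4; the headline comparison is NAP vs. MP2,
the level the NAP image was pixel-calibrated against.  Summary: mean
modulations, a paired two-sided Wilcoxon signed-rank test, and the
percentage of pairs with NAP > MP modulation.  (A per-unit percentile
rule and a plain absolute threshold are available as alternatives.)

The signed-rank test is implemented in the package with an exact tie-aware
null (generating-function convolution over midranks, $n \le 25$) and a
continuity- and tie-corrected normal approximation above; `stats::wilcox.test`
and exhaustive $2^n$ enumeration serve as independent oracles in the tests.

**Viewpoint generalization.**  A multi-class linear SVM (libsvm via
`e1071`) is trained on frame features of each model over 15 random splits.
Splits hold out whole sequences (20%, stratified by category), so test
frames come from viewpoint trajectories never seen in training; the cost
parameter is chosen per split by an inner 3-fold CV over training
sequences (grid $10^{-2}\ldots10^{2}$).  Accuracies are compared across
splits with the same paired signed-rank test, and a sequence-level
label-shuffling control verifies the chance level of $100/12 \approx
8.3\%$.

## Numerical choices and degenerate inputs

* S1 normalization guards: denominators below $10^{-10}$ (constant patch)
  give response 0; responses are clipped to 1 against rounding overshoot.
* C2 batch path uses the expansion $\lVert w-x\rVert^2 = \lVert w\rVert^2 +
  \lVert x\rVert^2 - 2\langle w,x\rangle$ with a floor at 0; the
  per-prototype path computes the distance directly.  Tests pin both to
  each other and to looped oracles.
* Percent modulation excludes base responses below $10^{-6}$ (never
  reached above the selection floor).
* A constant encoder (all modulations zero) or identical per-split
  accuracies yield a flagged degenerate comparison with $p = 1$ rather
  than an error.
* Zero-magnitude geometry (size or aspect ratio at 0) is rejected at
  `shape_spec()` validation, before rendering.
* Ties in the inner-CV cost selection resolve to the smaller cost.

## Limitations

* The renderer is a 2-D shaded-silhouette stand-in; NAP/MP axes are
  faithful in kind but not in pixel detail to the original probe images,
  so only the *structure* of the published results (orderings, signs),
  not their numerical values, is expected to reproduce.
* The size of the temporal-pooling effect is bounded by the geometry of
  the learned columns: pooling raises a unit's response only where the
  probe's displacement from the prototype lies along the column's
  view-spread manifold.  With smooth, low-texture synthetic objects the
  view spread within a 300 ms window is small relative to typical
  probe-match distances, so the extended model's NAP-over-MP preference
  and classification advantage, while consistently in the predicted
  direction, are far smaller than with rich natural video, and the paired
  tests over ~46 responsive units or 15 splits need not reach
  conventional significance at desk scale.
* In-depth rotation is emulated orthographically at the object-composition
  level; parts foreshorten and reorder but do not rotate about their own
  axes.
* Feature columns pool over one window of one sequence; cross-sequence
  pooling (the same feature re-encountered later) is not modeled.
* The desk-scale database (60 sequences) makes the SVM benchmark's split
  variance appreciable; the paired design across 15 splits is what gives
  the comparison its power.
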