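---
title: "Anatomical labeling of intracranial arteries: models, phantom and evaluation"
author: "arterylabel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anatomical labeling of intracranial arteries: models, phantom and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Time-of-flight MR angiography (TOF-MRA) renders flowing blood bright
without contrast agent, and is the workhorse modality for imaging the
intracranial arteries. Quantitative use of these scans — localizing a
stenosis to "the left M1", tracking a segment over time — requires two
steps after vessel segmentation: decomposing the vascular tree and
assigning each vessel voxel an anatomical label. This package implements a
complete labeling pipeline: from a raw intensity volume plus a binary
vessel mask to per-voxel and per-segment anatomical labels, with
evaluation at both levels. Because clinical angiography datasets are
rarely shareable, the package also ships a synthetic cerebrovascular
phantom generator, so every stage is exercisable (and is tested) without
any external data.

## Label constellations

Twenty-four artery segment classes are distinguished: ICA, ICA (Circle of
Willis segment), M1, M2 superior, M2 inferior, A1, A2, VA, PcomA, P1 and
P2 in dexter (`D-`) and sinister (`S-`) variants, plus the unpaired AcomA
and BA. With background (index 0) and non-annotated vessel (index 1) this
is the **detailed** constellation of 26 classes. The **aggregated**
constellation groups them into 11 clinically meaningful units — per side:
ICA (including its CoW segment), MCA (M1 + both M2s), ACA (A1 + A2, with
AcomA joining the left group), posterior circulation (PcomA + P1 + P2) —
plus BA and the two VAs, for 13 classes in total. Class order is a package
convention (the constellations themselves do not prescribe one):
background, non-annotated, then artery classes in reading order with
dexter before sinister. Short codes (`D-M2-sup`, `ACOM`, ...) are fixed in
one table and used in all serialized output.

Aggregation is a voxel-wise total map over detailed indices that fixes the
two auxiliary classes; coarsening can only merge error modes, so voxel
accuracy after aggregating both prediction and ground truth is never below
the detailed accuracy — one of the property tests.

## The phantom

`sample_subject()` draws one synthetic subject from a fixed template tree
of all 24 segments with anatomically plausible topology: ICA rising into
its CoW segment and splitting into M1 (lateral, then M2 sup/inf) and A1
(medial, meeting AcomA and A2 at the midline); both VAs merging into the
BA, splitting into P1s and on into P2s; PcomA bridging the ICA CoW segment
and the P1/P2 junction. Paired segments are exact mirror images across the
mid-sagittal plane in the template. Per subject:

- control points are jittered (Gaussian, default sd 0.8 mm) — shared
  junction points move together so the tree stays connected — and radii
  are scaled per segment (log-normal, sd 0.08);
- with probability `missing_prob` (default 0.8, matching the high reported
  prevalence of missing arterial segments in steno-occlusive disease
  cohorts) a random nonempty subset of the droppable segments — by default
  the commonly hypoplastic D/S-PcomA, D/S-A1, D/S-P1 and AcomA — is
  removed, which also produces disconnected trees, as in real pathology;
- with probability `nonannotated_prob` (default 0.25) a terminal segment
  (M2s, A2, P2) grows a short distal twig labeled *non-annotated vessel*,
  exercising that class without breaking per-segment label homogeneity;
- tubes are rasterized on an anisotropic grid (desk default 96 x 96 x 48
  voxels at 0.6 x 0.6 x 0.7 mm; a full scanner-matrix configuration is
  available through the same arguments): a voxel is vessel when its center
  lies within the tube radius of the nearest polyline point, and overlap
  ties go to the most interior tube — simple enough to check by brute
  force;
- the image is a constant tissue level (100) multiplied by a smooth
  low-frequency bias field (coarse Gaussian grid, trilinearly interpolated,
  amplitude 0.2 — emulating raw scans without non-uniformity correction),
  with vessel voxels at a bright flow-like level (300) and additive
  Gaussian noise (sd 20). At these defaults vessel and background
  intensities are separated by well over two background standard
  deviations, which the labeling task assumes.

What the phantom does **not** emulate: brain tissue structure (the
background is homogeneous apart from bias and noise), flow artifacts,
partial-volume intensity gradients at vessel walls, aneurysms or
stenoses, and anatomical variants beyond segment dropout (no fetal-type
PCA as a distinct class, no M1 trifurcations). Passing the end-to-end
tests therefore demonstrates that the pipeline machinery — geometry,
patch plumbing, optimization, washing, metrics — recovers labels under
realistic geometry, noise, bias and missing segments; it does not certify
clinical-grade accuracy on real TOF-MRA.

Cohorts (`generate_cohort()`) draw per-subject seeds without replacement
under one base seed and carry a two-level cohort tag (emulating a
two-study design, 72 + 170 = 242 at study scale) used for stratified
splitting.

## Geometry: centerlines and segments

`skeletonize()` thins the mask to a one-voxel-thin centerline by
sequential removal of *simple points* — voxels whose deletion provably
preserves topology, characterized by one 26-connected foreground component
in the punctured neighborhood and one 6-connected background component
among the 6/18-neighbors. Removal proceeds in increasing order of the
(anisotropic, spacing-aware) Euclidean distance transform so the curve
stays medial, and voxels with a single foreground neighbor (curve
endpoints) are protected. Each surviving voxel stores the distance-map
value as its radius in mm — the "vessel-specific" input channel of the
classifier. Free-ended runs shorter than 3 voxels are pruned as thinning
artifacts (configurable). Thinning preserves the number of connected
components, which is asserted on phantoms.

`extract_segments()` calls a voxel with three or more centerline neighbors
(26-connectivity) a junction voxel; maximal clusters of junction voxels
form one bifurcation node each, since thinning can emit adjacent degree-3
voxels. Removing the clusters leaves runs — the anatomical segments
between bifurcations. Every node voxel is then attached to its adjacent
run of lowest id, so the runs exactly partition the centerline (asserted
as a property test). Disconnected components simply yield separate
segments, keeping the decomposition well-defined on pathologically
disconnected trees. `segment_id_volume()` extends segment ids from the
centerline to the full lumen by nearest-centerline assignment in mm
metric. Whether washing should operate on centerline voxels only or the
full lumen is genuinely open; we label and wash the full lumen because
predictions cover all vessel voxels, and evaluate over the same extent.

## Patch extraction and training data

Subjects are split by `make_folds()` into k stratified folds (default 4):
within each cohort stratum, a seeded shuffle assigns `floor(n/k)` subjects
to each test fold; the `n mod k` leftovers join every training set and no
test set — with 72 + 170 subjects and k = 4 this yields the 182/60
train/test arithmetic, and it is the only reading that reconciles 4 x 60
test subjects with a 242-subject cohort.

For each segment, up to 8 centerline voxels are sampled without
replacement (all of them for shorter segments), once per dataset build.
Around each center two concentric patches are cut: the main patch
(desk-scale default 32 x 32 x 16 voxels — the study-scale analog would be
128 x 128 x 64) and a context patch twice that per axis, both with two
channels (image intensity, centerline radius) and zero-padded beyond the
volume border; the ground-truth patch matches the main size. Channels are
min-max scaled to [0, 1] with *global training-fold statistics* (not
per-image — fold-global is the natural reading of training-set statistics,
and the choice is localized in `fit_scaling()` so it can be flipped);
out-of-range test values clip to [0, 1].

Optional augmentation (`augment_rotations()`) inflates the training set by
a factor of 3: originals are kept and each patch gains two copies rotated
about a uniformly random axis by an angle uniform in [-60, +60] degrees,
in physical mm space. The image channel is interpolated trilinearly,
vessel and label channels nearest-neighbor — our choice, standard practice
that cannot invent labels (a property test).

## The classifier

`brave_net()` builds a multi-scale encoder-decoder: a standard 3-D U-Net
encoder over the main patch and a parallel *context path* — an encoder of
identical layout whose input is the context patch average-pooled by 2 at
entry, so it covers twice the field of view at half resolution. The two
bottlenecks are concatenated and fused by a convolution; the decoder
up-samples with kernel-2 stride-2 transposed convolutions, concatenates
the main-encoder skip at each level, and ends in a 1x1x1 convolution and
per-voxel softmax. Where the published architecture description is silent
we use 3x3x3 kernels, two convolutions per level, 2x max-pooling, and
per-channel instance normalization (learnable scale and shift) between
each convolution and its ReLU — standard encoder-decoder conventions, all
exposed in the configuration. Instance norm is preferred over batch norm
because its statistics are per sample, so inference is deterministic and
independent of batch composition; without any normalization layer the
network converges an order of magnitude more slowly on this task.
Deep supervision adds auxiliary softmax heads at intermediate decoder
levels, trained against stride-subsampled ground truth with weights 0.5
per level halving (a common convention). Regularization is an L2 penalty
(1e-3) on all convolution weights — no dropout. Weights are Glorot-uniform
initialized under a seed (normalization scales start at 1, all shifts at
0); training minimizes categorical cross-entropy (main + weighted
auxiliary) plus the L2 term with Adam at initial learning rate 1e-3.
Batch size, epoch count and any learning-rate decay are not prescribed by
the architecture and are surfaced in the training configuration; the
backward pass is verified against finite differences and training is
bit-reproducible given seeds.

Two further training options address the extreme class imbalance of
vessel volumes (arteries are a few percent of patch voxels, and plain
cross-entropy spends its first epochs collapsed onto background):

- `init_head_bias()` sets the softmax-head biases to log class priors, so
  the untrained network starts at the prior instead of having to learn it;
  convolution weights remain Glorot uniform.
- `train_network(class_weights = ...)` optionally weights the per-voxel
  cross-entropy by inverse (`"balanced"`) or inverse-square-root
  (`"sqrt"`) class frequency, normalized to mean 1. The default is plain
  unweighted cross-entropy; the desk-scale experiments enable both
  options, which is reported with their results.

Input dims are constrained divisible by 2^depth so the output grid equals
the ground-truth grid exactly; the off-by-one output-slice workaround that
mismatched dims would otherwise need never arises.

The engine is written in single-precision C++ (im2col + BLAS): training is
memory-bandwidth bound and voxel classification is insensitive to
precision beyond float.

`rf_baseline()` is the classical comparison: a random forest (default 50
trees) on per-voxel features. The feature set is our choice (the baseline
concept does not fix one): image intensity, vessel-channel radius, and
voxel coordinates normalized to [0, 1] per axis — a minimal
"image + vessel" reading plus location. Voxels are sampled class-balanced
per subject.

## Inference and segment washing

`predict_volume()` tiles the volume with main-size patches (stride
defaults to the patch size — non-overlapping, for speed; any smaller
stride averages overlapping softmax contributions and renormalizes) and
stitches the per-tile softmax into a whole-volume probability field.

`segment_wash()` then enforces anatomical consistency: per segment id, the
softmax scores of all its voxels are summed per class and every voxel of
the segment receives the argmax of the sums — equivalently the label of
highest average likelihood, so sum vs. mean is immaterial to the argmax.
Ties break to the lowest class index, voxels outside every segment keep
their per-voxel argmax. Washing output is segment-homogeneous and
idempotent, and is tested against a brute-force sum-and-argmax oracle on
random instances.

## Evaluation

Per class, F1 = 2TP/(2TP + FP + FN) (defined as 0 when the denominator is
0 — an unpredicted but present class scores 0, not NA) and recall =
TP/(TP + FN). Background and non-annotated are excluded from the
calculation in both directions: voxels (or segments) whose ground truth
is an excluded class contribute nothing — anatomical labeling is defined
over the annotated vasculature, and a prediction on a deliberately
unannotated vessel is unverifiable rather than wrong (were such voxels
counted, every distal artery class would be systematically penalized in
exactly the patients with unannotated vessels, i.e., most of them) —
while predicting an excluded class on an annotated voxel still counts as
a miss of the true class. Macro F1 (mF1) and balanced class accuracy
(bAcc) are unweighted means over *included* classes
restricted to classes with ground-truth support:
with missing-segment subjects some classes are absent from a fold, their
recall is undefined, and excluding them (while reporting the skipped
count) is our documented resolution of that ambiguity. Qualitative bands
for per-class F1: excellent (> 0.9), good (> 0.75), moderate (> 0.6), poor
(otherwise); boundaries are half-open so exactly 0.6 is poor.

Voxel-wise scores are computed on whole-volume labels; segment-wise scores
collapse each segment to a single (ground truth, prediction) pair — they
require washed predictions and are size-unbiased by construction.
`crossfold_summary()` reports mean and sample standard deviation across
folds plus per-class means.

## Numerical choices and degenerate inputs

- Ties: argmax ties (voxel and segment level) break to the lowest class
  index; majority ground-truth ties likewise.
- Segments with no ground-truth overlap fall back to the non-annotated
  class; mixed segments are labeled by majority and reported.
- Empty masks yield empty centerlines and empty segment tables; an empty
  table with a non-empty mask is an error (as is a degenerate scaling
  channel, a non-binary mask, or a patch center outside the grid).
- All randomness (phantom, folds, sampling, augmentation, initialization,
  shuffling) flows through explicit integer seeds; identical seeds give
  bit-identical artifacts.

## Problem sizes used by the test suite

The packaged experiments run at desk scale, chosen once as a realistic
miniature of the study conditions: 96 x 96 x 48 voxel grids at
0.6 x 0.6 x 0.7 mm, 20-subject cohorts (16 train / 4 test), main patches
32 x 32 x 16 with 64 x 64 x 32 context, base filters 4 and depth 3, 3
patch centers per segment for training, batch size 8, 8 epochs at
learning rate 2e-3 with inverse-square-root class weighting and log-prior
head initialization, and half-stride overlap-averaged tiling at
evaluation. Input-channel and augmentation comparisons run at a further
reduced scale (5 training / 2 test subjects, 2 centers per segment, 3
epochs, two seeds) so that one desk session covers all model variants;
at that scale the comparisons probe direction, not magnitude. The
full-scale settings of the study design (312 x 384 x 127 grids,
128 x 128 x 64 patches, base filters 16, 8 centers per segment) remain
available through the same configuration arguments.

One comparison deserves an explicit caveat: on clinical angiography,
image-only input is reported far weaker than vessel-only input, because
raw clinical intensities are ambiguous without a vessel prior. The
phantom's background is clean by design (no brain anatomy), so its image
channel alone carries nearly the full vessel geometry and an image-only
model can match or beat a vessel-only model here. The image-vs-vessel
ordering is therefore a property of clinical data that this phantom does
not reproduce — a known limitation of the synthetic cohort, not of the
pipeline.

## Known limitations

- The phantom's homogeneous background under-represents how much real
  tissue context contributes to labeling; conversely its stereotyped tree
  makes localization easier than in patients with severe deformation.
- The thinning-based bifurcation detector can split or merge runs near
  complex junction clusters; segment counts are therefore asserted with a
  small tolerance rather than exactly.
- The random-forest baseline's features include normalized coordinates,
  which on the phantom's consistent geometry is a stronger cue than it
  would be on unregistered clinical scans.
- No statistical comparison between models is implemented, and no
  graph-model relabeling (CRF/GNN) on top of washing.
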