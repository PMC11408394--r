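---
title: "Segmenting the female pelvis in 3D MRI: model, losses and evaluation"
author: "PelvicSeg3D"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting the female pelvis in 3D MRI: model, losses and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PelvicSeg3D)
```

## The problem

Radiation therapy planning for cervical cancer requires contouring the
tumour and the organs at risk (bladder, rectum) on pelvic MRI. Manual
contouring is slow and inter-observer variability is high, while automatic
segmentation is hampered by small labelled datasets and very large
anatomical variation: in clinical cohorts the bladder spans roughly 30 to
720 cm^3, the gross tumour volume (GTV) 11 to 712 cm^3 and the rectum 19
to 213 cm^3. Because the GTV often encroaches on the cervix and uterus,
these three structures are merged into a single training label, the CGU,
which forms the bulk of the clinical target volume. The package segments
four channels: background, bladder, CGU and rectum.

`PelvicSeg3D` implements the full pipeline — volumetric NIfTI I/O,
preprocessing, a bounding-box-aware loss, three 3D network architectures
with a built-in CPU training engine, synthetic phantom generation, random
augmentation, patient-level cross-validation and evaluation — so that the
method can be exercised end-to-end without access to clinical data.

## The positional Dice loss

The Dice loss compares a one-hot ground truth $p$ against the softmax
probability field $q$:

$$D_{loss} = 1 - \frac{2\sum p\,q}{\sum p^2 + \sum q^2},$$

with the sums running jointly over voxels and channels (the background
channel can be excluded; the training default excludes it so the organ
channels dominate the gradient). By convention $D_{loss} = 0$ when both
volumes are empty over the summed region: an absent structure predicted
absent is a perfect prediction.

Pelvic organs are single continuous volumes in a predictable location, so
spatially displaced false positives ("segmentation noise") can be
penalised through their effect on the per-axis bounding extents. For each
axis the mask is projected by summing over the two orthogonal axes and
binarising ($S(X) > 0 \to 1$); the extent of the union of truth and
prediction along axis $x$ is $R_x$. The bounding-box loss of a channel is

$$B_{loss} = \frac{|S_x(p) - S_x(q)| + |S_y(p) - S_y(q)| + |S_z(p) - S_z(q)|}
                   {R_x + R_y + R_z},$$

where $|S(p) - S(q)|$ is the elementwise L1 distance between the profiles
— the number of axis positions covered by exactly one of the two masks.
We read the numerator this way rather than as a difference of counts
because it upper-bounds the count difference and still penalises
displaced-but-equal-extent predictions; the two readings coincide on
nested masks. $B_{loss}$ is computed per foreground channel and averaged
— bounding boxes are per-structure by construction, and averaging rather
than summing keeps the value in $[0,1]$ regardless of channel count. The
positional Dice loss is the sum

$$PDL = D_{loss} + B_{loss} \in [0, 2].$$

```{r pdl-example}
shape <- c(8L, 8L, 8L)
mk <- function(xr) {
  m <- array(0, dim = c(shape, 2L))
  m[, , , 2][xr, 1:4, 1:4] <- 1
  m[, , , 1] <- 1 - m[, , , 2]
  m
}
positionalDiceLoss(mk(1:4), mk(1:2), excludeBackground = TRUE)
```

**Differentiable surrogate.** The binarisation $S(X)>0\to 1$ has no
gradient, so during training the soft profile $\min(\sum, 1)$ is used: it
equals the crisp profile on binary input and has a subgradient almost
everywhere. A consequence worth knowing: early in training, when the
probability mass is diffuse, the soft profiles saturate at 1 and the
bounding-box term contributes little gradient; it becomes active as the
prediction sharpens. The 0/0 cases (empty truth and prediction) are
defined as loss 0 for both terms.

The Dice + cross-entropy baseline (`dce`) adds the mean voxelwise
categorical cross-entropy with probabilities clipped at `1e-7`.

## Network architectures

All three networks share an encoder-decoder backbone over four
resolutions with base filter count $F$ (filters $F, 2F, 4F, 8F$):

* *standard block*: 3D convolution (kernel 3), instance normalisation,
  dropout 0.2, ReLU;
* downsampling by stride-2 convolution rather than max-pooling;
* per reconstruction stage: stride-2 transposed convolution, an
  *additive* skip join from the matching encoder level, then two standard
  blocks;
* a kernel-1 head with softmax giving per-voxel class probabilities.

**M-Net** adds a second input: a per-case binary class-label vector with
one entry per output channel, broadcast to a constant volume. The vector
encodes gross anatomical state — entry 2 is 1 iff the bladder's maximum
inscribed radius exceeds 17 mm, entry 3 is 1 iff the GTV volume exceeds
4 times the uterus volume (both strict; background and rectum entries are
always 0). A typical inflated-bladder/large-tumour case is `[0, 1, 1, 0]`.
The branch applies one convolution per encoder resolution with 2x average
pooling between resolutions, and its output is added to the encoder
feature map of matching shape — acting as a learned, class-conditioned
mask on the encoder. Injection happens after each level's convolution
blocks, immediately before the next downsampling (the precise insertion
point is an open design choice; injecting here keeps the skip
connections class-conditioned as well).

**DM-Net** additionally inserts, between the encoder and the decoder,
three dilated convolution blocks (instance norm + Leaky-ReLU with slope
0.01, no dropout) with equal dilation rates and descending filter counts
$4F, 2F, F$, followed by one standard block that restores the bottleneck
width. Equal dilation with descending filters enlarges the receptive
field while limiting gridding artefacts. The dilation rate is 2 (the
rate itself is a free choice; the blocks only need equal rates). The
dilated stack sits between the full encoder and the decoder — it is
appended rather than replacing the deepest encoder blocks, which
preserves the parameter-count ordering DM-Net > M-Net > U-Net.

Other defaulted choices: two standard blocks per encoder level, He
(fan-in) weight initialisation, instance normalisation with learned
affine terms, transposed convolutions with kernel 2. Inputs must have
extents divisible by $2^{levels-1} = 8$.

**Transfer learning.** `transferWeights()` copies every parameter tensor
whose name and shape match from a source network (e.g. trained on
male-pelvis MRI with 5 output classes) into a fresh target network; the
head — and any other unmatched tensor — keeps its fresh initialisation,
and a manifest records the decision per tensor.

**The engine.** Networks are executed by a compact built-in 3D conv-net
engine (im2col + GEMM convolutions in single precision, exact analytic
backward passes, Adam). It is deliberately minimal — batch size 1, CPU
only, deterministic given the R RNG — which is sufficient for the
desk-scale protocol below; the engine's primitives are finite-difference
tested.

## Preprocessing and post-processing

Cases are resampled to a working grid (default 256 x 256 x 64 voxels at
1.64 x 1.64 x 3 mm) centred on the input's physical centre — images
trilinearly, labels by nearest neighbour on the index map. Intensities
are z-scored per volume (some normalisation is required for stable
training; none is prescribed, so the simplest volume-wise form is used).
Bias-field correction is a pluggable hook: `n4Corrector()` delegates to
an external N4 implementation through a `python` interpreter, and the
hook degrades to the identity with a warning when no corrector is
available or it fails.

"Maximum radius of the bladder" is interpreted as the largest
inscribed-sphere radius, computed from an anisotropic Euclidean distance
transform (a centroid-to-surface or half-diameter reading would be
ill-defined for very irregular bladders). "GTV size" is interpreted as
physical volume. Both thresholds are strict, reading "above" and "larger
than" literally, and both are configurable in `preprocessConfig()`.

Predicted label maps can be post-processed by retaining, per structure,
only the largest 26-connected component (26-connectivity is the standard
choice for 3D blob retention and is least prone to splitting thin
structures; size ties — which are vanishingly rare — go to the component
encountered first in column-major scan order).

## Synthetic phantoms

The generator emulates the geometry and contrast of the clinical data,
not its physics: an ellipsoidal bladder (bright, fluid-like), a CGU
complex built from overlapping uterus/cervix/GTV ellipsoids
(intermediate intensity), and a curved tubular rectum (dark), placed
anterior-to-posterior in a field of view of 420 x 420 x 192 mm, with a
smooth multiplicative polynomial bias field (order 2, amplitude 0.2) and
additive Gaussian noise (SD 10 on a background of 100). Requested
structure volumes are met to within 5% by calibrating each structure's
size parameter against its rasterized voxel count, so populations can
span the full clinical ranges (`variation = "paper-range"`) or stay
within ±20% of the population medians (`variation = "small"`; bladder
200, GTV 111.7, rectum 57.95 cm^3). Repeat series of a patient jitter
the patient's anatomy by ±8%.

What the phantoms do *not* model: MR physics (no k-space, relaxometry or
coil profiles), soft-tissue texture, organ deformation by neighbouring
structures, multi-component or perforated organs, and the outlier
anatomy (e.g. an unusually large endometrium) that motivates excluding
cases from clinical test sets. Passing the phantom experiments therefore
demonstrates that the pipeline, losses and architectures are implemented
coherently and can learn — not that clinical-grade accuracy would be
reached on real MRI.

## Augmentation

`augmentDataset()` applies, per copy, a random non-empty subset of
elastic deformation (Gaussian displacements of SD 4 mm on a 32 mm
control grid), affine warping (scales 0.9–1.1, shears ±0.05), rotation
about one random grid axis (±15°) and integer voxel shifts (±10 in-plane,
±3 through-plane). The choice of operations is part of the training protocol; their
magnitudes are free parameters, and these defaults are anatomy-preserving and
config-exposed. The original series is kept alongside its 9 augmented
copies — 42 training series then yield 420, the accounting that a
training set of 41–42 inputs expands to 410–420 series. Copies that split a structure into several
components are redrawn.

## Cross-validation, evaluation and statistics

`makeFolds()` shuffles patients by seed and deals them round-robin into
k folds (sizes differ by at most one; 23 patients at k = 5 gives
5/5/5/4/4), keeping all series of a patient together. Outlier-flagged
series are excluded from every test list but remain available for
training. Training follows the fixed protocol: Adam, learning rate
0.001, batch size 1, a fixed epoch budget, no early stopping and no
validation split.

Evaluation hardens the softmax output by argmax (ties to the lowest
channel), optionally applies largest-component retention, and computes
per structure: DSC; the full (100th percentile) Hausdorff distance
between surface voxel centres in mm, honouring anisotropic spacing; and
the symmetric mean surface distance. Surfaces are mask voxels with a
face-adjacent background neighbour (volume borders count as background).
Distances use an exact anisotropic Felzenszwalb distance transform.
Approaches are compared per structure and metric with a two-sided paired
Wilcoxon signed-rank test (zero differences dropped; exact distribution
up to n = 25 without ties, otherwise a tie-corrected normal
approximation), flagged at α = 0.05 without multiplicity correction.

## Desk-scale problem sizes

The package's rehearsal experiment (`runExperiment()`, also recomputed by
`scripts/acceptance.R`) uses 8 patients x 5 series of `small`-variation
phantoms on a 48 x 48 x 16 grid at 8.75 x 8.75 x 12 mm (the clinical
field of view at one-fifth resolution, keeping extents divisible by 8),
2-fold patient-level cross-validation, base filters F = 8 and a 12-epoch
budget — about 240 optimisation steps per model and fold, chosen as the
point where the training curves of both approaches have clearly entered
their fast-descent phase on this task. At this scale DM-Net+PDL reaches
mean held-out bladder DSC well above 0.75. The coarse grid cannot
resolve the extreme ends of the clinical volume ranges (a 11 cm^3 GTV is
~12 voxels), which is why the rehearsal uses the `small` variation;
`paper-range` populations are exercised on the default 64 x 64 x 32
phantom grid instead.

## Known limitations

* Batch size is fixed at 1; there is no GPU path, no mixed precision
  beyond fp32 convolutions, and no gradient checkpointing — full-scale
  256 x 256 x 64 training is supported by configuration but not by the
  compute budget of a desk machine.
* The bounding-box surrogate provides no gradient through saturated
  profiles; alternatives (e.g. smooth maxima) were not explored.
* The phantom rectum at coarse grids is only 1–2 voxels thick per slice;
  rectum scores at 48 x 48 x 16 are correspondingly noisy.
* Orientation metadata is used as stored; no reorientation to an
  anatomical frame is attempted, and DICOM/RT-STRUCT ingestion is out of
  scope.
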