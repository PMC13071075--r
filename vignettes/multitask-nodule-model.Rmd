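---
title: "Joint segmentation and malignancy classification of pulmonary nodules: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint segmentation and malignancy classification of pulmonary nodules: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Pulmonary nodules on chest CT must be both delineated (voxel-wise
segmentation, for volumetry and follow-up) and characterized (benign versus
malignant). The two tasks share almost all of their visual evidence — size,
boundary spiculation, contrast against parenchyma — which motivates a single
multi-task network with a shared encoder, a decoder for segmentation, and a
light classification branch reading the encoder's high-level features.

`nodulemt` implements such a network end to end in R: a 3-D residual
encoder–decoder with attention-gated skip connections, multi-scale grouped
convolutions in the decoder, a squeeze-excite-gated classification branch,
the compound Dice + cross-entropy objective, the CT preprocessing chain, a
seven-metric evaluation harness, and a synthetic nodule-phantom generator so
that every part of the pipeline can be exercised on a desktop CPU without
any external imaging data.

## Model

**Encoder.** A 3-D adaptation of an 18-layer residual network: a 7³ stride-2
stem plus stride-2 max pooling, then four stages of two basic residual
blocks each, with stage widths 64/128/256/512 by default, producing feature
maps at 1/4, 1/8, 1/16 and 1/32 of the input resolution. We use group
normalization throughout rather than batch normalization: training runs at
batch size 4 on CPU, where batch statistics are unreliable, and the
attention gate below already prescribes group normalization internally.

**Attention-gated skips (GSA).** Each skip connection passes through a
global semantic attention gate before fusion. Two 1³ convolutional
projections (conv → group norm → ReLU) produce response maps; each is
squashed by a sigmoid and reduced to a per-channel descriptor — global
*average* pooling for the first, global *max* pooling for the second. The
skip feature is reweighted channel-wise by both descriptors
(multiplicative gating) and refined by a 3³ conv + norm + ReLU. With zero
projection weights both descriptors equal sigmoid(0) = 0.5, so the
pre-refinement output is exactly 0.25·x — a property the test suite pins
down. We deliberately keep the projections at full channel width: the
descriptors must have C channels to reweight x directly after the
sigmoid→pool reduction, which rules out a compressed bottleneck at that
point.

**Decoder and MSConv.** Each decoder stage trilinearly upsamples the deeper
feature, concatenates it with the gated skip, and fuses by a 3³ conv
(concatenation-then-convolution, the U-Net default; upsampling by
interpolation + convolution avoids the checkerboard artifacts of transposed
convolution). The fused feature then passes through a multi-scale grouped
convolution block:

$$Y = \mathrm{Conv}^{(g)}_{res}(X) + \sum_{k\in\{1,3,5\}} \mathrm{Conv}^{(g)}_{k}(X),$$

four parallel grouped convolutions (kernels 1³, 3³, 5³ and a residual 3³)
with "same" padding so the element-wise sum is well defined. All branches
share the group number

$$g = \max\{\,g : g \le \min(\lfloor C_{in}/2\rfloor,\ C_{out}),\ g \mid C_{out}\,\},$$

with g = 1 when the input has a single channel. The branches are plain
(dilation 1) convolutions by default; a `dilation` option exposes the
dilated reading of the same three-branch design, since enlarged receptive
fields can be obtained either way.

**Dual spatial attention (DSA).** In the two deepest decoder stages
(counting from the bottleneck outward), channel-wise average pooling and
channel-wise max pooling each give a one-channel spatial map; each map is
convolved (kernel 7³ by default) and passed through a sigmoid, and the two
rescaled copies of the feature are summed. The average branch emphasizes
consensus activations (nodule core), the max branch peak activations
(boundary); summation is the symmetric way to combine the two rescalings.
The shallowest decoder stage, close to full resolution, is left without DSA.

**Classification branch.** Encoder stages 3 and 4 and the first fused
decoder feature (the early-fusion map of the deepest decoder stage, taken
after the fusion convolution and before the MSConv/DSA refinement) each pass
through their own squeeze-excite channel attention (reduction ratio 4),
global average pooling, concatenation, one hidden fully connected layer, and
a 2-logit output. CA weights are sigmoid-bounded in (0,1), so each stream is
attenuated, never amplified.

**Ablation switches.** `network_config(active_blocks = ...)` activates any
subset of {CA, GSA, DSA, MSConv}; an inactive block is the identity, so
parameter counts are strictly monotone from the baseline multi-task topology
to the full model, and `with_classifier = FALSE` gives the pure
segmentation network.

## Objective

With voxel softmax probabilities $p_{i,c}$ and one-hot ground truth
$y_{i,c}$ over $C = 2$ classes:

$$L_{CE} = -\tfrac1N \sum_{i=1}^{N}\sum_{c=1}^{C} y_{i,c}\log p_{i,c},
\qquad
L_{Dice} = 1 - \frac{2\sum_i p_{i,1}y_{i,1} + \epsilon}
                    {\sum_i p_{i,1} + \sum_i y_{i,1} + \epsilon},$$

with $\epsilon = 10^{-5}$, both computed per sample and averaged over the
batch (the Dice ratio is defined for one volume; per-sample averaging
matches per-case evaluation). The classification branch uses the standard
cross-entropy over the batch, and the total objective is the unweighted sum

$$L_{total} = (L_{CE} + L_{Dice}) + L_{cls}.$$

Probabilities are floored at $10^{-12}$ inside logarithms; the training path
computes both losses in logit space (fused softmax) for numerical stability
and is tested to agree with the probability-space reference implementation.
Dynamic task weighting is deliberately out of scope.

## Numerical core

No deep-learning framework is used: the package carries a small
reverse-mode automatic-differentiation engine over dense R arrays, with the
heavy kernels (grouped 3-D convolution via vol2col + GEMM, max pooling,
trilinear resizing) in C++ through Rcpp/RcppArmadillo. Every operator's
gradient is finite-difference-checked in the test suite (relative error
around 1e-10 on small instances; the block-level acceptance check uses a
1e-3 tolerance). Optimization is plain SGD with momentum 0.9 and weight
decay 1e-4 at a constant learning rate of 0.01, batch size 4 — the training
protocol of the study the package models; no schedule is applied because
none is specified. Convolution weights are Kaiming-initialized with zero
biases from the configuration seed, so model construction, training and
inference are bit-reproducible on CPU.

## Preprocessing

Volumes are resampled to 1 mm isotropic spacing (image trilinear, mask
nearest-neighbour; output shape per axis `round(shape·spacing/target)`),
clipped to [−1000, 400] HU and mapped linearly to [0, 1], and cropped to
64³ patches centered on the lesion (0-based index 32 holds the center
voxel; out-of-volume regions are padded with 0, i.e. air). Augmentation
applies, each with probability 0.5: axis-aligned 90° rotations (free-angle
rotation would require an interpolation convention the protocol does not
fix), elastic deformation from a 4³ control grid with displacement sd 1.5
voxels (image trilinear, mask nearest, one shared field), axis flips, and
Gaussian intensity noise (sd 0.02) on the image only, re-clipped to [0, 1].
The elastic amplitude was chosen so that a canonical ball phantom changes
its foreground volume by well under 15%.

## Evaluation

Seven metrics: Dice, mean IoU, accuracy, sensitivity, specificity,
precision and F1, reported per case and aggregated as mean ± sample sd in
percent. Mean IoU averages the *per-case foreground* IoU — under that
reading IoU = DICE/(2−DICE) holds case by case, which is the consistency
the reported metric pairs satisfy; a per-class variant is available but
non-default. Segmentation predictions are binarized by argmax over the two
softmax channels; classification by thresholding the malignancy probability
at 0.5. Ratios with empty denominators are reported as missing, not as 0,
and two empty masks have Dice 1 by convention.

## The phantom generator

The generator replaces external CT cohorts for all tests. Each phantom is a
64³ volume at 1 mm spacing: lung-window background at −800 HU, one
star-shaped nodule with boundary radius
$r(\theta,\phi) = r_0\,(1 + a\,s(\theta,\phi))$, where $s$ is a sum of
`spike_count` von-Mises-like bumps at seeded random orientations,
normalized to zero mean and unit maximum, so $a < 1$ keeps the radius
positive. Benign cases draw $r_0 \in [1.5, 6]$ mm, $a \in [0, 0.1]$, 0–4
spikes, and intensity in [−100, 0] HU; malignant cases draw
$r_0 \in [5, 15]$ mm (spanning the 3–30 mm diameter range of clinically
annotated nodules), $a \in [0.15, 0.4]$, 6–14 spikes, and intensity in
[0, 100] HU — so size, spiculation and contrast all carry class signal, and
a trivial volume-threshold classifier already exceeds 80% accuracy on a
default cohort. Straight cylindrical vessels (radius 1–2 voxels) of
near-nodule intensity graze the nodule surface without entering the mask,
emulating the vessel-adjacency confound; Gaussian noise (sd 40 HU) and a
one-sided partial-volume halo outside the boundary emulate scanner blur
while keeping the in-mask mean intensity unbiased. The noiseless setting
renders a strict two-valued volume, which the geometric-consistency tests
rely on.

What the phantoms do *not* emulate: real parenchymal texture, airways and
lobar anatomy, pleural attachment, non-solid/ground-glass nodules, scanner
reconstruction kernels, or multi-nodule scans. Passing the phantom
experiments therefore demonstrates that the architecture, losses, and
pipeline are implemented correctly and can learn joint segmentation +
classification signal — not that clinical-level performance is attained.

## Desk-scale experiments

Two seeded learning experiments are part of the test suite and the
acceptance script, run with reduced widths (8/16/32/64) and 32³ patches —
sizes chosen so the whole suite completes on one CPU core:

- **Overfit**: 8 fixed phantom patches, at most 150 SGD steps; training
  Dice reaches ≥ 0.8 with training classification accuracy 1.0 in at least
  2 of 3 seeds.
- **Generalization**: a 40-phantom cohort split 8:1:1; after 40 epochs the
  held-out classification accuracy exceeds 0.8 and held-out Dice exceeds
  0.7, demonstrating that both branches learn transferable signal.

A reproducibility check runs the full chain (generate → train → predict →
evaluate) twice with one seed and requires byte-identical metric CSVs.

## Degenerate inputs and numerical choices

- Nodules whose spiculated envelope would cross the volume boundary are
  rejected with a geometry error at mask construction.
- Group normalization uses the largest divisor of C not exceeding 8 groups;
  Dice and CE smoothing constants are 1e-5 and 1e-12 as above.
- Max-pooling argmax ties break toward the first index; channel-max
  likewise — both deterministic.
- `group_number` returns 1 whenever ⌊C_in/2⌋ = 0, the always-admissible
  group count.

## Known limitations

Training the full-width model (≈43M parameters) at 64³ is computationally
heavy in this CPU-only implementation; it is built and shape-checked in the
tests, while the learning experiments use the reduced configuration. One
lesion per manifest row is assumed (no multi-nodule handling), input is
NIfTI only, and there is no learning-rate schedule, early stopping beyond
the documented step caps, or dynamic loss balancing.
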