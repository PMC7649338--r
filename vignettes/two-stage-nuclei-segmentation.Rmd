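---
title: "Two-stage stacked U-Nets for overlapping-nuclei segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage stacked U-Nets for overlapping-nuclei segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sunseg)
```

## The problem

Nuclear morphology carries diagnostic signal in histopathology, and most
quantitative tissue analyses start from per-nucleus delineation of
hematoxylin-and-eosin (H&E) stained images. Two difficulties dominate:
per-pixel classification of nucleus vs background across heterogeneous
tissue, and the separation of *overlapping* nuclei, where a single binary
mask fuses several objects and any partition of the foreground must decide
which pixels belong to whom — possibly to more than one nucleus at once.

`sunseg` implements a two-stage answer. Stage one is a semantic segmenter:
a stacked U-Net predicts the probability that each pixel belongs to any
nucleus; thresholding at 0.5 and a marker-based watershed give a first
instance segmentation in which the foreground is partitioned (no shared
pixels). Stage two is an overlap detector with the same stacked
architecture but a four-channel input — the RGB patch plus stage one's
binary mask — that predicts pixels where two or more nuclei overlap.
Each connected overlap component sharing at least `min_overlap = 10`
pixels with an instance is unioned into that instance's mask; a component
crossing two instances is added to both, which is exactly how shared
pixels re-enter the final, possibly overlapping, per-object masks.

## The stacked architecture

Each stage holds **four parallel U-Net backbones**, one per pyramid scale
(1.25, 1.0, 0.75, 0.5 of the patch size). A backbone is a VGG16-style
encoder — two 3×3 convolution + ReLU layers per block, channel width
doubling from `base_width` and capped at `8 * base_width`, 2×2 max-pooling
between blocks — mirrored by a decoder using 2×2 transposed convolutions
and skip copy-and-concatenation, with a 1×1 single-logit head. Spatial
size is preserved end to end; levels not divisible by `2^depth` are
reflection-padded internally and cropped after decoding.

The four logit maps are resampled (bilinear) back to the base resolution
and fused by the **attention generation module (AGM)**: eight convolution
layers in a ResNet-34 flavour — a 3×3 stem over the four concatenated
prediction maps, three two-convolution residual basic blocks, and a 1×1
head — whose four output channels pass through a per-pixel softmax. The
result is a per-pixel convex combination: weights are non-negative and
sum to one at every pixel, so the fused logit is an interpretable
attention-weighted average of the four scale-specific predictions, and
the output probability is `sigmoid(sum_k w_k * logit_k)`.

Two structural choices were genuinely open and are resolved as follows.
First, the AGM consumes the four prediction maps rather than deep
feature maps, which keeps the module agnostic to the backbone widths:
it literally learns how to weight and sum the predictions. Second, the
AGM's eight convolution layers are organized as a stem, three
two-convolution residual basic blocks, and a head — mirroring the first
stage of a ResNet-34 after its stem. The per-pixel softmax is what makes
"weight and sum" well-posed: it guarantees a convex combination.

All layers are implemented in compiled code (im2col + BLAS GEMM for the
convolutions) with hand-derived backward passes; the full network
gradient is verified against central finite differences in the test
suite, for both losses, to a relative error below `1e-4`.

## Training

Both stages train with SGD (momentum 0.9) over shuffled mini-batches with
joint image/mask augmentation sampled uniformly from the identity,
right-angle rotations, and vertical/horizontal flips. Right-angle
rotations avoid any interpolation or cropping policy. The full-scale
defaults are learning rate `1e-4`, batch size 4, 20 epochs, 384-pixel
patches.

Stage one minimizes mean binary cross-entropy. Stage two minimizes focal
loss, `-alpha_t (1 - p_t)^gamma log(p_t)`, because overlap pixels are a
rare class (a few percent of the image); `gamma` down-weights
easily-classified background so the loss concentrates on the hard overlap
boundary pixels. Package defaults are the canonical `gamma = 2`,
`alpha = 0.25`. With `gamma = 0, alpha = 0.5` the focal loss reduces
exactly to half the cross-entropy, which the tests assert to `1e-9`.

Stage two trains with the *ground-truth* semantic mask as its fourth
channel (teacher forcing) and consumes the stage-one *prediction* at
inference. This decouples the stages during training; the alternative —
training on predicted masks — would couple stage two's data distribution
to a partially trained stage one.

Probabilities are clamped to `[1e-7, 1 - 1e-7]` inside both losses; the
loss gradients are taken with respect to the fused pre-sigmoid logit in
closed form. Binarization of probability maps uses a fixed 0.5 cut.

## Watershed and the merge rule

The stage-one mask is split by a marker-based watershed on the Euclidean
distance transform (EDT): markers grow outward by a priority flood in
order of decreasing distance, restricted to the mask, with ties broken by
pixel index so the partition is deterministic. Markers default to the
connected plateaus of local maxima of the lightly smoothed EDT within a
5×5 neighbourhood (`peak_footprint = 2`), keeping peaks of height at
least `min_peak = 1`. We also provide the simpler per-component threshold
rule (`marker_method = "ratio"`: pixels with EDT at least 0.7 of their
component's maximum), but its markers miss the core of a small nucleus
attached to a much larger one, which systematically under-segments
clusters; the peak method separates touching nuclei of unequal sizes.
These defaults were selected by scanning separation quality on generator
ground-truth masks. Objects below `min_size = 20` pixels are removed.
Component labelling uses 8-connectivity throughout.

The merge rule is a set union: every overlap component is added to every
instance it shares at least 10 pixels with. Nothing is ever removed from
an instance, so the final foreground contains the stage-one foreground,
and a component matching no instance is discarded as a false positive.

## The synthetic generator

Every stage of the pipeline is testable without external data through a
generator of H&E-like scenes with exact ground truth. Nuclei are filled
rotated ellipses with semi-axes drawn from `radius_range`; a fraction
`overlap_fraction` of them (after the first) is placed with its centre at
0.5–0.95 of the summed semi-majors from an existing nucleus — within one
diameter, forcing a genuine but partial intersection; near-concentric
placements are excluded because two almost-coincident nuclei would not be
annotated as distinct objects. Non-overlapping nuclei are placed clear of
existing ones, with bounded retries and a generation error reporting the
achieved count when the canvas is too crowded.

Rendering is multiplicative stain attenuation: starting from an
eosin-pink background (≈ (230, 200, 215)), every covering nucleus
multiplies each channel by `color/background` with its own jittered
hematoxylin-purple colour (≈ (90, 60, 150)), so pixels covered by two
nuclei are visibly darker than singly covered ones — the cue a real
overlap region offers through higher chromatin density. Gaussian noise
(sd 8 intensity units) is added and intensities are rounded and clipped
to 0–255. Overlap ground truth is defined as pixels covered by at least
two instance masks; the semantic mask is their union, and the three masks
are mutually consistent by construction.

What the generator does *not* emulate: chromatin texture, stain
variation between slides, non-elliptical and lobulated nuclei, tissue
architecture, and out-of-focus blur. Passing the end-to-end demonstration
therefore shows that the architecture, losses, optimizer, watershed and
merge logic function and interlock correctly — not that the tiny models
would segment real tissue; the full-scale configuration exists for that
purpose and trains unchanged, only slower.

## The scaled-down demonstration

`run_demo()` exercises everything at CPU scale: 200 training and 25
held-out images of 64×64 pixels with 5 nuclei each (semi-axes 4–9 px,
`overlap_fraction` 0.5), tiny networks (`base_width` 8, depth 3, AGM
width 8), stage one trained 2 epochs with cross-entropy at learning rate
0.05, stage two trained 3 epochs with focal loss (`alpha` 0.75) at
learning rate 0.4. Two optimizer choices differ deliberately from the
full-scale defaults. The tiny learning rates are larger because training
from random initialization for two epochs on 800 gradient steps needs
them; and stage two's rate exceeds stage one's by about 8× because the
focal modulation `(1 - p_t)^gamma` scales early-training gradients
(where `p_t ≈ 0.5`) down by roughly an order of magnitude. The overlap
class weight `alpha = 0.75` approximately complements the ~2% overlap
prior, calibrating the detector around the 0.5 cut.

The demo reports, on the held-out images: per-image and mean AJI and
semantic F1; the AJI between ground-truth overlap components and the
pixels assigned to two or more final instances ("overlap-region AJI");
and pooled overlap-pixel recall with stage two enabled versus stage one
alone. The stage-one-only recall is structurally zero whenever overlap
exists, because watershed instances are disjoint — that recall gap is
precisely what the second stage contributes. Typical runs reach a mean
AJI of 0.55–0.69 and overlap recall of 0.10–0.19 within about three
minutes on one CPU; on the same scenes, a watershed applied to the
*ground-truth* mask attains a mean AJI around 0.8, which bounds what any
stage-one mask of this quality can achieve under these overlap
conditions.

## Evaluation metrics

The **Aggregated Jaccard Index** matches each ground-truth object with
the predicted object of maximum Jaccard index (ties to the lowest
predicted label, deterministic) and is the ratio of summed best-match
intersections to summed best-match unions plus the area of unmatched
predictions. Two readings of "unmatched" exist: the printed definition —
predictions intersecting *no* ground-truth object — and the original
used-flag bookkeeping, which also penalizes predictions that intersect
ground truth but are never selected. Both are implemented
(`aji_variant = "printed"` is the default; `"used_flag"` is never larger)
and both are verified exactly against an independent brute-force oracle
on random instance maps. Degenerate conventions: empty vs empty scores 1;
one side empty scores 0; the same conventions hold for the pixel metrics
`precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
`F1 = 2TP/(2TP+FN+FP)`. Because final instances may overlap, AJI is
computed object-wise on per-object masks, never on the flattened
rendering. Set-level results are unweighted per-image means.

## Numerical and design notes

* Coordinates are 0-based `(row, col)`; shapes `(H, W)`; intervals
  half-open. Border tiles shift inward so every patch contains real
  pixels; stitching averages multiply-covered strips.
* Bilinear resampling (half-pixel convention) for continuous channels;
  nearest-neighbour for binary channels, which therefore stay binary.
* Max-pooling ties take the first maximum in a fixed scan order;
  watershed ties take the lower pixel index — both make the pipeline
  bit-reproducible under a fixed seed in single-threaded BLAS mode.
* All randomness (weight init, shuffling, augmentation, scene synthesis)
  flows from R's RNG; per-sample seeds derive deterministically from the
  master seed, so datasets reproduce bit-identically.
* He-normal initialization; constant learning rate (no schedule); plain
  SGD with momentum, gradients averaged over the batch.
* Known limitations: no pretrained weights; no stain normalization; the
  merge rule only annotates shared pixels and never splits a stage-one
  blob that watershed failed to divide; whole-slide formats are out of
  scope (fixed-size patch tiling only).
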