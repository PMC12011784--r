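---
title: "histofuse: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{histofuse: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histofuse)
```

## The problem and the model

histofuse classifies two-class H&E histopathology images (1 = normal,
2 = malignant) by fusing two complementary descriptions of each image:

1. **Deep features** from a dual-branch cross-attention vision transformer.
   Each branch splits the image into non-overlapping patches of its own size
   (12 px and 16 px under the paper-scale preset), linearly embeds the
   flattened patches, prepends a learned CLS token, adds a learned positional
   encoding, and runs a stack of pre-norm transformer encoder layers
   (multi-head self-attention plus a GELU feed-forward block, both with
   residual connections). The branches then exchange information: each
   branch's CLS token, projected into the other branch's token width, is the
   sole query of a cross-attention over the other branch's patch tokens
   (softmax scaled by $1/\sqrt{d_k}$) and is updated with a residual add. The
   final layer-normalized CLS vectors — 384-dim (small branch) and 768-dim
   (large branch) at paper scale — are the deep features. As a standalone
   classifier the backbone applies one linear head per branch and averages
   the logits elementwise.
2. **Handcrafted features**, 818 values in a fixed order:
   a 768-bin fuzzy color histogram (FCH), a 26-bin rotation-invariant uniform
   local binary pattern histogram (LBP), and 24 gray-level co-occurrence
   matrix (GLCM) statistics.

Per branch, the fused vector is the CLS vector followed by the handcrafted
vector — 1,202 values for the small branch and 1,586 for the large branch at
paper scale — and the default classifier is one single-hidden-layer
feed-forward network on the 2,788-dim concatenation of both.

## Reconstruction choices for the handcrafted extractors

The three extractors are classical but underdetermined by their printed
dimensionalities alone; the following choices pin them down.

**FCH (768 = 12 × 8 × 8).** HSV space with 12 hue, 8 saturation and 8 value
bins; hue gets the finest angular resolution because hematoxylin/eosin
contrast is primarily a hue axis. Triangular membership functions peak at the
bin centers and fall linearly to zero at the neighboring centers, forming a
partition of unity per dimension (circular wrap on hue; the outermost
saturation/value bins absorb the tails). Each pixel therefore distributes
exactly unit mass over at most 2×2×2 bins, so total mass is conserved and
the normalized histogram sums to 1 regardless of how many bins a pixel
touches. Compared to hard binning, this halves (in practice) the histogram
movement caused by small intensity shifts such as staining variation — the
test suite checks this on a +3/255 brightness shift.

**LBP (26 = P + 2 with P = 24).** Rotation-invariant uniform patterns with
24 circular neighbors at radius 3 are the unique standard parameterization
whose bin count is 26. Neighbors are sampled by bilinear interpolation on
the grayscale image; the comparator is `neighbor >= center` (with a 1e-7
slack that only absorbs floating-point noise from interpolating
integer-valued pixels — a constant image yields exactly the all-ones
pattern). Codes with at most two 0/1 transitions are binned by their number
of set bits (0–24); all other codes share one catch-all bin. The histogram
is computed over interior pixels (3-px margin) and is invariant under
90°/180°/270° image rotations because the sampling offsets (snapped to 8
decimals) map onto themselves under quarter turns.

**GLCM (24 = 6 × 4).** Grayscale is quantized to 64 levels (`floor(g/4)`),
keeping the co-occurrence matrices tractable; symmetric normalized matrices
are built at distance 1 for 0°, 45°, 90°, 135°. Per angle we report
contrast, dissimilarity, homogeneity, energy, correlation and entropy —
a six-statistic set that includes the three named classics (contrast,
entropy, homogeneity) and multiplies out to the printed 24. Entropy uses the
natural log with $0 \log 0 = 0$; correlation is defined as 0 when either
marginal standard deviation vanishes (constant images).

Features are computed on the full image, not on patches. Grayscale
conversion uses the conventional 0.299/0.587/0.114 luminance weights with
round-half-to-even, which makes unit expectations bit-exact (pure red maps
to 76).

## Backbone design notes

* **Preset geometry.** The paper-scale preset uses image size 240 rather
  than 224: the small branch's 12-px patches require a side divisible by 12,
  and 240 (divisible by 12 and 16) is the standard choice for a 12-px-patch
  branch. The CLS widths (384/768) — the quantities that matter downstream —
  are unchanged. Encoder depth (2), heads (6 paper / 2 tiny), MLP ratio and
  the single bidirectional cross-attention round are free architectural
  choices kept deliberately compact for CPU use; all are configurable.
* **Cross-attention dimensions.** The update of branch $b$'s CLS uses a
  projection $f$ into the other branch's width for the query/key space,
  while the value projection maps back to branch $b$'s width so the residual
  add is well-typed. With zero patch tokens the softmax over the single CLS
  position is 1 and the update reduces to the residual plus the value
  projection of the projected CLS — a degenerate case the tests pin down.
* **No dropout at inference**; the forward pass is deterministic.
* **Training.** The backbone trains by minibatch Adam on the fused-logit
  cross-entropy with hand-derived reverse-mode gradients for every
  parameter; the test suite validates them against central finite
  differences (tolerance 1e-3 on unit-scale comparisons) and requires 200
  one-batch steps to at least halve the loss. Attention and all
  accumulations are in double precision.
* **Weight archives** are plain JSON manifests of named tensors with
  explicit shapes. Loading replaces parameters by name, reports unmatched
  names on either side, and refuses shape conflicts — the hook intended for
  externally pre-trained weights.

## Fusion classifier

The paper-style ANN is a single-hidden-layer perceptron (default 128
rectified-linear units, 2-class softmax) trained with minibatch Adam on
cross-entropy, up to 100 epochs with early stopping (patience 20, capped at
the epoch budget). Per-feature standardization is fitted on the training
split only and reused for validation/test — the tests assert the stored
statistics equal the train-split moments even when the validation
distribution is shifted. The returned model is the snapshot of the epoch
with the lowest validation cross-entropy, and the training history records
both curves plus that best epoch.

Whether the two branch-fused vectors feed one classifier or two is an open
reading of the architecture; the default (`mode = "joint"`) feeds the
combined 2,788-dim vector to one network — the simplest reading — while
`mode = "perbranch"` trains one network per branch and averages their
logits, mirroring the backbone's own logit fusion.

## Synthetic data: what it emulates, and what it does not

`generateImage()` renders an eosin-like background (hue/saturation from the
class appearance; brightness modulated by a multiplicative Gaussian-smoothed
noise field whose correlation length is the `textureGrain` parameter),
hematoxylin-like nuclei as anti-aliased filled ellipses (count
`round(density · H·W / 10^4)`, Gaussian-perturbed radii, random
eccentricity 0.65–1 and orientation), and per-channel Gaussian sensor noise.
All randomness uses R's Mersenne-Twister with inversion normals; dataset
image $i$ uses seed $(s + 9973\,i) \bmod (2^{31}-1)$ from master seed $s$,
so datasets are bit-reproducible and any image can be regenerated alone.

The bundled `"easy"` preset separates the classes by a 40° background-hue
gap, clearly distinct texture correlation lengths (6 px vs 2 px) and nucleus
densities (25 vs 55 per 10^4 px²) — conditions under which the full pipeline
should be near-perfect, which is exactly what makes it a useful end-to-end
recovery check. The `"hard"` preset narrows the hue gap to 8°, overlaps the
texture parameters and doubles the noise. Defaults were chosen once to give
visually plausible H&E-like images at 64–240 px and are not tuned further.

What the generator does **not** emulate: realistic nuclear morphology and
chromatin texture, stain deconvolution physics, tissue architecture
(glands, stroma), compression artifacts, or whole-slide pyramids. Passing
the synthetic end-to-end check therefore demonstrates that the pipeline's
plumbing — generation, features, fusion, training, evaluation — carries
class signal correctly; it says nothing about accuracy on real biopsy
slides, which additionally requires transfer-learned backbone weights and
real data.

## Numerical and procedural conventions

* **Augmentation** applies, in order: horizontal flip, vertical flip,
  rotation with angle uniform in ±15° (bilinear resampling, reflect padding,
  cropped back to the input size — the interpolation/padding is a declared
  choice, shape-preserving so batches stay rectangular), then multiplicative
  brightness, contrast-about-128 and saturation factors uniform in
  1 ± delta. A zero-strength spec is the pixelwise identity.
* **Splits** use floor-then-largest-remainder rounding (ties broken train,
  val, test), so sizes sum exactly to $n$: 1,000 items at 70/15/15 give
  700/150/150, and 10 items give 7/2/1. Stratified mode applies the rule per
  class, keeping class shares within one item.
* **Metrics.** Positive class is 2 (malignant). Zero-denominator
  conventions (all flagged in the report): precision/sensitivity/specificity
  0 when undefined, F1 = 0 when precision + sensitivity = 0, kappa = 0 when
  chance agreement is 1. ROC uses grouped thresholds with trapezoidal
  integration, equivalent to the half-tie Mann-Whitney statistic; exact
  probability ties in prediction go to class 1.
* **Problem sizes.** The test suite and the acceptance script exercise the
  tiny backbone at 64 px with 100 images per class end to end, and the
  paper-scale backbone (240 px, dims 384/768) for single forward passes;
  these sizes keep a full run in the minutes range on one CPU core while
  still exercising every code path at the printed dimensionalities.

## Known limitations

* The backbone is a faithful but compact reconstruction: depth, heads, and
  cross-attention rounds are not prescribed by the architecture's printed
  description and default to small values.
* No GPU path; training the paper-scale backbone from scratch in R is out of
  scope (the weight-archive loader is the intended entry point for large
  pre-trained weights).
* Binary classification only; no stain normalization or whole-slide tiling.
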