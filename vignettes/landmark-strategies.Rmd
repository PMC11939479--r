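---
title: "Coordinate-regression strategies for carapace landmark detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coordinate-regression strategies for carapace landmark detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shellmark)
```

## The problem

Morphometric studies of the Chinese mitten crab (*Eriocheir sinensis*)
describe the carapace by a fixed set of named landmark points: the start,
peak and end of each of the twelve marginal teeth (four frontal, four on
each lateral margin, with adjacent teeth sharing their junction point), the
three points of the rear edge, and the seven points of the M-shaped neck
groove. That gives $3 \times 9 + 3 + 7 = 37$ anatomical points; two
bounding-rectangle corners (upper-left, lower-right) are appended as points
38 and 39 so a regressor simultaneously localises the animal:

```{r}
sch <- carapace_schema()
table(sch$group)
```

Detecting these points is a coordinate-regression problem: map an RGB image
to 39 (x, y) pairs. `shellmark` implements and compares three strategies
that share one convolutional backbone and differ only in how the spatial
feature maps become numbers.

## Coordinate frames

All learning happens in a *normalized frame*. A pixel-frame coordinate $x$
on an axis of $W$ pixels (0-based, pixel centres) maps to

$$x' = \frac{2(x + 1) - (W + 1)}{W},$$

so pixel centres sit strictly inside $(-1, 1)$ and the map is exactly
invertible, $x = (W x' + W - 1)/2$. The same pixel-centre convention
defines the signed coordinate grids used by the soft-argmax head
(`dsnt_grids()`): $X_{ij} = (2j - (n+1))/n$ with 1-based $j$. An
alternative "endpoint" convention, $2(j-1)/(n-1) - 1$, which pins frame
borders to exactly $\pm 1$, is available through the `convention` argument
of the frame-conversion functions but is not the default: the pixel-centre
form treats each grid cell as a cell centre, which is consistent with how
the heatmap renderer and the bilinear resampler address pixels.

## The three heads

**Fully-connected regression.** The backbone features are compressed by a
*global depthwise convolution* (GDConv) — a per-channel inner product with
a learnable kernel of the same spatial size as the feature map, which
reduces each channel to one number and is initialised at the uniform kernel
$1/(wh)$, i.e. exactly global average pooling at the start of training.
The GDConv descriptor is concatenated with the flattened backbone features
and passed through a three-layer fully-connected stage onto the
$1 \times 78$ output. Almost all of this network's budget sits in the wide
first FC layer; the two hidden widths (205, 237) were fixed once so the
total comes to 27.93 M trainable parameters, the published budget for this
strategy.

**Gaussian-heatmap regression.** Three *semantic embedding blocks* fuse
deep, low-resolution backbone features with shallow, high-resolution ones
(3×3 convolution on the deep path, 1×1 on the shallow path, bilinear
upsampling to a common size, elementwise product), and a final 1×1
convolution plus upsampling yields one heatmap per landmark at the input
resolution — 39 × 512 × 512 at the canonical configuration. Training
regresses rendered target heatmaps, unnormalised Gaussians with peak 1 at
the landmark and standard deviation `hm_sigma` (7 px at 512; scaled
proportionally at other resolutions); landmarks outside the frame get
all-zero channels. Decoding is per-channel argmax with ties broken by
row-major scan order — simple, but non-differentiable and quantised to
whole pixels.

**Differentiable spatial-to-numerical transform (soft-argmax).** A 1×1
convolution maps the deepest backbone features (128 × 32 × 32 at the
canonical configuration) to 39 channels, each spatially
softmax-normalised into a discrete distribution $\hat Z$, and the
coordinates are the expectations

$$x = \langle \hat Z, X \rangle_F, \qquad y = \langle \hat Z, Y \rangle_F.$$

The transform has no parameters beyond the 1×1 convolution, outputs live
strictly inside $(-1,1)$, and the whole decode path is differentiable, so
the coordinate loss reaches the convolutional weights directly. Its
combined loss is the coordinate MSE plus $\lambda$ times a distribution
regulariser: the mean Jensen–Shannon divergence between each $\hat Z$ and a
unit-mass Gaussian (`sigma_t` grid cells) centred at the target, which
keeps the heatmaps compact and unimodal rather than any distribution with
the right mean.

## Backbone and parameter budgets

The shared backbone is a lightweight stack of strided 3×3 convolutions
(partly grouped), batch normalisation and ReLU6, followed by three
inverted-residual blocks (1×1 expand, depthwise 3×3, 1×1 project, skip
connection at matching geometry). Intermediate taps feed the semantic
embedding blocks of the heatmap head. Published per-network budgets pin the
design: channel widths and the FC hidden sizes were tuned once, before any
experiments, so that

```{r}
resource_report()[, c("network", "params", "params_m", "flops_g",
                      "model_size_mb")]
```

reproduces 27.93 M (fully-connected), 0.97 M (heatmap) and 0.84 M (DSNT)
trainable parameters at 512 × 512. `count_resources()` is a pure function
of the network specification; the test suite verifies that the compiled
engine allocates exactly the counted parameters.

A `preset = "compact"` variant of each network (thinner backbone, same
topology) exists for fast experiments at reduced resolution; all
scientific structure — heads, losses, grids, decoding — is identical.

## The training engine

No deep-learning framework is involved: forward and backward passes are
written in single-precision RcppArmadillo code. Convolutions run as im2col
plus BLAS matrix multiplication (with a direct path for depthwise kernels),
batch normalisation uses batch statistics during training and running
statistics at evaluation, upsampling is bilinear with half-pixel centres,
and optimisation is Adam. Activations use one column per sample with
element order `(row * width + col) * channels + channel`, which keeps
channel vectors contiguous. Weight initialisation is He-style Gaussian
from a seeded generator, so `build_landmark_network(spec, seed)` is fully
deterministic. Double-precision R reference implementations of the
numerically delicate pieces (softmax, expectation and its gradient,
GDConv) exist alongside the engine and are checked against it and against
finite differences in the test suite.

## Synthetic carapaces

`make_carapace_sample()` renders a parametric carapace with exact ground
truth. The rim is a super-ellipse (exponent 2.5, wider than tall, slightly
fuller in front than behind) with twelve teeth displaced radially outward
in fixed angular sectors; tooth start/junction/end points lie on the base
rim and peaks on the displaced rim. The neck groove is a seven-point
M-shaped polyline drawn as a darkened stroke; textures are smooth
value-noise fields and a linear illumination gradient over a flat
background. `sample_carapace_params()` jitters centre, axes, orientation,
tooth amplitudes, groove shape and colours under a seed, and
`simulate_carapace_dataset()` packs `n` such samples (one seed each) into
the engine's column layout. The generator's default jitter ranges are the
study conditions and are deliberately not tuned to any particular
experiment's outcome.

Synthetic data is the point, not a stand-in: it provides noise-free,
perfectly repeatable annotations at any sample size, which is what lets the
test suite make sharp claims (a rendered heatmap decodes back to exactly
the rounded landmark position, a rotation moves landmarks by exactly the
rotation matrix).

## Augmentation

Four stochastic transforms, each applied independently with probability
0.5: Gaussian blur (σ ∈ [0.5, 3]), brightness/contrast
(±40, ×[0.7, 1.3] about mid-grey), rotation (±30° about the image centre,
bilinear, border-median fill) and 1–3 rectangular occluders (2–10 % of the
image area each). Rotation remaps every landmark with the exact rotation
matrix and recomputes the bounding-box corners from the rotated points;
points leaving the frame keep their coordinates but are flagged invalid.
Occluders do not move labels — learning to infer hidden landmarks from
context is their purpose. `simulate_carapace_pair()` renders each base
carapace once and returns the un-augmented ("source") and augmented
datasets of the same animals, which is also the cheaper way to build the
pair.

## The parallel experiment design

`experiment_groups()` fixes seven groups: groups 1–3 train the
fully-connected network on source data under L1, Smooth L1 and Wing loss;
groups 4–5 are replicate L1 runs on augmented data (identical settings,
different seed); group 6 is the heatmap network and group 7 the DSNT
network with its combined loss, both on augmented data. All groups share
one augmented (hence rotated) test set — one tenth of the pool — so
robustness to the transforms is part of the comparison. Training stops
early when the mean epoch loss falls below 0.001, otherwise after 300
epochs. `train_landmark_model()` records per-epoch loss and pooled
MAE/MSE/$R^2$ (computed in the normalized frame after decoding, so all
heads are measured on one scale); `tidy()`, `glance()`, `autoplot()` and
`experiment_report()` summarise fits.

## Numerical choices and limitations

* Single precision in the engine, double precision in all R-side oracles;
  gradient checks therefore run against the R implementations, where
  relative errors below $10^{-4}$ are meaningful.
* The spatial softmax subtracts the per-channel maximum before
  exponentiating; rendered Gaussians are truncated at $4\sigma + 1$ cells
  for speed.
* Argmax decoding quantises the heatmap head to whole pixels, a structural
  disadvantage at low heatmap resolution that the soft-argmax head does not
  share; this is visible in the compact-resolution experiments.
* The semantic embedding blocks keep their branch convolutions linear
  (batch-normalised, no activation): an elementwise product of two clipped
  non-negative branches has an exact dead stationary point at disjoint
  spatial supports — each factor's gradient is the other, zero, factor —
  and pixelwise losses reliably drive the decoder into it. Signed branches
  remove that equilibrium without changing the parameter count.
* Pixelwise L1 on sparse heatmaps has the all-zero map as its per-pixel
  median optimum when the Gaussian mass fraction is small, and its
  constant-magnitude gradients cannot cross that barrier; `hm_sigma` must
  be large enough relative to the heatmap grid (several cells) for the
  heatmap head to train under L1. The default (7 px at 512, scaled with
  resolution) suits the canonical configuration; compact-resolution runs
  set it explicitly.
* The generator produces one centred animal per image over a clean
  background; detection under clutter, multiple animals, or real
  photographic nuisance factors is out of scope.
* Resource accounting counts 2 operations per multiply–accumulate for
  convolution/FC/GDConv layers only; normalisation and elementwise
  activations are excluded.
* Reported training times are wall-clock on the current machine and are
  not comparable across hardware.
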