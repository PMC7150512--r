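---
title: "Methods: the dermpipe dermoscopy classification pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the dermpipe dermoscopy classification pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Multi-class skin-lesion classification from dermoscopic images is dominated
by three practical difficulties: raw images mix cropped close-ups with
uncropped frames where the circular illuminated field of view (FOV) sits
inside a large near-black border; the class distribution is severely
imbalanced (common nevi outnumber rare dermatofibromas by orders of
magnitude); and images arrive from many scanners with different illuminants.
dermpipe implements a full pipeline that addresses each of these — FOV
auto-cropping, class-balanced training, color constancy — plus patient
metadata fusion, deterministic multi-crop test-time augmentation, and
cross-validation-driven ensemble subset selection, and makes every stage
testable at desk scale on synthetic data with exact ground truth.

# Field-of-view cropping

`auto_crop()` composes four steps:

1. **Binarization** (`binarize_fov()`): a pixel is foreground when its mean
   channel intensity exceeds a very low threshold. The default is 20/255 —
   above the sensor noise we simulate in black borders (uniform in
   [0, 10]/255) and far below any skin tone. The threshold is a parameter of
   `crop_params()` because border brightness varies between scanners.
2. **Moment ellipse** (`fit_fov_ellipse()`): the foreground's center of mass
   and the ellipse with the same second central moments. We use the standard
   equivalent-ellipse convention, semi-axis = 2·√(eigenvalue of the
   second-central-moment matrix): a filled disk of radius *r* then yields
   semi-axes exactly *r* (its second moment is *r*²/4), and a full *w* × *h*
   frame yields *w*/√3 × *h*/√3. Orientation comes from the principal
   eigenvector and is reported in (−π/2, π/2]. An empty mask raises a
   "no field of view found" condition which `auto_crop()` converts into a
   no-crop outcome with a warning; a collinear mask is rejected as
   degenerate.
3. **Bounding box** (`ellipse_to_bbox()`): the tight axis-aligned box of the
   rotated ellipse, with half-extents hx = √(a²cos²θ + b²sin²θ),
   hy = √(a²sin²θ + b²cos²θ), floored/ceiled outward and clipped to the
   frame. All coordinates are 0-based with half-open boxes
   [x0, x1) × [y0, y1), x = column, y = row; one fixed convention avoids
   off-by-one drift between modules.
4. **Crop-necessity heuristic** (`needs_cropping()`): crop only when at
   least 5% of the image area lies outside the box **and** the inside is at
   least 2× brighter than the outside (plus 1/255 so a pure-black border
   cannot divide by zero). Both constants are exposed in `crop_params()`;
   the defaults are conservative enough that full-frame images are never
   cropped (we verify zero false crops on 100 full-frame fixtures) while
   disk-FOV fixtures are recovered within 3 px per edge in well over 95% of
   200 cases.

# Color constancy and resizing

`shades_of_gray()` estimates the per-channel illuminant as the Minkowski
p-norm mean e_c = (mean I_c^p)^(1/p) with p = 6 and rescales each channel by
g/e_c. The gain g is the arithmetic mean of the three illuminants — the
choice preserves overall brightness while making the three post-correction
p-norm means exactly equal (our tests require agreement to 1e-4 relative in
the absence of clipping; uniform achromatic images are exact fixed points).
Output is clipped to [0, 1]; an identically-zero channel is left unchanged
with a warning rather than divided by zero.

`resize_longer_side()` shrinks only images whose longer side exceeds the
target (600 px by default, the HAM10000 reference resolution), preserving
aspect ratio to within one pixel; smaller images are never upscaled, which
also makes the operation idempotent. Interpolation is EBImage's antialiased
bilinear filter — adequate for the ≤ 2× downscales the pipeline performs.

# Metadata encoding

Patient metadata is encoded as an 11-vector: 8 one-hot anatomical-site
features (the ISIC 2019 site vocabulary, in fixed alphabetical order so
vectors are reproducible), 2 one-hot sex features (female, male), and raw
age in years. Missing categorical properties zero their whole block; missing
age becomes the sentinel −5, which lies outside the legitimate value range
(age 0 exists, so 0 cannot mark missingness). Age is deliberately left
unstandardized — the sentinel's meaning depends on the raw scale. Dropout
for metadata (`apply_meta_dropout()`, default p = 0.1) operates on the
*record*, before encoding, so a masked property always produces a consistent
all-zero block or sentinel; masking the encoded vector could produce
states no real record can reach.

# Augmentation and input strategies

`random_augment()` composes a center-based affine transform (rotation,
isotropic scale, shear — black fill), flips, brightness/contrast jitter and
CutOut (one 16 px hole, zero fill, clipped at borders). The transform
*families* are fixed; magnitudes default to rotation ±180°, scale 0.8–1.2,
shear ±10°, brightness ±0.3, contrast 0.7–1.3 and are all configurable.
Each call attaches its sampled magnitudes as an attribute, so tests can
verify the sampling distributions directly rather than inverting image
transforms.

Two input strategies feed training: `same_size_crop()` takes a fixed-size
window at a uniformly random valid offset (zero-padding smaller images), and
`random_resize_crop()` is the ImageNet-style operator — area fraction
uniform in (0.08, 1), aspect log-uniform in (3/4, 4/3), ten attempts, then a
center-crop fallback.

# Model and training

The classifier is two-branch: any backbone satisfying a minimal contract
(declared input size, pooled feature width, init/forward/backward) feeds
global-average-pooled features either straight into a linear classifier
(image-only mode) or into a fusion layer after concatenation with the
metadata branch (11 → 256 → 256, each layer with batch norm, ReLU and
dropout 0.4; fusion layer 1024 units by default, scalable). The package
ships `tiny_backbone()` — three 3×3 conv blocks with average pooling,
trained by a small built-in engine (im2col convolutions, Adam) — because the
pipeline must be trainable and testable on one CPU in seconds; GPU-scale
pretrained backbones plug in through the same contract.

Training follows the two-stage protocol. Stage 1 trains the CNN on images
only with weighted cross-entropy: class *i* is weighted by
n_i = (N/N_i)^k with k = 1, so Σ N_i·n_i = C·N — an identity our tests
check numerically, alongside agreement of the whole loss with a per-sample
brute-force oracle. The learning rate halves every 25 epochs; the held-out
fold's mean sensitivity is evaluated every `eval_period` epochs; both the
best-so-far checkpoint (ties keep the earlier, less-overfit epoch) and the
final checkpoint are retained. Stage 2 (`train_meta()`) freezes the backbone
bit-for-bit — asserted structurally after every run — and trains only the
metadata branch, fusion layer and classifier, with image augmentation still
active (so CNN features vary between passes) and metadata dropout applied.

Cross-validation is lesion-grouped (`grouped_kfold()`): lesions are shuffled
under the seed and dealt round-robin, so all images of one lesion share a
fold and fold sizes differ by at most one lesion. Records can be flagged
train-only (the treatment given to external data), joining every training
set and no validation set.

Default scales: the shipped backbone uses 48 × 48 inputs and a base
learning rate of 3e-3. The published protocol's 100-epoch/1e-3-and-below
regimes belong to large pretrained backbones; at the tiny backbone's scale
(hundreds of images, ~10 epochs) 3e-3 converges reliably while 1e-3 does
not move past chance, which is why 3e-3 is the package default and the rate
remains a per-backbone configuration value.

# Prediction

Test-time augmentation is fully deterministic. The same-sized strategy uses
36 ordered crops on a 6 × 6 grid with corners evenly spaced from 0 to
(dim − crop) — the simplest deterministic layout consistent with 36 views
that covers the four corners and the center. The random-resize strategy uses
4 center crops at fractions {1.0, 0.875, 0.75, 0.625} of the shorter side ×
4 flip variants (identity, horizontal, vertical, both) = 16 views, the only
factorization of 16 consistent with "four scaled center crops and flips".
Per-view softmax vectors are averaged arithmetically (metadata passed
unchanged to every view), and per-view probabilities are retained for audit.

# Ensembling

Configurations' cross-validated held-out predictions form a
configurations × folds tensor. `exhaustive_subset_search()` scores all
2^n − 1 nonempty subsets by the mean sensitivity of their averaged
predictions and returns the argmax. Two open choices were resolved as
follows:

* **Objective**: S is computed on the held-out folds *pooled* into one
  vector (a single-number objective); per-fold S values of the winner are
  also reported so fold variability stays visible.
* **Tie-breaks**: argmax prediction ties go to the lowest class index;
  subset-score ties prefer the smaller subset, then lexicographic order —
  the search is fully deterministic.

By construction S(C*) is at least the score of the full-ensemble average
and of every singleton; the test suite asserts this on tensors where one
configuration has skill 0.9 and seven are at chance, and checks the
averaging against an independently coded nested mean. `pool_best_last()`
adds the last-checkpoint predictions of the selected configurations to the
final ensemble.

# The synthetic-data generator

`gen_dermoscopy_image()` renders a skin-toned disk (RGB ≈ (0.80, 0.62,
0.55) plus Gaussian noise, σ = 0.02) over a noisy near-black border
(uniform [0, 10]/255, exercising the low-threshold binarization), with an
elliptical lesion whose hue (class/9 on the HSV wheel) and relative size
(0.25 + 0.04·class) are deterministic functions of the class index — a
nine-class task a tiny CNN can separate, by design. Ages are multiples of
five in 0..85, mirroring ISIC's five-year age groups; metadata fields go
missing independently at configurable rates. Two switches control where
class signal lives: `image_class_signal = FALSE` makes lesions
class-independent, and `metadata_class_signal = TRUE` writes the class into
site/age/sex — together they let tests isolate what the metadata branch
contributes (image-only S collapses to chance ≈ 1/9 while the meta stage
recovers S ≈ 1).

What the generator deliberately does **not** emulate: hair, rulers, gel
bubbles, vignetting, off-circle FOV shapes, intra-class appearance overlap,
or correlated missingness. Passing tests therefore demonstrate that the
*mechanisms* (cropping geometry, loss weighting, grouping, selection) are
correct, not that the tiny backbone would rank well on real dermoscopy.

# Problem sizes and numerical choices

The test and acceptance suites use sizes chosen so the whole pipeline runs
comfortably on one CPU: 200 disk + 100 full-frame fixtures for crop
recovery, 50 images for the color-constancy property, 1000 random lesion
structures for the leakage check, an 8 × 5 × 200 tensor (255 subsets) for
the search, and a ~450-image, 10-epoch smoke run for training (held-out
S ≥ 0.60 vs chance 1/9). Probability rows are validated to 1e-9, metric
oracles to 1e-12, the loss oracle to 1e-6 relative. Degenerate inputs have
defined behavior throughout: all-black images are returned uncropped with a
warning, single-class truths yield `NA` AUCs, absent classes are excluded
from S with a warning, and a diverging (non-finite) training loss aborts
with a diagnostic rather than continuing.

# Known limitations

* The built-in engine is plain R; it is fast enough for the tiny backbone
  but not a vehicle for EfficientNet-scale models — those enter through the
  backbone contract with their own implementation.
* The search is exhaustive by design and capped at 16 configurations
  (65 535 subsets) unless the cap is raised explicitly.
* Synthetic fixtures are separable by construction; none of the reported
  sensitivities transfer to real ISIC data.
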