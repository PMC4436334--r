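---
title: "Counting fly eggs by density estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting fly eggs by density estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(eggCounter)
```

## The problem

Fecundity assays in *Drosophila* produce hundreds of vials whose egg
loads must be counted. Eggs are small, bright, ellipsoidal, often
clustered or overlapping, and sit on food surfaces that range from a
translucent defined medium to an opaque, textured sugar/yeast medium,
with bubbles, specular reflections from the vial wall and marks on the
vial base confusing any naive detector. `eggCounter` counts eggs without
ever segmenting them, using supervised density estimation: the model
learns what "density of egg centres" looks like per pixel, and a count
is just the sum of a predicted density map.

## The model

### Density ground truth

A labelled image is a set of dots, one per egg centre. Each dot is
replaced by a discrete 2-D Gaussian kernel of width `sigma` (default
1.0 px), evaluated at pixel centres over a window of radius
`truncationRadius * sigma` (default 4) and normalized to **exactly**
unit mass over that window. Summing the resulting density map over any
region therefore returns the number of contributing eggs; this exactness
is the contract the whole method rests on, so normalization is by the
discrete window sum rather than the continuous Gaussian constant. Mass
of a kernel that sticks out of the image is lost, not renormalized —
the same thing convolution of a dot grid with a finite kernel would do,
and eggs essentially never touch the frame of a vial photograph. `sigma`
must stay smaller than the egg so that neighbouring kernels do not merge
into blobs wider than the objects; if you image at a very different
resolution, rescale `sigma` with it.

### Features

Every pixel is described by a multiscale filter bank: at each scale
`sigma` in (0.8, 1.6, 3.2, 6.4, 12.8) and on each of the R, G, B
channels the package computes

* the Gaussian gradient magnitude at scale `sigma`,
* the Laplacian of Gaussian at scale `sigma`,
* the two eigenvalues of the 2 × 2 structure tensor (gradients at the
  inner scale `sigma`/2, tensor smoothing at the outer scale `sigma`),

giving 3 × 5 × 4 = 60 rotation-invariant planes. The smallest scales
respond to egg edges and the speckle grain of opaque food; the largest
scales encode illumination context. All kernels are sampled Gaussians
truncated at 3 `sigma` (the usual window for this family of filters);
first- and second-derivative kernels are corrected to have exactly zero
response to constant images. Boundaries are handled by half-sample
reflection so that every pixel — including the edge of a training ROI —
has a well-defined feature vector. Convolution is FFT-based, padded up
to 2-3-5-smooth sizes (R's mixed-radix FFT degrades badly on large prime
lengths). Integer-coded 8- and 16-bit images are divided by 255 and
65535 up front so that models transfer across bit depths.

### Regression

Feature vectors are regressed onto density values with an ensemble of 30
extremely randomized trees: each split draws `ceiling(sqrt(60))` = 8
candidate features, one uniformly random threshold per candidate between
that feature's observed minimum and maximum, and keeps the candidate
with the largest variance reduction of the density labels; trees are
grown to purity (minimum terminal node size 1). The ensemble is fitted
by `ranger` (`splitrule = "extratrees"`, `num.random.splits = 1`, no
bootstrap), which implements exactly this rule; a compiled traversal of
the stored forest is used for whole-image prediction and is asserted
equal to `ranger`'s own predictions in the test suite. Predictions are
per-pixel tree averages of non-negative training densities, hence
non-negative and bounded by the largest training target by construction;
no clamping stage exists anywhere.

Training uses every pixel of every labelled ROI. Density targets come
from the density map of the *full* image cropped to the ROI, so kernels
of eggs lying just outside an ROI still contribute the correct partial
mass inside it. For whole-image training regions at vial-photo scale
the design matrix reaches millions of rows; `fitModel(maxPixels = ...)`
and `loocvConfig(maxTrainingPixels = ...)` (default 20000 per fit) take
a seeded *uniform* subsample of rows. Uniformity matters: it preserves
the marginal distribution of density targets, so the summed prediction
stays an unbiased count estimator, which stratified or
background-balanced sampling would break.

### Bias correction

Raw summed counts regress toward the mean of the training counts:
sparse vials are over-estimated and dense vials under-estimated,
because features of partially occluded, clustered eggs are diluted.
The correction is the affine map

$$CC = \beta \, PC + c$$

with $(\beta, c)$ the least-squares solution over the training regions'
(predicted, actual) count pairs, computed in closed form from the
normal equations. It needs at least 3 regions with at least 2 distinct
predicted counts. Corrected counts carry a 95% *prediction* interval
(new-observation interval, $t$ distribution with $n - 2$ degrees of
freedom) rather than a confidence interval for the line's mean: the
user's question is "how certain is the corrected count of this one new
vial", not "where is the regression line". With exactly collinear pairs
the residual variance is zero and the interval degenerates to zero
width; it is returned flagged rather than silently. Negative corrected
counts under extreme extrapolation are reported with a warning, never
clamped. The correction is fitted once per training session (and, in
cross-validation, once per fold from that fold's training images only —
the only leakage-free reading).

### Evaluation protocol

Accuracy is reported as percent accuracy,
$100 - \frac{1}{n}\sum_i |PC_i - GT_i| / GT_i \cdot 100$ — 100 minus
the mean absolute relative count error (the error itself is also
reported). It can go negative when the mean relative error exceeds
100%. `runLoocv()` implements hold-one-out cross-validation with whole
images as training regions, per-fold bias refitting, and `nReplicates`
(default 5) statistical replicates with derived seeds, summarized as
mean ± SE (`sd / sqrt(nReplicates)`).

## The synthetic generator

`generateVialImage()` renders a seeded vial scene: a circular food disc
under a radial illumination falloff inside a dark frame; anti-aliased
bright ellipsoidal eggs (major axis 8–14 px, minor 3–5 px, random
orientation, per-egg intensity jitter, default 30% of eggs placed
within one egg-length of an existing egg so clusters and overlaps
occur); bubbles with dark rims and specular glints; bright elongated
specular streaks near the vial wall; dark base marks; additive Gaussian
noise (s.d. 0.01). Two media are modelled on the two real food classes:
*translucent* defined medium renders as a darker, smooth surface on
which bright eggs stand out, while *opaque* sugar/yeast food is pale,
strongly speckled and close to egg brightness — which is what makes the
opaque class measurably harder, as it is for real photographs.
`generateDataset()` spreads egg counts across a range (default 15–410,
a broad span of realistic vial densities) and derives one seed per
image from a master seed, so any image is reproducible from the
manifest alone.

What the generator does *not* emulate: camera optics (defocus,
chromatic aberration, JPEG artefacts), perspective distortion of the
vial wall, egg reflections on the glass, and larvae or debris. Passing
the synthetic recovery tests therefore shows the pipeline is correct
and learnable under the stated conditions; it does not certify any
particular accuracy level on a given real camera setup, which is what
the interactive retraining workflow is for.

## Numerical and design choices

* Coordinates are 0-based (row, col), row-major, with half-open ROIs —
  the convention of the mask/CSV annotation dialects the package reads
  and writes; conversion to R's 1-based indexing happens only at
  indexing sites.
* A mask pixel can encode at most one egg; CSV annotations can carry
  duplicate coordinates (two eggs closer than one pixel).
* Dot order (row-major for masks, file order for CSV) never affects any
  downstream result; tests assert order-invariance of the metric.
* The structure tensor's inner scale is `sigma`/2 — the filter family
  names only one scale per level, and the half-scale gradient is the
  common convention of the underlying filter library lineage.
* All randomness flows from one master seed through named substreams
  (a 31-bit hash), so every component — per-image scenes, pixel
  subsampling, per-forest seeds — is independently reproducible, and
  unseeded CLI runs log the entropy seed they drew.
* Degenerate inputs: an all-zero mask is a valid empty annotation;
  training targets that are all zero yield a model that predicts
  exactly zero everywhere; identical feature vectors with differing
  targets are averaged by the trees, not rejected.

## Problem sizes used by the checks

The test suite and the acceptance script run entirely on synthetic
scenes. The leave-one-out recovery study uses 8 translucent vials of
600 × 600 px spanning ~15–410 eggs with 5 replicates and 30 trees; the
acceptance script repeats it at reduced size for both media, scaling
the count range with image area (translucent 400 × 400 px, 15–182
eggs; opaque 320 × 320 px, 15–117 eggs) so the eggs-per-pixel crowding
of the full-scale condition is preserved — keeping the raw count range
while shrinking the dish would quadruple the crowding and push the
densest vials into a regime the affine correction is not meant for; the
repeated-training variability check uses one 300 × 300 px vial with 120
eggs and 30 differently seeded fits; the training-curve and
medium-difficulty checks use 5–6 vials at 256 × 256 px. These sizes are
the package's own desk-scale choices; the pipeline itself is
resolution-agnostic.

## Known limitations

* The bias correction is strictly affine; strongly nonlinear count
  bias (e.g. saturation at extreme crowding) is out of its reach.
* Counts are not integers; the method estimates density mass, and
  values like 203.4 are normal.
* Models are tied to their feature configuration; archives refuse to
  load into a mismatched configuration rather than mispredict.
* Two eggs closer than one pixel cannot be expressed in mask
  annotations (use the CSV dialect).
* JPEG input is not supported; convert to PNG or TIFF.
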