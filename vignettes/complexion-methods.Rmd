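---
title: "Facial complexion analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Facial complexion analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(complexion)
```

## The problem

In Traditional Chinese Medicine (TCM) facial inspection, a physician reads a
patient's *complexion* — the combination of facial color and gloss — as a
diagnostic sign. Six color categories are conventional: normal, cyan
(bluish), red, yellow, white (pale), and black (darkish); gloss indicates
disease severity. This package implements a computerized pipeline for that
reading: it is *qualitative* (a six-class facial-color classifier) and
*quantitative* (continuous color-degree and gloss-degree rankings per
subject).

The pipeline has four stages:

1. **Skin detection.** Frontal photographs are downscaled 8-fold by block
   averaging, skin pixels are detected in log-opponent chromaticity space,
   the mouth region is excluded by a rectangular box, and luminance
   extremes (moles, hair, specular spots) are trimmed.
2. **Chromaticity bases.** Four representative chromaticity points — one
   per chromatic class (normal, cyan, red, yellow) — are learned by
   *two-level* fuzzy c-means clustering in the CIELAB (a, b) plane.
3. **Complexion histogram.** Each face becomes a normalized histogram:
   every skin pixel is assigned to its nearest base and, within the base,
   to a luminance sub-bin. Optionally the face is split into five weighted
   regions (cheeks, forehead, nose, jaw) whose histograms are fused.
4. **Recognition and ranking.** A one-against-one RBF-kernel SVM predicts
   the color class under leave-one-out cross-validation; unsupervised
   min–max ranking functions then place every subject on a
   (color degree, gloss degree) plane.

## Color spaces

RGB is converted to CIEXYZ by the standard D65 linear matrix and scaled to
0–100 so the ratios against the reference white (95.047, 100, 108.883) are
dimensionless; CIELAB follows with the usual piecewise cube-root encoding.
The matrix is applied to the camera RGB values as given — the
`assume_linear_rgb` flag records this reading; no sRGB gamma decoding is
performed, since the intended acquisition pipeline is color-managed and
the transform's role here is a fixed feature map, not colorimetry against
a display standard.

Skin detection uses log-opponent (LO) coordinates. Only the channel
*names* (I and By) are fixed by the method's lineage, so the package
documents its own dialect: with $\ell(x) = \log(x+1)$,

$$I = \tfrac{1}{3}(\ell(R)+\ell(G)+\ell(B)),\quad
  Rg = \ell(R)-\ell(G),\quad
  By = \ell(B)-\tfrac{1}{2}(\ell(R)+\ell(G)).$$

The $+1$ offset keeps every 8-bit pixel finite.

## Skin detection

The detector fuses two rules, both estimated from the input image itself
(no training corpus):

* **Histogram rule.** A 2D histogram of (I, By) with `histogram_bins = 24`
  bins per axis is smoothed by a Gaussian of `smoothing_sigma = 2.5` bins.
  Bins above `density_threshold = 0.15` (relative to the modal bin) are
  grouped into connected components, and the component holding the largest
  pixel mass is taken as the skin locus. The mass rule reflects the
  acquisition setting this tool targets — tightly cropped frontal
  photographs in which skin is the dominant content — and rejects dense
  but smaller background modes.
* **Mixture rule.** A two-component diagonal-covariance Gaussian mixture is
  fit to (Rg, By) (on a seeded subsample of at most 2000 pixels for
  speed; posteriors are evaluated for all pixels). The skin component is
  the one whose members lie at higher in-region histogram density; pixels
  with posterior above `gmm_posterior_threshold = 0.5` pass.

The default fusion is OR (detection-favoring, to cope with the variety of
skin tones); AND is available by configuration. The smoothing width and
relative threshold sit in the middle of the plateau on which the detector
is insensitive to class, severity, and luminance profile; too little
smoothing lets a bimodal skin distribution (a morbid patch color plus the
basic skin color) split into two components, while too low a threshold
lets downscaling-blended boundary pixels bridge skin to the background
mode.

Lips overlap skin in chromaticity and are the classic false detection, so
a rectangular mouth box — supplied per image (the synthetic fixtures carry
one; for real data any external mouth detector can produce it) — is simply
subtracted from the mask. Finally, pixels below the 1% or above the 99%
luminance quantile are dropped (`low_tail`/`high_tail`), which removes
dark moles, stray hair, and specular highlights.

## Two-level chromaticity bases

A face's skin chromaticities typically form *two* clusters: the person's
basic skin color and (for a morbid face) the disease-related color, which
in mild cases is the **minor** cluster. Taking each image's dominant
cluster as "the" facial color therefore fails on mild cases. The two-level
construction avoids this:

1. *Pixel level*: per image, fuzzy c-means with $c=2$ (fuzzifier $m=2$,
   tolerance $10^{-5}$, at most 300 iterations, seeded random membership
   initialization) on the (a, b) values of skin pixels yields a dominant
   and a subdominant center, ordered by hard member count.
2. *Chromaticity level*: per class, the dominant **and** subdominant
   centers of all images (two points per image) are pooled and clustered
   again with $c=2$; the center with the greater number of members is the
   class base.

The class's shared morbid chromaticity accumulates across images
regardless of whether it was dominant in any single face, while each
basic-skin point is one vote among many. A face whose second pixel-level
cluster holds under 10% of its pixels is treated as unimodal — its
subdominant duplicates the dominant — so that tiny artifact clusters
(downscaling-blended boundary pixels, residual lip fringe) never enter
the pool, while any genuine minor facial color far exceeds that share. Clustering uses only (a, b):
bases are chromaticity objects, and luminance is layered on afterwards as
sub-bases. White and black carry no base — their chromaticity gamut
overlaps normal skin — and are recognized through the luminance sub-bins
instead.

Member-count ties in `largest_cluster` are broken deterministically by
lexicographic center order. One degeneracy is worth knowing: if *every*
image of a class is bimodal (morbid color always minor, never absent), the
pooled point set contains exactly one morbid and one basic point per
image, the second-level counts tie, and the tie rule decides. On cohorts
with any severity spread — where the most severe faces are fully covered
by the morbid color and hence contribute two morbid points — the morbid
cluster genuinely outnumbers basic skin and the construction is stable.
The synthetic cohorts' default severity ramp includes such faces because
clinical cohorts do.

The single-level baseline (`single_level_baseline`) reproduces the older
dominant-color-only construction: one FCM pass per image, keep the larger
cluster, average over images. On minor-cluster cohorts it collapses onto
basic skin; the package keeps it for exactly that comparison, with the
four-bin peak classifier (`classify_by_peak`) as the accompanying
SVM-free evaluation.

## The complexion histogram

Pixels are assigned to the nearest base by Euclidean (a, b) distance; the
luminance axis from `lum_lo = 25` to `lum_hi = 95` is divided into
$K = \lfloor 70 / \text{interval} \rfloor$ sub-bins. With
`include_base_bins = TRUE` the feature vector holds, per base, one
aggregate bin plus its $K$ sub-bins: $4K + 4$ features. This layout
reproduces every dimension the method's development traverses — 40
(coarse 0–100 range, interval 10, sub-bins only), 24 (refined 25–95,
interval 14), 12 and 284 (sweep endpoints, intervals 35 and 1), and 120
(five fused regions × 24). The default interval of 14 was the sweep's
optimum in the original development; `interval_sweep()` re-runs that
experiment on any cohort. Luminance values outside the range are clamped
into the boundary bins so normalization stays exact. Histograms are
normalized by pixel count — aggregate bins sum to 1 and sub-bins sum to 1
— and are **not** rescaled per dimension before the SVM, because the
values are proportions on a common scale and rescaling would destroy
them.

For the regional variant, the skin mask is closed morphologically (square
element, side ≈ 3% of the bounding-box height, minimum 3), the bounding
rectangle is split by fixed fractions — forehead: rows 0–33%; cheeks and
nose: rows 33–75% with columns 0–35 / 35–65 / 65–100%; jaw: rows 75–100%
— and each block is intersected with the mask. The five regional
histograms are concatenated after scaling by weights (0.3, 0.3, 0.1, 0.1,
0.2): cheeks carry the most diagnostic signal, the jaw some, forehead and
nose least. Because the weights sum to 1, the fused vector's total
aggregate mass is already 1 and no renormalization is applied (the split
fractions are this package's own choice; only the weights are inherited).
Classifier-level fusion — five regional SVMs whose votes are combined with
the same weights — is also provided.

## Recognition protocol

`train_svm` is a one-against-one RBF SVM (libsvm via e1071): 6 classes →
15 binary models, majority vote. $C$ and $\gamma$ are searched over powers
of two spanning $2^{-8}..2^{15}$ and $2^{-8}..2^{8}$. Two protocol details
are deliberate:

* The default exponent step is 2 (a 12 × 9 grid) with 3-fold stratified
  inner cross-validation per leave-one-out fold; step 1 is available via
  `svm_grids(step = 1)`. Model selection is *honest*: the held-out image
  never influences the chosen parameters. The development history of this
  method permits an optimistic reading in which parameters are chosen per
  fold by test outcome; `paper_protocol = TRUE` reproduces it for
  comparison, and it is not the default.
* In every leave-one-out fold the four bases are **rebuilt from the
  training images only** and all features are re-extracted against them,
  so no information from the held-out image leaks into the representation
  (a dedicated test perturbs the held-out image and asserts the fold's
  bases are unchanged).

Evaluation reports the confusion matrix (rows actual, columns predicted)
with row-normalized (recall) and column-normalized (precision) views,
per-class precision/recall/F, micro averages (TP/FP/FN pooled over
classes) and macro averages (per-class means), with $F_\beta$ at
$\beta = 1$. Empty denominators yield 0.

## Degree ranking

After recognition, two unsupervised rankings are computed:

* **Color degree** (chromatic classes only; white/black have no base):
  each subject's proportion of pixels on their predicted class's base,
  min–max normalized *within* the predicted-class group. A constant group
  (or a single subject) maps to the midpoint 0.5.
* **Gloss degree** (all classes): the four bases of the histogram are
  merged into a pure luminance distribution; the gloss score is
  $\sum_j w_j h_j$ with non-decreasing weights, by default
  $w_j = \text{bin-center}/100$ — the minimal choice satisfying the
  brighter-is-glossier principle — then min–max normalized across the
  whole cohort.

For region-fused features the five weighted blocks are summed back into
one whole-face histogram before ranking. `ranking_coordinates()` exports
the (color degree, gloss degree) table. Min–max ranking is invariant to
any strictly increasing rescaling of the raw scores, so the degrees are
rankings, not calibrated severities; no expert-validated ground truth for
degrees exists, which is why the package validates them by parameter
recovery on synthetic gradients only.

## The synthetic-face generator

Clinical images of this kind are not publicly available, so the package
ships a generator whose fixtures carry full ground truth (skin mask,
mouth box, planted chromaticity, severity, luminance profile). A fixture
is an elliptical skin region filling most of a 256 × 256 frame — tightly
cropped, as clinical facial photographs are — on a dark bluish backdrop
with strong luminance texture (so its log-opponent locus is diffuse).
Skin pixel chromaticities mix the class's planted (a, b) center (weight
`minor_fraction`) with a shared basic-skin chromaticity (13, 16),
with Gaussian noise of 2.5 Lab units; luminance is Gaussian with
class-dependent mean (60 for the chromatic classes, 80 for white, 38 for
black; SD 7). The planted centers — cyan (−2, 8), red (26, 14), yellow
(12, 30), normal = basic skin — are mutually separated by at least 10
Lab units. Mole disks and hair strands are near-black artifacts; a lip
ellipse of overlapping chromaticity sits inside the mouth box. Lab values
render to RGB through the analytic CIELAB inverse; out-of-gamut pixels
get their luminance remapped into range (as highlight/shadow
desaturation) and the generator errors if more than 1% would still clip.

Two generator choices matter scientifically:

* **Morbid color is spatially coherent.** The minor indicator thresholds
  a smoothed random field (patch scale ≈ 16 px), not per-pixel noise —
  real morbid coloration is regional, and independent per-pixel mixing
  would be annihilated by the 8-fold block-average downscale.
* **Severity varies within a class.** The default cohort ramps
  `minor_fraction` from 0.45 up to 1 (capped), so the most severe ~15%
  of each chromatic class is fully covered by the morbid color. With
  `degree_gradient = TRUE` the ramp is strictly linear over 0.4–1 and
  luminance means ramp ±10 around the class mean, making the true
  color/gloss orderings known by construction.

What the generator does **not** emulate: facial geometry and landmarks,
texture, illumination gradients, ethnicity-dependent basic skin tones,
camera noise, or compression artifacts. Passing tests therefore show that
the pipeline's machinery is correct under its stated model — pixel
mixtures in Lab space with known parameters — not that clinical accuracy
figures transfer to real patients.

## Problem sizes and numerical conventions

The validation suite uses the cohort scale of the original study — 122
subjects (24 normal, 15 cyan, 18 red, 24 yellow, 21 white, 20 black) — at
256 × 256 pixels per face (downscaled 8-fold in the pipeline), 20-image
classes over 20 replicates for the minor-cluster recovery experiment, and
12 subjects per class for degree gradients. Tie-breaks are fixed
throughout: lexicographic center order in `largest_cluster`, canonical
class order in `classify_by_peak` and SVM voting, smaller $C$ then
smaller $\gamma$ in the grid search, highest-weight region (region order
within equal weights) in classifier fusion. FCM assigns a point
coinciding with a center full membership there; its objective trace is
asserted non-increasing in the tests. All randomness — generator fields,
FCM initialization, GMM subsampling, inner folds — derives from explicit
seeds, and re-running any stage with the same inputs and seeds reproduces
outputs byte-identically.

## Known limitations

* The skin detector's LO dialect, histogram/mixture thresholds, and the
  region split fractions are this package's documented choices where the
  method's lineage leaves them unspecified; they were engineered for
  robustness on the generator's image model and may need retuning for
  other acquisition setups.
* Color degrees are undefined for white/black subjects by construction.
* Under a cohort in which *every* image shows the morbid color as a
  minor cluster at the same fraction, the second-level member counts tie
  exactly and the recovered base for a class whose planted center is
  lexicographically larger than basic skin falls back to basic skin (red,
  in the default constants). The medians over classes and replicates
  remain well inside tolerance; cohorts with any severity spread do not
  exhibit the degeneracy.
* Device color correction, chromatic adaptation, and gloss
  *classification* are out of scope.
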