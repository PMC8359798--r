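---
title: "Methods: image-based cephalopod beak identification"
author: "beakid authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based cephalopod beak identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beakid)
```

## The problem

Cephalopod beaks are chitinous mouthparts that survive digestion, so they are
routinely the only identifiable prey remains in predator stomachs. Their shape
and pigmentation are species-specific, which makes photographic identification
feasible: a beak is photographed in left-lateral view on a white lightbox, the
dark silhouette is segmented by a global grey-level threshold, and descriptors
of the silhouette's texture (histograms of oriented gradients, HOG) and
geometry (ten morphological shape descriptors, MSD) — or deep features from a
pre-trained convolutional backbone — feed a supervised classifier. `beakid`
implements this pipeline end to end, together with a synthetic image generator
that supplies labelled data with known ground truth for every stage.

## The synthetic generator

`generateBeakImage()` renders a stylized hooked-crescent silhouette built from
three implicit lobes (a hood ellipse, a posterior wing ellipse and a rostral
hook disc) minus a notch that carves the hooked rostrum profile. Species enter
through `SpeciesShape` parameters: hood-to-wing ratio (drives the bounding-box
aspect ratio), wing length fraction, rostrum curvature, nominal size range, and
a pigmentation model in which grey level rises linearly with normalized
distance from the rostrum tip (tanned chitin is darkest at the tip). Per-image
randomness (size, position, small rotation, pixel noise) is drawn from a seed
derived deterministically from the dataset seed, so a configuration is
reproducible byte for byte.

Two constructions are deliberate:

* **Separability by construction.** Object grey levels are clamped below 236
  and background levels inside the configured range within [240, 255], so
  threshold-240 segmentation recovers the emitted ground-truth mask exactly
  (before smoothing). This turns the segmentation stage into a testable
  contract rather than an approximation.
* **Working resolution.** Images default to 532 x 299 px, the resolution the
  study protocol reaches after downscaling 5312 x 2988 camera originals to
  10%. Every downstream constant (128-px HOG cells, the 240 threshold) is
  defined at this resolution, and nothing the descriptors measure lives in the
  discarded pixels, so the generator emits working-resolution rasters directly
  and the pipeline's rescale factor defaults to 1 (0.1 is the documented
  setting for full-resolution photographs).

The default cohort mirrors the study collection: 174 samples of seven species
— four squid species (96 samples), two cuttlefish (49) and one octopus (29).
Per-species counts are not published, so taxon totals are split evenly
(24 x 4, 25 + 24, 29); this preserves the published totals and the class
imbalance. What the generator does **not** emulate: camera optics, shadows,
specular highlights, partially digested or damaged beaks, and operator
cropping. Passing tests therefore demonstrate correctness of the pipeline's
mechanics and its behaviour on well-separated classes, not field accuracy on
real photographs.

## Imaging

Greyscale conversion uses the luma transform
$Y = 0.299R + 0.587G + 0.114B$, kept in floating point. Thresholding at 240
supports both polarities: the protocol text assigns 240–255 to the object,
which contradicts a dark beak on a white lightbox, so `binarize()` defaults to
`dark` (object below threshold) and offers `bright` to match the text
verbatim. Gaussian smoothing (default sigma 1 px, radius `ceiling(3*sigma)`,
replicate borders, `sigma = 0` is the identity) is a conventional light
denoise; the protocol does not state its parameters. Rescaling rounds each
target dimension half-up, so 5312 px at 10% gives 531 px (the protocol prints
"approximately 532"; no exact-width assertion is made).

Object pixels are treated as 8-connected (background 4-connected), the
standard pairing for Moore boundary tracing; contours are closed, clockwise in
image coordinates (x right, y down), with 0-based pixel-centre vertices. The
ROI is the largest contour by shoelace area above a minimum-area floor that
discards noise specks.

## HOG descriptors

Gradients use the centred-difference kernel (-1, 0, 1) with replicate borders;
magnitude is $\sqrt{G_x^2 + G_y^2}$. The orientation default is the standard
unsigned $\mathrm{atan2}(G_y, G_x)$ folded to [0°, 180°); the protocol's
printed ratio has the arguments transposed, which is most plausibly a
transcription slip, so that form is available behind `asPrinted = TRUE` rather
than as the default. Cells are 128 x 128 px (partial edge cells dropped), nine
bins with centres 0°, 20°, …, 160°, and each pixel's magnitude is split
linearly between the two nearest bin centres, circularly over 180° (hard
assignment available). Blocks of 2 x 2 cells slide with stride one cell; each
36-vector is L2-normalized, with all-zero blocks passed through as zeros.
Block normalization is not mentioned in the protocol, but without it the
scales inside hybrid concatenations are arbitrary; the canonical HOG choice is
used and stated here so that numbers are comparable. On a 532 x 299 image the
cell grid is 4 x 2, giving 3 blocks and a 108-feature descriptor. Colour HOG
computes per-channel gradients and lets the channel with the largest magnitude
supply each pixel's vote, leaving the length unchanged at 108.

## Shape descriptors

The ten MSD values are computed on the contour polygon (sub-pixel geometry)
rather than on pixel counts, which removes connectivity ambiguity from the
formulas: shoelace area, polygon perimeter, bounding-box aspect ratio
$w/h$, extent, solidity, equivalent diameter, circularity
$4\pi \cdot \mathrm{area}/(\mathrm{convex\ perimeter})^2$, rectangularity,
form factor $4\pi \cdot \mathrm{area}/\mathrm{perimeter}^2$ and narrow factor.
Two fidelity choices are worth flagging. The descriptor table's equivalent
diameter is printed as $(4 \times \mathrm{area})/\pi$ — without the square
root, so it carries px² units; it is implemented as printed, with
`standard = TRUE` switching to $\sqrt{4 \cdot \mathrm{area}/\pi}$ (the switch
propagates into the narrow factor). The bounding box is axis-aligned, under
which rectangularity $(w \times h)/(\mathrm{bounding\ box\ area})$ is
identically 1; both it and extent are kept because the descriptor table lists
both. Hybrid descriptors concatenate HOG first, then MSD: 108 + 10 = 118
features.

## Deep features

The three backbone adapters fix the published input/output conventions —
vgg19: 224 x 224 in, 4096 out (second fully connected layer); inceptionv3:
299 x 299 in, 2048 out; resnet50: 224 x 224 in, 2048 out (global average
pool) — with bilinear resizing and mean-RGB subtraction (ImageNet channel
means; 127.5 for the inception convention). The adapters instantiate seeded
random weights in a small convolutional stack (7x7/stride-4 conv, ReLU,
3x3/stride-2 conv, ReLU, global average pool, dense projection to the feature
dimension). Random weights fix everything the offline tests assert — input
handling, output dimensionality, manifest ordering, determinism — while
pretrained weights, which would carry accuracy, require a download and are
therefore rejected with a named "backbone unavailable" error rather than
silently substituted.

## Classifiers

Eight classifiers sit behind one build/fit/score contract, each configured
with the benchmark hyperparameters: ANN (one hidden layer of 30 neurons, at
most 200 iterations), SVM (C = 30, sigmoid kernel, one-vs-one), RF (100 Gini
trees, sqrt-features), DT (information-gain splits, depth 2), kNN (k = 8,
Euclidean, uniform weights), multinomial LR (C = 0.15), LDA (SVD solver,
tolerance 1e-4) and Gaussian naive Bayes (variance smoothing 1e-9). Backends
are the established R implementations (`nnet`, `e1071`, `randomForest`,
`rpart`, `caret::knn3`, `nnet::multinom`, `MASS::lda`, `e1071::naiveBayes`).
Mapping notes, stated once here:

* The ANN is `nnet`'s single-hidden-layer network, which optimizes by BFGS
  with logistic hidden units; the configured learning-rate key is stored but
  inert under that optimizer. Size and iteration budget are honoured.
* LR's squared-L2 penalty maps to `multinom`'s weight decay as `1/C`.
* LDA is listed with a C parameter it does not possess; it is ignored with a
  warning. Features with (near-)zero pooled within-group variance are dropped
  before the fit (the discriminant is undefined along them; rectangularity is
  such a feature by construction), and the SVD solver's rank truncation
  handles collinear HOG blocks.
* `naiveBayes` has no variance floor, so the floor
  `varSmoothing * max(feature variance)` is added to the stored per-class
  variances after fitting.
* Feature scaling is not stated in the protocol; z-score standardization
  fitted on the training rows only is applied by default (ANN/SVM/kNN are
  scale-sensitive) with an off switch. Zero-variance columns scale by 1.
* Scores are class probabilities where defined; the SVM, configured without
  probability calibration, reports one-vs-one vote shares in [0, 1].
  Hard labels are the row argmax with ties resolved to the lowest class
  index.

## Evaluation protocol

"Five-fold cross-validation stratified shuffle split, tested 10 times" is
internally contradictory — shuffle splits are not partitions — and is read as
the only consistent interpretation: per run, five independent stratified
80/20 shuffle splits; ten runs; 50 fits in total. Per-class test counts are
the largest-remainder rounding of `classCount * 0.2` against an overall test
size of `round(n * 0.2)` (ties by class order), so every class's test
proportion is within one sample of 20%; at the 174-sample cohort this
allocates exactly 35 test samples. Fold f of run r draws with seed
`baseSeed + 1000r + f`.

Accuracy is trace/total of the confusion matrix (the binary
TP/TN formula's multiclass generalization); reports state the mean and
standard deviation over all 50 folds as proportions (the published "±" values
do not state their units or aggregation level; over-all-folds is used and
labelled). Precision and recall are one-vs-rest per class. PR curves pool the
test scores over all folds, and the AUC is the step-wise average precision
$\sum_i (R_i - R_{i-1}) P_i$ — not trapezoidal interpolation, which is known
to be optimistic in PR space. Multiclass PR is one-vs-rest per class with a
macro average.

## Problem sizes and numerical choices

The study-scale checks run the full default cohort: 174 generated images,
hybrid (118) and grey-HOG (108) features, 50 ANN fits each — a few minutes on
one CPU; unit and property tests use small rasters (≤ 64 x 64 for the
per-pixel HOG oracle, 1e-9 relative agreement) and reduced datasets. Other
numerical choices: HOG orientation at exactly a bin centre contributes wholly
to that bin (interpolation weight 0 to the neighbour); zero gradients are
assigned orientation 0; degenerate precision/recall denominators return 0
with an explicit flag; the ROI selector raises a named error when no contour
passes the area floor; collinear-feature warnings are handled where the
backend tolerates them.

## Known limitations

The generator's silhouettes are stylized — two-lobe crescents, not digitized
beak outlines — so absolute descriptor values are not comparable to real
beaks, only the pipeline mechanics and class-structure properties are. The
end-to-end accuracy floor (≥ 0.90 for ANN on hybrid features) holds for
well-separated synthetic species and says nothing about accuracy on real
photographs, where published figures were obtained with pretrained deep
features and 174 real images. Pretrained backbones are intentionally not
bundled; plugging them in requires only an adapter honouring the
`BackboneSpec` contract.
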