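---
title: "Methods: synthetic cohorts, detection post-processing, and lesion-level evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic cohorts, detection post-processing, and lesion-level evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slidemets)
```

`slidemets` packages the computational machinery of a breast-cancer
lymph-node metastasis detection study — from cohort construction through a
fully convolutional detector to lesion-level statistical evaluation — in a
form where every step can be exercised and verified at desk scale. This
vignette is the package's own account of the models and procedures, the
parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic data can and cannot tell you about
real slides.

## The problem and the quantities measured

A whole-slide image (WSI) is a gigapixel scan of a stained lymph-node
section. A patch classifier applied fully convolutionally produces a
*heatmap*: a tumor-probability raster at a coarser grid than the slide.
Clinical interpretation happens at two levels:

* **Slide level.** A slide is called positive if it contains a
  micro-metastasis (deposit > 0.2 mm and ≤ 2 mm) or a macro-metastasis
  (> 2 mm). Deposits of ≤ 0.2 mm are isolated tumor cells (ITC) and count
  as node-negative under TNM. The slide score is the maximum heatmap value
  over retained detection regions, and discrimination is summarized by the
  area under the ROC curve (AUC), computed as the Mann–Whitney statistic
  with ties counted one half.
* **Lesion level.** Each detection point is a true positive if it falls
  inside a ground-truth lesion outline and a false positive otherwise;
  lesions hit by no point are false negatives. The FROC curve traces lesion
  sensitivity against the average number of false-positive points per
  metastasis-free slide, and the FROC score is the mean sensitivity at six
  predefined false-positive rates: 1/4, 1/2, 1, 2, 4 and 8 per slide.

Both metrics get 95% percentile-bootstrap confidence intervals (resampling
slides with replacement) and differences between datasets or models are
assessed by permutation tests on the absolute difference of the statistic.

## Cohort construction

`study_composition()` encodes the study's published per-dataset
composition: two CAMELYON multicenter sentinel-node sources and two local
datasets (sentinel and axillary-dissection procedures), with per-split
target counts, the 16 ITC-only positives excluded before analysis, and the
nine extra-nodal "enrichment" negatives fixed to training (6) and
validation (3). `build_manifest()` expands this to one record per slide,
`exclude_itc()` removes ITC-only records (idempotently, preserving order),
and `stratified_split()` assigns splits by exact-count sampling within
(dataset, class) cells. Exact counts rather than per-slide Bernoulli draws
were chosen because the published split tables are not exact fractions of
the totals; sources that ship pre-generated splits keep them.

Where a composition does not record the micro/macro breakdown of its
positives, records carry the coarse label `"positive"`; synthetic manifests
always carry the exact size class.

## The synthetic-data generator

The generator stands in for the WSI archives and the trained base model.
It emulates exactly the statistical structure the analysis consumes, and
nothing more:

* **Slides** are square (default 20 mm at a working raster spacing of
  16 µm/px for cohort assets; the recorded level-0 spacing is 0.5 µm/px).
  Tissue is a centered ellipse covering ~85% of the extent with a smooth
  low-frequency intensity texture; there is no H&E color or scanner-artifact
  simulation. Patches are rendered with a class-dependent chromatic shift
  plus fine-scale noise — enough structure for a classifier to learn, not
  histology.
* **Lesions** are ellipses parameterized by their major axis — the one
  geometric property the TNM rules consume. Diameters are drawn uniformly
  per size class: ITC (0.05–0.18 mm), micro (0.3–2 mm), macro (2.5–8 mm by
  default, narrowed in small-extent runs). The micro/macro ranges keep a
  guard band away from the 0.2 and 2 mm decision boundaries so the planted
  size class survives rasterization at the working spacing; without the
  band, a lesion planted at 0.201 mm could legitimately measure 0.199 mm
  on the raster and flip its class, making planted truth unrecoverable by
  any implementation.
* **Annotations** are 64-vertex polygons inscribed in the lesion ellipse,
  exported as ASAP-dialect XML. Heatmap lesion interiors are rasterized
  *from the polygon* (pixel centers inside the polygon), so every in-lesion
  heatmap pixel is inside the exported annotation and a detection point in
  a recovered lesion always scores as a hit — the same point-in-polygon
  test is used on both sides.
* **Heatmaps** draw in-lesion and background scores from clipped normal
  distributions (`c(location, spread)`; spread 0 gives a constant — the
  "perfect detector" used for planted-truth recovery). False-positive
  confounder blobs arrive at a Poisson per-slide rate, each filled with one
  score; preset rates of 35 and 1.3 per slide emulate the false-positive
  burden of an unadapted and a locally retrained detector. Lesions never
  overlap each other and blobs never touch lesions or each other
  (rejection sampling with a clearance margin), so the detection count and
  every region score are analytically known. A blob that cannot be placed
  on a crowded small raster is dropped rather than misplaced, keeping the
  planted table faithful to the raster. The real model-output score
  distribution is not characterized anywhere; these distributions are
  stand-ins and are fully exposed in `heatmap_spec()`.
* **Determinism.** Every generator is a pure function of `(seed, index)`;
  per-slide and per-epoch streams derive from the master seed by a fixed
  integer hash, and all randomized functions restore the caller's RNG
  state.

What passing tests on this generator demonstrate: the *analysis machinery*
(post-processing, sizing, labeling, metrics, inference) is correct against
enumerable ground truth. What they do not demonstrate: detection
performance on real histology, stain variation, scanner artifacts, ILC
morphology, or annotation noise — none of which the generator attempts.

## Detection post-processing

Heatmaps are thresholded at 0.5 (score ≥ threshold retained) — the single
operating point used project-wide, including for hard-negative mining —
and components are labeled with 8-connectivity, which avoids splitting
diagonally connected blobs. Each region's *diameter* is the major-axis
length of its moment-matched ellipse (`4·sqrt(λmax)` of the pixel-center
covariance, scaled to millimeters), which equals the true diameter for a
filled disc or ellipse and matches the pathologist's long-axis convention.
The detection *point* is the region's score argmax; among tied maxima the
pixel nearest the region centroid is taken, so flat-topped regions yield an
interior point.

Two boundary conventions deliberately differ and are unit-tested:
detections with diameter *less than* 0.2 mm are excluded (a region of
exactly 0.2 mm is retained), while hard-negative mining keeps regions
*larger than* 0.2 mm (exactly 0.2 mm is not mined), and the TNM label rule
calls exactly 0.2 mm ITC — so a retained 0.2 mm region still yields a
negative slide label. Whether ground-truth "overlap" in mining means pixel
or bounding-box overlap is unstated in the protocol; pixel overlap is
implemented (one shared pixel disqualifies a region).

The automatic slide label applies the TNM rule to the largest retained
detection; the slide score is the maximum retained region score, 0 when
nothing is retained. Regions export to ASAP-dialect XML (convex hull of
the region's pixel centers, slide micrometers, origin top-left) for review.

## The network

The classifier is a DenseNet-style stack with valid padding everywhere:
3 dense blocks of four 1×1 (64-channel) and three 3×3 (32-channel)
convolutions in alternation, each 1×1 receiving the channel concatenation
of the block input and all preceding 3×3 outputs center-cropped to the
current size; a transition block (1×1 convolution + 2×2 average pooling,
stride 2) after each block but the last; a final 3×3 convolution to class
scores; batch normalization and ReLU after every convolution except the
final one, which gets a soft-max; He initialization; 279 px input patches
at 0.5 µm/px. All of these dimensions scale down (`network_config()`), and
tests run tiny instances.

Open wiring details were fixed as follows and verified against the
package's own layer-arithmetic oracle (`output_shape()`), since the source
architecture's cropping details are not printed anywhere: center-cropping
of skip tensors is forced by valid padding (all crops are even because
sizes shrink by 2 per 3×3); pooling uses stride 2 with floor, dropping the
last row/column of odd inputs; training supervises the center position of
the output map, consistent with center-pixel patch labels. Valid padding
makes patchwise and fully convolutional inference agree exactly, so tiled
slide inference with stride-aligned tile origins reproduces the untiled
heatmap to floating-point summation order; the heatmap grid has spacing
`input spacing × 2^(blocks−1)` and an offset placing each output at the
center of its field of view.

No autodiff framework is involved: forward and backward passes (im2col
convolutions via BLAS matrix products, batch-norm, pooling and dense-block
concatenation gradients) are implemented in the package and validated by
central-difference gradient checks in development and by overfitting
contracts in the tests.

## Training

Optimization follows the study schedule: Adam (framework-default moments
0.9/0.999, eps 1e-8 — the study states only the learning rate) from
1e-4, categorical cross-entropy plus L2 weight decay of 1e-4 on
convolution weights, rate divided by 10 after 4 consecutive epochs without
validation-accuracy improvement, early stopping after 20, at most 200
epochs, best-validation checkpoint returned. "Improvement" is strict
(`>` the best so far) — the conservative convention. The schedule is a
pure function of the validation-accuracy sequence (`lr_schedule()`), so it
is testable without training. Validation accuracy is patch accuracy;
validation patches are resampled with a fixed per-epoch seed sequence so
epochs are comparable.

Each epoch samples patches with a 20/80 tumor/healthy ratio (class first,
then a pixel of that class with probability proportional to its weight).
The full-scale default is 262,144 patches per epoch for training and
validation individually; tests and the toy pipeline use a few thousand at
most — the statistical contracts (realized fractions within binomial
bounds) are scale-free. The three retraining strategies compose in the
sampler: `scratch_pooled` vs `finetune_local` transfer, uniform vs
local-upweighted source sampling (per-pixel weight multiplier), and
hard-negative mining (code-3 pixels oversampled by a configurable weight
among healthy draws; with no mined pixels anywhere the sampler is
draw-for-draw identical to mining disabled).

Augmentation applies, in fixed order: horizontal flip; rotation by
0/90/180/270°; scaling in [0.9, 1.1] (bilinear, center crop or
edge-replicating pad back to size); hue [−0.1, 0.1] and saturation
[−0.25, 0.25] offsets in HSV (the ranges are unitless fractions);
additive brightness and multiplicative contrast in [−0.25, 0.25] in RGB;
Gaussian noise with sd in [0, 0.05]; Gaussian blur with sigma in [0, 1] px
(sigmas below 0.05 px are identity). Parameters are drawn uniformly,
logged per patch, and the all-identity draw reproduces the input exactly;
output is clipped to [0, 1] and labels are untouched.

## Statistical inference

Bootstrap intervals are percentile intervals over 10,000 resamples of
*slides* (the dataset's sampling unit); resamples on which a statistic is
undefined — a single-class draw for AUC, no lesion or no metastasis-free
slide for FROC — are redrawn. FROC sensitivity "at" a predefined rate is
the maximum sensitivity over thresholds whose false-positive rate does not
exceed the target (step-function reading, no interpolation), and rates
beyond the curve's maximum reuse the terminal sensitivity, so a model with
few false positives is not penalized at generous budgets.

Permutation tests are two-sided on the absolute difference, with an
add-one correction, in two modes (the study does not state which was
used, so both are provided): unpaired shuffles slide-to-group assignment;
paired swaps the two models' per-slide predictions with probability one
half. Calibration is checked empirically in the acceptance suite: type-I
error within binomial bounds of 0.05 over 200 null replications (500
permutations each), and bootstrap coverage within binomial bounds of 95%
over 200 replications (500 resamples each) against a closed-form planted
AUC. No multiple-testing correction is applied, matching the study design.

## Problem sizes and numerical choices

The test and acceptance runs use deliberately small instances: 5–8 mm
synthetic slides at 16 µm working spacing (rasters of a few hundred pixels
square), cohorts of 10–100 slides, networks of 1–3 blocks with 3–8
channels, patch sets of tens to thousands, 100–500 bootstrap/permutation
replicates in unit tests and the criterion-mandated 200×500 in
calibration checks. These sizes make every contract checkable in seconds
to a couple of minutes while leaving the full-scale defaults (20 mm
slides, 0.5 µm patches, 262,144 patches/epoch, 10,000 resamples)
documented and reachable through configuration.

Other numerical choices: heatmap values are validated into [0, 1] and
float32 storage round-trips through a JSON metadata sidecar; region
moments use population covariance (a single-pixel region has diameter 0);
degenerate inputs fail loudly (slides too small for their lesions, split
targets exceeding cell counts, missing spacing metadata, finetuning
without a checkpoint, empty patch streams).

## Known limitations

The generator's appearance model is chromatic, not histological; nothing
here speaks to stain normalization or morphology-specific failure modes
(e.g. lobular carcinoma). The dense-block wiring fixes one self-consistent
reading of the architecture's skip connections; other croppings would
change parameter counts but none of the tested contracts. Full-scale
training (262,144 patches/epoch at 279 px) is far beyond a single CPU and
is exercised only at toy scale; the package asserts the training
*mechanics* (sampling proportions, schedule, convergence on separable
data), not full-scale detection skill.
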