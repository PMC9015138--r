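---
title: "Segmenting and classifying FDG-PET uptake volumes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting and classifying FDG-PET uptake volumes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Whole-body FDG-PET of lymphoma patients shows tracer uptake both in tumor
lesions and in a long list of physiological sites — brain, heart, kidneys,
urinary bladder, skeleton and bone marrow, salivary glands and other
head-and-neck soft tissue, gastrointestinal foci, genital organs and
activated brown fat. Measuring the metabolic tumor volume, or any texture
or heterogeneity marker of the tumor burden, first requires separating
tumor uptake from all of these mimics. `petlymph` implements an automatic
pipeline that does this in five stages: denoising and SUV conversion, a
heuristic cranio-caudal crop, watershed segmentation with
texture-similarity merging, a 31-feature radiomics description of every
segmented volume, and a random-forest classification into 14 tissue
categories evaluated by nested cross-validation.

## Preprocessing

Voxel intensities are denoised with an isotropic Gaussian filter,
$\sigma = 2.0$ in voxel units by default. The width is interpreted in
voxels because that is the convention of common discrete filter
implementations; a `sigma_in_mm` flag converts per-axis when physical
units are preferred. Smoothing runs *before* SUV conversion — the two
commute up to a scalar, but the stage order is part of the method and is
preserved. Convolution uses reflect padding so the high-uptake structures
at the scan ends (brain, bladder), which the cropping stage depends on,
are not dimmed by zero-padding.

SUV conversion uses the body-weight formula
$\mathrm{SUV} = c \cdot w / D$ with $c$ the activity concentration in
Bq/ml, $w$ the body weight in grams and $D$ the injected dose in Bq, so a
uniform water-equivalent distribution of the full dose gives SUV 1.
Activity values are assumed decay-corrected to injection time, as is
standard for clinical reconstructions; no decay handling is attempted.
Coronal maximum-intensity projections are produced for visual quality
control only — the pipeline makes no automatic accept/reject decision on
scans, since no objective validity criterion exists for that step.

## Cropping

Scan length varies across acquisition protocols (skull base to mid-thigh,
true whole body, ...), so scans are standardized by cropping along the
cranio-caudal axis between the two most reliable landmarks, brain and
urinary bladder. The heuristic:

1. project the SUV volume onto the xz-plane (maximum over y);
2. drop lateral extremities by keeping a symmetric band, 60% of the image
   width by default, centred on the column with the largest summed
   intensity (the body axis);
3. collapse to a 1-D profile of per-slice SUV maxima, cranial to caudal;
4. smooth the profile (1-D Gaussian, $\sigma = 2$ slices) and find local
   maxima; a peak is *significant* when its topographic prominence is at
   least 25% of the global profile maximum. The first and last significant
   peaks become the cranial and caudal crop anchors.

Maximum (not sum) projections are used in steps 1 and 3 because the
profile is defined as a function of SUV maxima. The prominence rule makes
"significant" concrete: brain and bladder both show distinct physiological
uptake well above the remaining profile, while prominence — unlike raw
height — also admits a bladder peak that sits on an elevated abdominal
baseline. Both constants are configurable.

Regions are kept only when their whole voxel extent lies *strictly*
between the two anchor slices; a region touching a boundary slice is
excluded, which deliberately removes the brain and bladder themselves
along with lesions straddling the anchors. When fewer than two significant
peaks exist the filter passes regions through with a warning (a strict
mode raises instead); the failure is surfaced rather than guessed around.
The known failure mode of the heuristic is a missing brain: the first
significant peak then falls at the salivary glands — or at a cranial tumor
— and everything above it is lost. The phantom generator reproduces this
on demand (`brain_absent`).

## Segmentation

Voxels with SUV below 2.5 are excluded; this fixed, sensitive threshold
keeps all potential tumor lesions at the price of many physiological
regions, which the classifier later sorts out. A flooding watershed on the
inverted SUV topography partitions the mask: basins are seeded at regional
maxima (26-connectivity, plateau-aware) and flooding proceeds in
descending SUV order. Watershed-line voxels — reachable from several
basins — are assigned to the neighbouring basin with the higher SUV
maximum, so the final labels exactly partition the mask; ties fall to the
lower label id for determinism.

Oversegmentation is repaired by texture merging. For each region a
grey-level co-occurrence matrix is accumulated over all 26 direction
offsets at distance one, restricted to voxel pairs inside the region, and
summarized by the mean of contrast, entropy (log2) and inverse difference
moment. Two 26-adjacent regions merge when their aggregated measures
differ by strictly less than 2. Merging is best-first: the most similar
adjacent pair merges, the merged texture is recomputed, and the process
repeats — a deterministic schedule under which the label count never
increases. SUV values are quantized for all texture computations into
fixed 0.5-SUV-wide bins anchored at the 2.5 threshold; absolute binning
keeps texture comparable across scanners, consistent with the absolute
segmentation threshold. Finally, regions smaller than 2.0 ml are dropped
(a region of exactly 2.0 ml is kept). The volume filter runs after
merging, so fragments that merge into a sufficiently large region
survive.

## Features

Each region is described by 31 features: 19 SUV-based, 6 shape-based and
6 spatial-location features.

* **SUV statistics** (max, min, mean, median, range, variance, energy
  $\sum v^2$, entropy, kurtosis, uniformity, mean absolute deviation,
  RMS, standard deviation, skewness). Moments are population moments
  (divide by $n$) so they stay defined for tiny regions; kurtosis is the
  Pearson form (normal $\to$ 3); skewness and kurtosis of a zero-variance
  region are defined as 0. Entropy and uniformity use the same
  0.5-SUV-bin histogram as the texture stage. Energy is the raw sum of
  squares, with uniformity as its histogram analogue.
* **NGTDM texture** (coarseness, contrast, busyness, complexity) in the
  Amadasun–King form standardized by the IBSI, computed on the quantized
  region with 26-neighbourhoods restricted to the region. A perfectly
  homogeneous region has $\sum_i p_i s_i = 0$; coarseness is guarded with
  $\varepsilon = 10^{-6}$ and reported as $1/\varepsilon$ there, and
  busyness falls back to 0 when its denominator vanishes.
* **Outside difference**: mean SUV inside the region minus the mean over
  a 1-voxel 26-connected dilation shell, excluding voxels of other
  segmented regions — uptake contrast against the local background.
* **Shape**: surface area by exposed-face counting (mm²);
  area-surface ratio $V/S$ (the bounded direction of the ratio);
  sphere-normalized compactness $36\pi V^2 / S^3$; maximum diameter as
  the largest Euclidean distance between voxel centres (attained on the
  surface, so only surface voxels are searched; surfaces above 1500
  voxels are deterministically thinned first); and *surface difference* —
  the mean over up to 500 seeded random surface-voxel pairs of Euclidean
  distance divided by geodesic distance along the 26-connected
  surface-voxel graph, 1 for convex surfaces and smaller for folded ones.
  A single-voxel region reports diameter 0 and surface difference 1.
* **Location**: the centroid as fractions of the cropped body bounding
  box (x and y over the body-mask extent, z over the crop interval), and
  the major-axis direction — the unit eigenvector of the largest
  eigenvalue of the region's second-moment tensor in mm, sign-fixed to
  non-negative z (then x, then y); an isotropic tensor reports +z.

Features are computed on the original grid in physical units and then
standardized to patient size: with $L$ the cropped body length in mm,
scaled volume is $V_{ml}/L^3 \times 10^6$, scaled surface area is
$S_{mm^2}/L^2 \times 10^4$, and the maximum diameter is divided by $L$.
SUV and texture features are quantized in absolute SUV and pass through
unchanged; centroid and axis features are already normalized. This
normalization avoids resampling the image itself and the interpolation
artifacts that would introduce. Surface-area estimates by face counting
are resolution-dependent at the discretization level; the scaled versions
remove the patient-size dependence, which is the dominant effect at
clinical resolutions.

## Classification

A random forest (500 trees by default) classifies regions into the 14
categories; the prediction is the majority vote of the trees, with ties
broken by the canonical class order. Forest training and prediction are
delegated to `ranger`; the vote with its documented tie-break is applied
on top of the per-tree predictions.

Nested cross-validation estimates performance without leaking model
selection into the test data. Per repetition the dataset is randomly
partitioned into three parts at *patient* level — regions of one patient
never straddle parts, preventing within-patient leakage; region-level
partitioning remains available by configuration. The parts rotate so each
is the test set once; for each rotation the inner step fits every
combination of the hyperparameter grid — maximum tree depth
$\{4, 8, 16, \infty\}$ and features per split $\{6, 10, 16\}$ (around
$\sqrt{31} \approx 6$) — on the training part, selects the pair with the
highest validation accuracy, and applies that fitted model to the test
part. Ten repetitions with fresh partitions are averaged: confusion-matrix
cells are averaged and rounded to integers, and each region's final label
is its modal prediction. A class absent from a training fold simply cannot
be predicted in that fold (it is logged, not fatal) — with a single liver
region in a realistic cohort this is the expected behaviour, and the
per-class accuracy of such rare classes is honestly poor.

All randomness — partitioning, forest seeds, surface-pair sampling —
derives from explicit seeds, and every library call runs single-threaded,
so identical configurations produce byte-identical outputs.

## Evaluation

The 14×14 confusion matrix is oriented rows = automatic, columns =
manual. Binary tumor metrics collapse it with tumor = {T, T+NT}: composed
tumor/non-tumor volumes count as tumor so that no tumor lesion is missed.
Sensitivity, specificity, PPV, NPV and
$F_1 = 2/(\mathrm{sens}^{-1} + \mathrm{PPV}^{-1})$ are kept as raw
proportions internally and rounded to whole percent only at the reporting
layer. Per-tissue accuracy is the matrix diagonal over the manual column
sum, with the kidneys additionally pooled. Per-patient summaries count
false-negative tumor lesions and false-positive non-tumor volumes per
patient. The package ships a published reference confusion matrix from a
60-patient clinical Hodgkin-lymphoma cohort
(`clinical_confusion_matrix()`) against which all derived numbers are
reconstructed exactly in the test suite; one row label in the printed
source table ("HAT") is read as the heart row, an evident typo.

## The phantom generator

No public clinical dataset accompanies the method, so the package
includes a synthetic whole-body phantom generator that makes every stage
testable. A phantom is an elliptic-cylinder body (background SUV 1.0,
Gaussian noise sd 0.1) in air, on a 102×77×272 grid at 2.5 mm isotropic
spacing (≈ 68 cm of body), carrying class-specific blobs:

* brain (z ≈ 0.075 of the scan, SUV ≈ 7) and bladder (z ≈ 0.93, SUV ≈ 8) —
  the two crop anchors, rendered with centrally peaked interiors so their
  intensity maxima are stable landmarks;
* an elongated midline skeleton column, rendered as sequential rod
  segments along the spine (SUV ≈ 4.6);
* paired kidneys (SUV ≈ 6), heart (left-sided, SUV ≈ 5), head-and-neck
  foci, paired lateral brown-fat foci, scattered gastrointestinal foci,
  rare liver and genital blobs;
* ellipsoidal tumor lesions (SUV ≈ 8 ± 1, 3–15 ml) anywhere in the nodal
  stations, Poisson-distributed with mean 3.75 per patient plus a 35%
  chance of a composed tumor/non-tumor volume — about 4.1 tumor lesions
  per patient;
* composed volumes (T+NT, NT+NT) as two overlapping lobes of different
  SUV sharing one ground-truth region.

Blobs are flat-topped: a plateau at the class SUV declining to a fixed
edge level of 4.0 at the nominal boundary, with a short Gaussian tail
(1.2 voxels) beyond. The edge level is chosen so that after denoising the
2.5-SUV contour sits at the truth boundary — the blurred edge midpoint
$(4.0 + 1.0)/2 = 2.5$ equals the segmentation cut — making the nominal
blob volume the segmentable volume. Uptake texture is multiplicative
log-normal noise with class-specific amplitude (tumors and
gastrointestinal foci rough, skeleton and brain smooth). Placement is
rejection-sampled so that blobs keep a 7-voxel margin, preventing
denoising halos from bridging distinct structures. Per-patient counts
roughly mirror the class frequencies of a clinical cohort
(skeleton-heavy; liver, genital, bladder and composed volumes rare), so
the classifier faces the same rare-class stress cases. A configurable
fraction of cohort patients (15% by default) lacks the brain, exercising
the cropping failure mode.

What the phantom deliberately does *not* model: scanner point-spread
functions beyond the denoising blur, attenuation, scatter, reconstruction
artifacts, organ shapes beyond ellipsoids and rods, and continuous
anatomical context (e.g. the spine is a chain of separated segments, not
one connected column). Passing the phantom-based tests therefore shows
the pipeline machinery is correct and that classes separable by SUV
level, shape and location are recovered — it does not certify clinical
performance, which depends on uptake patterns the phantom idealizes away.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline on a
60-patient phantom cohort (≈ 700–900 regions), matching the scale of the
reference clinical cohort; texture-oracle comparisons use exhaustive
brute-force enumeration on regions up to 4×4×4, where exact agreement is
asserted. Watershed and profile peak detection are exact integer/float
computations with documented tie-breaks; the only stochastic elements are
the phantom draws, data partitioning, forest training and surface-pair
sampling, all seeded. Degenerate inputs follow documented conventions:
empty masks yield empty labelings, single-voxel regions have defined
shape features, flat profiles yield not-found crop boundaries, and
single-class training sets degenerate to a constant classifier with a
warning.

## Known limitations

* The crop heuristic requires both anchors; scans missing the brain crop
  at gland level (or at a cranial lesion) and lose everything above.
* Composed volumes are classified as a whole; no splitting of merged
  tumor/organ regions is attempted.
* Tiny classes (single liver region, a handful of genital/bladder
  volumes) cannot be learned reliably and their per-class accuracies are
  reported as the honest near-zero values.
* The SUV threshold, merge threshold and minimum volume are fixed
  clinical choices, not tuned parameters; adaptive thresholds
  (%SUVmax, background-relative) are out of scope.
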