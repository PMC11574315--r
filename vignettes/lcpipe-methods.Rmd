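---
title: "Methods: annual land-cover mapping from irregular satellite time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annual land-cover mapping from irregular satellite time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The mapping problem

`lcpipe` implements an annual land-cover mapping pipeline for optical
satellite time series whose observation record is irregular: acquisition
dates differ between pixels and years, clouds remove observations at
random, and the archive density changes by a factor of three to four
between the Landsat-only era and the years in which Sentinel-2 also
observes. The pipeline classifies every pixel every year into a
hierarchical legend of 8 general classes (Level 1) refined into 18 final
classes (Level 2): six stable surface types, three wetland subtypes
(marsh, exploited and unexploited peat bog), and nine
cropland/grassland classes (eight crop types plus grassland). Map codes
run 1–18 with 0 as nodata.

All stages operate on a 30 m analysis grid in a projected CRS
(EPSG:3035 by default), tiled into 30 km processing tiles.

## Weekly temporal encoding

Each pixel-year is represented as a fixed 52 × 9 matrix: 52 calendar
weeks by 9 features (six reflectance bands — red, green, blue, NIR,
SWIR1, SWIR2 — plus NDVI, NDWI and SAVI). All clear observations of a
week are averaged into that week's slot; weeks without a clear
observation hold exactly 0. The representation neither interpolates nor
compresses the series, and its length is independent of the observation
density, which is what lets one model serve both sparse and dense
years. The feature count is 52 × 9 = 468.

Numerical choices the encoder fixes:

* week index `floor((doy - 1)/7)`, capped at 51, so days 365/366 fold
  into the last week and the year maps onto exactly 52 slots;
* non-clear observations are ignored entirely;
* indices are computed from reflectance before averaging:
  NDVI = (NIR − red)/(NIR + red), NDWI = (green − NIR)/(green + NIR)
  (the green/NIR water-index form, which the water sampling rule's
  NDWI > 0.3 threshold presumes), SAVI with soil factor L = 0.5.
  Zero denominators yield 0 with a flag.

## Classifier

The classifier is a 1-D convolutional network applied along the
temporal dimension of the 52 × 9 input: three convolution blocks
(kernel length 5 weeks, ReLU, max-pool 2) with 32/64/64 filters, a
dense ReLU layer of width 128 with dropout 0.3, and a softmax head.
Training uses Adam (learning rate 1e-3), batch size 256, 30 epochs, and
inverse-frequency class weights. The default width is a capacity choice
for desk-scale scenes (a few thousand samples per model); all values
are configurable through `cnn_spec()`. Missing weeks enter as zeros with
no mask channel — robustness to missingness is learned, not encoded.

Two training-time augmentations harden the model against the
varying observation record:

* **random observation selection** — a keep fraction is drawn uniformly
  from [0.25, 1] per sample and epoch, and each clear observation is
  kept independently with that probability (at least one is always
  retained). The lower bound 0.25 makes a dense year (~30 clear
  observations) look like a sparse one (~8), which is exactly the
  density ratio between archive eras.
* **random day shifting** — one shared offset drawn uniformly from
  ±7 days shifts all dates of a sample; observations leaving day 1–365
  are dropped. A single shared offset models a phenological shift of
  the whole season rather than independent date jitter.

Samples that are invariant over a period carry one annual series per
year, and training draws one uniformly per epoch; crop samples use
their labeled year only.

### Hierarchical prediction

A Level-1 model (8 classes) routes each pixel: classes 1–6 pass through
to the final legend; Wetland pixels receive the argmax of a 3-class
wetland specialist (codes 7–9); Cropland-and-Grassland pixels receive
the argmax of a 9-class crop specialist (codes 10–18). Two specialist
models (rather than a single 18-class head) mirror the two subdivided
branches of the legend; the single-head alternative would be a
one-line change but is not implemented.

## Rule-based reference sampling

Training pixels for the ten non-crop-specific classes are mined from
multi-year reference-product stacks (imperviousness %, tree-cover
density %, forest-type codes, a coarse land-cover inventory code layer
and a finer protected-sites code layer, plus NDVI/NDWI percentile
layers). Each rule is a conjunction of per-pixel or focal conditions;
thresholds and strict/non-strict inequalities are transcribed exactly
(center imperviousness > 50 % with the 24 surrounding pixels > 20 %
for built-up; 90th-percentile NDVI < 0.3 for bareland;
10th-percentile NDWI > 0.3 for water; tree density > 75 % for forest,
< 30 % for shrubland; and so on), with the product epochs
{2006, 2009, 2012, 2015, 2018}, {2006, 2012, 2018} or
{2012, 2015, 2018} per condition. Decisions the rule engine fixes:

* percentiles use linear interpolation between order statistics
  (`stats::quantile()` type 7), so the 0.3/0.0 thresholds are
  reproducible;
* focal conditions quantify over every pixel of the window ("all") or
  every surrounding pixel ("ring"); windows touching the raster edge
  or nodata are ineligible, because an "all pixels" condition cannot
  be evaluated there;
* where a rule demands that both code products contain one of a set of
  classes, the two products must agree on the *same* subclass in each
  year (the lenient either-subclass reading would only enlarge the
  candidate set);
* up to 10,000 points per invariant class and 50,000 per crop class and
  year are drawn uniformly without replacement.

Pixels eligible for a rule are treated as invariant over 2006–2018,
which is what justifies training on a uniformly drawn year per epoch.

## Post-classification filters

Three single-purpose filters remove classification noise:

* **spatial majority (3 × 3)** — the center is replaced by the modal
  neighbour class only when it differs from *all eight* neighbours
  (the salt-noise reading; a simple-majority trigger would also smooth
  genuine boundaries). Ties between neighbour modes break to the
  smallest class code; the pass is single and evaluated on a frozen
  copy; border pixels and nodata windows are untouched.
* **temporal (3-year window)** — per pixel, windows run backwards from
  the last to the first year; a pattern (X, Y, X) becomes (X, X, X),
  with updates visible to the subsequent (earlier) windows. First and
  last years are never modified. Applied to Level-1 maps only.
* **spatio-temporal (3 × 3 × 3)** — for each year (backwards) and each
  3 × 3 patch (stride 1): if one class fills the patch completely in
  both bracketing years and at least 7 of the 9 center-year pixels
  already hold it, the whole center patch converts. Within a year all
  patch decisions are taken on a frozen snapshot (overlapping decisions
  cannot conflict, since the bracketing-year patches overlap too).
  Because a genuine crop rotation breaks the bracketing-year
  homogeneity, rotations survive; this is why Level-2 maps get this
  filter instead of the plain temporal one.

The "two patches of the surrounding years" are read as years t−1 and
t+1; the alternative any-two-of-three reading is not implemented.

## Accuracy and area estimation

Validation uses the stratified good-practice estimators with map
classes as strata. With stratum weights \(W_i = A_i / A_\mathrm{tot}\)
and error-matrix cell proportions \(\hat p_{ij} = W_i n_{ij}/n_{i\cdot}\):

* estimated area \(\hat A_j = A_\mathrm{tot} \sum_i \hat p_{ij}\), with
  the stratified standard error and a normal-approximation CI
  (z = 1.96 at 95 %);
* overall accuracy \(\sum_j \hat p_{jj}\), user's accuracy
  \(n_{ii}/n_{i\cdot}\), producer's accuracy
  \(\hat p_{jj}/\hat p_{\cdot j}\), each with the corresponding
  stratified variance.

Per-class F1 is the standard form TP/(TP + 0.5(FP + FN)), i.e. the
harmonic mean of user's and producer's accuracy. Classes absent from
both map and reference have undefined F1 and are reported as NA.
Validation points falling on nodata, outside the map, or in classes
absent from the map year are dropped with a logged count.

Annual class-area series are pixel counts times pixel area;
`compare_area_series()` reports raw and relative differences against an
external statistics table without smoothing.

## The synthetic-scene generator

Real imagery is out of scope, so every downstream stage is exercised on
synthetic scenes whose statistical structure matches the analysis
assumptions:

* **phenology** — each class has a per-band double-logistic annual
  curve \(v(t) = base + amp\,[\sigma(k_g(t-t_g)) - \sigma(k_s(t-t_s))]\)
  with additive Gaussian noise (default sd 0.02), clipped to [0, 1].
  Crop classes differ chiefly in green-up/senescence timing (winter
  cereals from day ~80–95, spring cereals ~125–135, maize and root
  crops late and long) and grassland stays green over the whole season.
  The defaults claim *class separability*, not spectral realism: a
  masked nearest-centroid oracle on encoded features attains ≥ 95 %
  accuracy at 20 clear observations/year, which is what makes the
  downstream recovery tests meaningful. The shrubland and grassland
  parameter sets were revised once during generator design after the
  first draft left them nearly colinear with each other and with
  broadleaf forest, violating that separability contract.
* **acquisitions** — the number of clear observations per pixel-year is
  Poisson (defaults ~8/yr for pre-2015 years, ~30/yr afterwards,
  mirroring the two archive eras); dates are distinct days drawn with
  probability proportional to a 52-week seasonal weighting (uniform by
  default).
* **landscape** — a Voronoi patch mosaic (or a user-supplied map) with
  persistent non-crop classes, crop *fields* (patches) rotating as
  units by a configurable row-stochastic matrix (default: arable crops
  persist with p = 0.4, otherwise rotate uniformly; grassland
  persistent) — per-field rotation keeps crop truth spatially coherent,
  which the spatio-temporal filter presumes — and
  unexploited-bog pixels converting to exploited bog at a configurable
  rate (default 2 pixels/year; capped with a warning when the bog is
  exhausted).
* **reference products** — derived from the truth map: imperviousness
  80 on built-up else 0, tree density 90/15/0, forest-type codes, and
  the two categorical code layers through fixed synthetic dictionaries,
  with configurable contamination and disagreement rates (0 by
  default). STM layers are the noise-free closed-form percentiles of
  each class's curve.

What the generator does **not** emulate — mixed pixels, geometric and
radiometric error, cloud-shadow structure, spatially correlated noise,
within-class spectral diversity, class imbalance at realistic
proportions — bounds what passing tests show: they demonstrate the
pipeline's correctness and its density-transfer property, not the
accuracy level attainable on real imagery.

## Problem sizes and reproducibility

The recovery benchmark uses a 40 × 40-pixel scene over 6 years
(dense profile, 30 obs/yr), a 70/30 stratified pixel split, and the
default training configuration; the sparse-transfer check re-simulates
the same landscape truth at 8 obs/yr and reuses the dense-trained
models. Filter and encoder verification run against brute-force oracles
on thousands of random 5 × 5 × 5 label cubes and random series; CI
calibration uses 500 simulated stratified samplings at 100 points per
stratum. These sizes were chosen so the full suite reproduces the
pipeline's properties on a single CPU in minutes.

All stochastic components draw from R's RNG under explicit seeds;
`simulate_landscape()`, `train()` and the pipeline stages are
bit-reproducible given (configuration, seed). Pipeline stages write
JSON manifests recording the derived stage seed and counters.

## Known limitations

* Raster I/O uses TIFF imagery with an ESRI world file and a JSON
  sidecar for CRS/nodata rather than embedded GeoTIFF tags, and point
  I/O is CSV; CRS handling is metadata-only (no reprojection). The
  in-memory containers and the module surface are unaffected.
* Parcel rasterization supports axis-aligned rectangular parcels — the
  form the synthetic generator produces — not arbitrary polygons.
* The classifier trains on CPU in plain R; it is sized for method
  validation, not continental production runs.
* One widely seen printed feature-count for this encoding, 486, is
  inconsistent with 52 × 9; the package implements 468 and does not
  force the printed total.
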