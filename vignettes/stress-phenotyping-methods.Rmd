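---
title: "Methods: pixel-level drought-stress phenotyping from autofluorescence images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pixel-level drought-stress phenotyping from autofluorescence images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afpheno)
```

## The problem and the model

Plants excited with short-wave blue light re-emit over the visible spectrum.
In healthy tissue chlorophyll dominates the emission recorded by a top-view
fluorescence camera; drought-killed, browning tissue loses chlorophyll and its
recorded colour shifts. `afpheno` treats stress quantification as pixel-level
binary classification inside the plant region: a classifier `C` maps each
plant pixel's (r, g, b) intensity triple to stressed (1) or non-stressed (0),
producing a binary *stress image* per plant and day. Two phenotypes are
derived from it:

* **Average percentage stress** for plant *i* on day *j*:
  `100 * stressed plant pixels / plant pixels`. Genotype values are
  arithmetic means over replicate plants present that day, reported with the
  standard error `sd / sqrt(n)`.
* **Moving average percentage stress**: the trailing mean of a plant's daily
  values over the `n` most recent imaging days, including the current one.
  This smooths day-to-day fluctuations and exposes the temporal trend of
  stress induction.

Per-pixel independence is part of the contract: no spatial smoothing or
regularisation is applied to predictions, so the stress image is exactly the
classifier applied to each plant pixel.

## Pipeline stages and their assumptions

### Segmentation

The plant is extracted by colour thresholds, not by a learned model. Two rules
are available and an `auto` mode switches between them by mask area:

* **HSV rule** (small plants): foreground iff hue, saturation and value lie in
  configured bounds. Defaults: hue in the wrap-around band [-40°, 80°]
  (red-centred; channel noise pushes red-hued pixels to either side of 0°),
  saturation ≥ 0.30, value ≥ 0.35. Young seedlings are dim and close to the
  soil in intensity, where the value/saturation bounds discriminate better
  than a red-dominance test.
* **Red-dominance rule** (grown plants): foreground iff red ≥ 110 and red
  exceeds green and blue by ≥ 20. Grown plants fluoresce strongly in red,
  making this rule nearly error-free.
* **auto**: segment with HSV; if the mask exceeds `auto_switch_area`
  (default 1500 px) re-segment with the red rule. Mask area is used as the
  proxy for plant age/size because it is observable and makes the switching
  rule explicit and testable.

Noise removal is morphological opening with a disc of radius 1 (the full
3 × 3 neighbourhood; out-of-image neighbours count as foreground during
erosion, so plants touching the border are not eroded) followed by removal of
8-connected components under 15 px. Opening-then-area-filtering was chosen as
the simplest operator pair that removes both single-pixel speckle and small
debris blobs; it is idempotent when the opening radius is 0 and its output is
always a subset of its input.

The threshold values themselves were calibrated once against the synthetic
generator's default pixel populations and shipped as defaults; every one is a
config field and a CLI flag. On real imagery they would be recalibrated to the
camera — the method is the contribution, not the numbers.

### Ground truth

Training data comes from elliptical patches placed on leaf regions: circles on
healthy tissue, ovals on dried tissue (one ellipse type covers both). For every
patch, each lattice pixel inside the ellipse *and* inside the segmented plant
mask contributes one row `(r, g, b, label)`; pixels outside the mask contribute
nothing, and a patch that misses the mask entirely yields a warning and zero
rows rather than an error. The feature vector is deliberately the raw 3-channel
intensity triple — the most faithful reading of a 24-bit camera — and is
recorded as a fixed contract in the serialised classifier bundle; loading a
bundle against a different contract errors.

Manual annotations are accepted as a patch CSV
(`plant_id,dag,row,col,a,b,orientation_deg,label`). For synthetic data,
`auto_place_patches()` stands in for the annotator: seeded rejection sampling
places non-overlapping circular patches fully inside the correct truth region,
falling back (with a warning) to fewer patches when a region is too small.
Avoiding leaf veins, which the annotation protocol asks of human annotators,
is not enforced in code.

### Classifier families

Six families are trained and compared; the fixed hyperparameters are:

| family | implementation | fixed settings |
|---|---|---|
| ensemble_bagged_trees | `randomForest` | 30 bootstrap trees, all 3 features eligible per split (pure bagging) |
| neural_network | `nnet` | 1 hidden layer × 25 units, inputs standardised, 300 iterations |
| svm_quadratic | `e1071::svm` | degree-2 polynomial kernel, C = 1, training-set standardisation |
| decision_tree | `rpart` | grown with cp = 0, pruned back to ≤ 20 splits |
| logistic_regression | `glm` | binomial; non-convergence warns and the fit is retained |
| naive_bayes | `e1071::naiveBayes` | Gaussian per-channel densities; predict with no density clamping |

Rows are split 60/20/20 into train/validation/test, stratified by class so
both classes appear in every part; the proportions are config. Accuracy is the
fraction of correctly labelled held-out pixel rows. The selected family is the
arg-max of test accuracy, ties broken by validation accuracy and then by the
fixed family order above — on well-separated data all families reach the
ceiling and the tie deliberately resolves to the ensemble.

Two numerical choices matter for reproducibility. First, majority voting over
30 trees can tie 15–15; the underlying library breaks such ties with the
global random-number generator, so predictions use an explicit rule instead
(stressed vote fraction > 0.5 → stressed, a tie → non-stressed). Second, the
naive Bayes prediction disables the library's default density clamping
(threshold 0.001), which would otherwise distort 3-channel Gaussian density
products (order 1e-5) and break the exact correspondence with the posterior
arg-max; underflow to zero cannot occur for 8-bit inputs at the fitted
standard deviations.

### Phenotype computation

Days on which a plant's segmentation comes back empty are flagged and excluded
from genotype means and tests (they would otherwise read as spurious zeros);
`percentage_stress()` raises an error on an empty plant mask for the same
reason. The moving-average window is interpreted as the `n` most recent
*observations* of the plant's dag-sorted series; at the start of a series the
mean is taken over the days that exist, so there is one output per observed
day. The default `n = 3` days smooths single-day imaging artefacts while
following week-scale drought progression; it is exposed as a config field and
CLI flag.

Genotypes are compared per day with Welch's two-sample t-test on replicate
percentage-stress values — the robust default when replicate groups have
unequal variances, which stressed and unstressed genotypes typically do. No
multiple-testing correction is applied across days; days are reported
individually, and readers should treat isolated significant days accordingly.
A degenerate case is handled explicitly: two zero-variance groups compare to
p = 1 when their means are equal (and p = 0 otherwise), where the textbook
statistic is undefined.

## The synthetic-data generator

`render_plant_image()` draws a rosette — overlapping filled ellipses around a
central disc — on a soil background with a darker pot ring, then relabels a
contiguous region of plant pixels as stressed. The stressed region grows from
a random leaf-tip seed by breadth-first accretion over the 4-neighbourhood
until exactly `round(stress_fraction * plant pixels)` pixels are collected,
because real drought damage is spatially contiguous rather than salt-and-
pepper. Pixel intensities are per-channel clipped Gaussians:

| label | mean (r, g, b) | sd |
|---|---|---|
| non_stressed | (170, 60, 50) | 12 |
| stressed | (215, 150, 55) | 12 |
| soil | (60, 45, 35) | 10 |
| pot ring | (30, 30, 32) | 6 |

plus additive scene noise (sd 4). Healthy tissue is red-dominant (chlorophyll
fluorescence); stressed tissue is brown-yellow (red and green high). The green
channel separates the two classes by 90 intensity units ≈ 7.5 combined
standard deviations, comfortably above the 4-sigma separability the
configuration guarantees; a configuration below 4 sigma triggers a warning.
These intensity statistics are the package's own choice — no public statistics
exist for the real camera — and everything downstream treats them as config,
not doctrine.

`simulate_drought_experiment()` renders one image per (genotype, replicate,
day). The per-image stressed fraction is a genotype drought curve evaluated at
the day plus Gaussian replicate noise (sd 0.02 on the fraction scale, clipped
to [0, 1]), reflecting that individual plants vary widely in drought response.
The curve family is a rescaled logistic,
`plateau * (S(d) - S(onset)) / (1 - S(onset))` with
`S(d) = 1/(1 + exp(-rate (d - inflection)))`: zero before the stress onset
day, monotone non-decreasing, bounded by the plateau. The default experiment
uses onset day 10 and days 5–30 DAG with six replicates per genotype —
matching a progressive-drought greenhouse protocol in which watering is
withheld from day 10 and plants are followed to day 30 — and three genotypes:
a tolerant one plateauing at a 15 % stressed fraction (plateau 0.15, rate 0.9,
inflection day 13) and two susceptible ones still rising at day 30 (plateaus
0.55 and 0.60, rates 0.25 and 0.22, inflections 22 and 21). Plant size grows
linearly with DAG from scale 0.35 to 1.

Default scenes are 160 × 160 px rather than camera resolution: the generator
emulates the *statistical* structure the pipeline assumes — two separable
pixel populations on a distinguishable background, growth, contiguous damage —
so a full default experiment (3 × 6 × 26 = 468 images) renders, trains and
classifies in about half a minute, which is the problem size the test suite
and the acceptance script use.

What the generator does **not** emulate: leaf venation, overlapping/occluding
leaves with distinct per-leaf intensities, specular highlights, illumination
gradients, camera vignetting or PSF blur, and gradual class boundaries
(half-dead tissue). Passing tests on synthetic data therefore demonstrate that
the pipeline's machinery is correct and well-calibrated under its own
assumptions — not that the shipped thresholds or the reported accuracies
transfer to real imagery, where class overlap is larger and annotation is
imperfect.

## Determinism

Every stochastic step takes an explicit seed and runs under a local RNG, so
library calls never perturb the caller's random state. The pipeline fans one
global seed out into stage-specific derived seeds (simulation, split,
training, patch placement), making stages independently reproducible: staged
execution and the end-to-end runner produce byte-identical CSV outputs, and
two runs with the same seed produce identical images, bundles and reports.

## Known limitations

* Raw (r, g, b) features carry no texture or neighbourhood information; tissue
  whose colour overlaps the opposite class will be misclassified, and the
  4-sigma assumption hides this failure mode on synthetic data.
* Segmentation thresholds are scene-calibrated constants; changing camera,
  filters or substrate requires recalibration (all values are config).
* The moving-average window counts observations, not calendar days; for
  irregular imaging schedules with long gaps the two readings differ.
* Per-day Welch tests are uncorrected for multiplicity and assume approximate
  normality of replicate means at small n (6 replicates by default).
* No recovery-threshold analysis, no mixed-effects/longitudinal modelling, no
  side-view geometry, and no support for hyperspectral or thermal modalities.
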