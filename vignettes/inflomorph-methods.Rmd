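---
title: "Methods: from inflorescence photographs to yield analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from inflorescence photographs to yield analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inflomorph)
```

`inflomorph` turns a calibrated photograph of trimmed cannabis
inflorescences on a contrasting board into per-object morphometrics and
population-level yield analytics. This vignette explains each model, its
assumptions, the tunable parameters, and the numerical and design choices
— including what the synthetic generators do and do not emulate.

## Image model and calibration

An input image is an 8-bit RGB raster with square pixels and a per-image
scale `cm_per_pixel` (p_l), measured externally (for example from a ruler
photographed in the scene). All absolute quantities derive from p_l:
lengths scale with p_l and areas with p_l². The package performs no lens
or illumination correction; wide-field distortion is assumed corrected in
camera, and residual shading is handled by manual edit masks
(`applyEditMask()`), expressed as `(mask AND NOT remove) OR add`.
Coordinates are x = column, y = row, origin top-left, pixel centres at
integer positions. EXIF orientation codes can be supplied to
`loadImage()` and are applied before any measurement.

## Segmentation

**Blue band.** Plant matter reflects little blue light, so on any
background bright in the blue band the blue channel alone is strongly
bimodal. `extractBlueBand()` returns the channel unchanged; no colour
space transformation is used.

**Minimum-error threshold.** `minimumErrorThreshold()` minimizes, over
all 255 splits of the 256-bin histogram,

$$J(T) = 1 + 2\,[P_1\ln\sigma_1 + P_2\ln\sigma_2]
           - 2\,[P_1\ln P_1 + P_2\ln P_2],$$

with class priors, means and variances taken from the histogram mass at
levels ≤ T and > T. The criterion is the classification-error
approximation for a two-Gaussian mixture; when the mixture model holds
and the modes are moderately separated, its argmin tracks the
equal-posterior Bayes boundary to within a few gray levels. Numerical
choices:

* **Exhaustive scan** over all T rather than the classical fixed-point
  iteration: 255 evaluations are cheap and the global minimum is exact.
* **Variance floor 1/12 gray²** (the quantization variance of a single
  level) applied to each class variance before the logarithm, so spike
  classes (e.g. a two-delta histogram) stay well-defined.
* The class split is between T and T+1, so the effective continuous
  boundary is T + ½.
* A histogram with all mass in one bin has no two-class split and raises
  a "degenerate histogram" error — a blank frame is a user error, not a
  scene.

One property worth knowing: when the two modes are *extremely* separated
the histogram has a wide empty plateau between them, every cut inside the
plateau classifies identically, and the criterion surface is nearly flat —
the argmin can then sit several levels from the nominal Bayes point with
no effect on the segmentation. Agreement with the Bayes boundary is
therefore asserted (in the tests) for moderate-separation mixtures, the
regime of real blue-band histograms; the misclassification rate itself is
checked in both regimes.

**Polarity.** Default `object_side = "below"` (dark objects on a
blue-bright background). The surface colour is a property of the user's
rig, so the polarity is configurable.

**Area opening.** Debris below `min_area_cm2` (default 1 cm², the
standard cutoff for isolated leaf/stem fragments after trimming) is
removed: components with pixel count below `ceil(min_area_cm2 / p_l²)`
are deleted, all other pixels are untouched. The operation is idempotent
and anti-extensive, and is verified against a brute-force
label-and-delete oracle.

**Labeling.** Connected components via a run-based union–find, default
8-connectivity (diagonally touching pixels merge; the package does not
attempt to split touching inflorescences — that is what edit masks are
for). Labels are deterministic: 1..K in raster-scan order of each
component's first pixel.

## Morphometry

**Size.** IS = nₐ·p_l² exactly, from the pixel count.

**Best-fit-ellipse axes.** With central moments
u_pq = Σ(xᵢ−x̄)ᵖ(yᵢ−ȳ)q over the object's pixels,

$$\mathrm{IL}, \mathrm{IW} = 2\sqrt{2}\,
  \sqrt{\frac{u_{20}+u_{02} \pm \sqrt{(u_{20}-u_{02})^2+4u_{11}^2}}{u_{00}}}
  \cdot p_l.$$

The 2√2 constant calibrates the estimator for *filled* regions: for an
ideal filled ellipse with semi-axes a ≥ b it returns exactly 2a and 2b.
`moment_source = "region"` (all object pixels) is therefore the default.
A boundary-only variant (`"boundary"`) is retained for comparison with
software that measures boundary moments, but note it inflates a disk's
diameter by √2 under the same constant — the two modes are not
interchangeable. Degenerate objects (a single pixel, or exactly collinear
pixels) get width 0, ISH = NA, and are flagged out of shape statistics.

**Convex hull.** Andrew's monotone chain over the object's boundary
points, with strict turn tests so collinear interior points are excluded;
area by the shoelace formula, perimeter by the closed vertex loop. By
default the hull is taken over the **4 corner points of each boundary
pixel** (`hull_points = "corners"`), which makes the hull provably
enclose the full pixel area, so CH ≥ IS holds as a hard invariant;
`"centers"` reproduces the convention of tools that hull pixel centres
(CH then undershoots IS for thin objects). Which convention other
software uses varies, which is exactly why both are implemented.

**Exact scaling laws.** Doubling p_l doubles IL, IW, HP, quadruples IS,
CH and leaves ISH unchanged — exactly, not approximately; the test suite
asserts bit-level equality.

## Plant summaries, fresh/dry calibration

`summarizePlant()` computes IN, TIC = ΣIS (exact, hence additive over
record batches), and mean/sd per trait with the n−1 denominator (sd is NA
for IN < 2). Trimmed material can be photographed fresh (harvest day) or
after drying; to merge the two states, `fitFreshDryCalibration()` fits
per-trait OLS trendlines dry ~ fresh on plants imaged in both states and
gates each trait on R² > 0.9 — traits failing the gate are flagged and
refuse calibration rather than silently passing biased values.
`applyCalibration()` applies the trendline (or its inverse for
dry→fresh) and flips the `state` field, so state bookkeeping is
mechanical, not conventional.

## Broad-sense heritability

With clonal replicates, the genotype is the replicated unit and
H² = V_G/V_P is estimable as a clonal repeatability.
`broadSenseHeritability()` uses the one-way random-effects method of
moments: from the between/within mean squares of genotype groups and the
unbalanced-design coefficient k₁ = (N − Σnᵢ²/N)/(G−1),

$$\hat V_G = \max\!\left(\frac{MS_B - MS_W}{k_1},\, 0\right),
  \qquad \hat V_P = \hat V_G + MS_W,
  \qquad \hat H^2 = \hat V_G / \hat V_P.$$

Truncating negative V_G keeps H² in [0, 1]. Both components are returned
so users can form alternative ratios (e.g. genotype-mean-basis V_P). Two
caveats are intentional: no spatial/field-design adjustment is applied
(supply spatially adjusted values if the trial layout warrants them), and
the estimator is a *plot-level* repeatability — its value will differ
from mixed-model REML estimates on the same data. Simulation tests
confirm the estimator recovers true V_G/(V_G+V_E) ∈ {0.2, 0.4, 0.6}
within 0.05 at G = 100 × 4 clones.

## Yield analytics

**Apportioning.** Each plant's g/cm² density = IDB/TIC converts object
sizes to weights, w_i = density·IS_i; conservation Σw_i = IDB is exact by
construction. This assumes weight proportional to 2-D coverage within a
plant — justified by the near-unity coverage–biomass correlation but
still an approximation for strongly 3-D buds.

**Cumulative thresholds.** `yieldThresholdFraction()` sorts weights
descending (ties by object id, so results are reproducible) and returns
the percent of the object count needed to accumulate a fraction q of
IDB. Verified against prefix-sum enumeration; monotone in q.

**Width-based prediction.** `defaultPredictionModel()` ships
IDB[g] = 59.14·IW[cm] − 134.97, with IW the mean width of the plant's 20
longest inflorescences and a fit domain of mean IW > 2.5 cm — predictions
below the domain warn. These coefficients are environment-specific:
inflorescence width responds strongly to light, density and pruning, so
the model should be refit (`refitPrediction()`, OLS with R² and
F(1, n−2)) whenever local width/biomass pairs exist. The model consumes
fresh-equivalent widths; `refitPrediction()` refuses tables whose `state`
says dry, and dried widths should be mapped back with the dry→fresh
calibration first. Top-k selection breaks length ties by larger width
then object id, a deterministic convention.

**Subsampling simulation.** `samplingSimulation()` emulates measuring
only m of the k longest inflorescences: seeded draws without replacement,
summarised by the worst relative deviation from the full-k mean. Defaults
m ∈ {5, 10, 15}, 10 rounds. The m = k case returns the full mean exactly
and dispersal shrinks in expectation as m grows, both asserted in tests.

## Synthetic generators

`generateScene()` renders non-overlapping filled superellipses
(|u/a|ᵉ + |v/b|ᵉ ≤ 1, rotated) with a blue-band contrast of background
200 / object 60, additive Gaussian noise (sd 6 by default), optional
linear shading, and sub-floor debris specks on request. Ground truth
(centres, semi-axes, orientations) is recorded at placement time, never
re-derived from the rendering. Choices:

* **Superellipse exponents in [2, 2.2]**: exponent 2 is the pure ellipse
  for which the moment axes are exact; pushing slightly above exercises
  segmentation and measurement on non-ideal shapes while keeping the
  moment-ellipse axes of the true shape within ~1.8% of 2a/2b, so the 3%
  axis-recovery tolerance retains margin for digitization and
  thresholding noise.
* **Non-overlap enforced** by rejection sampling (bounded attempts, then
  an error): separating touching buds is a manual-edit problem, not one
  the labeling stage claims to solve, and fixtures should not smuggle it
  in.
* Scene defaults (900×700 px at 0.05 cm/px, semi-axes 0.75–3 cm, 12
  objects) keep a test scene around a megapixel-tenth so the full suite
  stays fast while objects remain tens of pixels across.

`generatePopulation()` draws genotype effects Normal(0, V_G) and plant
deviations Normal(0, V_E) on the log-length location; object counts
Poisson(λ = 250), lengths log-normal (median 2.2 cm, log-sd 0.35), widths
as a truncated-normal shape ratio (mean 0.6) times length, areas
π/4·IL·IW, and IDB = 0.1 g/cm² · TIC · (1 + Normal(0, 0.04²)). These
defaults emulate a controlled-environment trial of ~119 genotypes × 4
clones with 200–300 buds per plant, mean bud sizes of a few cm², plant
biomass from tens to hundreds of grams, and a coverage–biomass
correlation above 0.99. `generateTraitPopulation()` is the direct
trait-level simulator used for heritability recovery studies, where the
object layer would add cost but no information.

What the generators do **not** emulate — and hence what passing tests do
not certify on real photographs: touching or overlapping buds, specular
highlights and colour casts, non-linear vignetting, soft shadows larger
than the debris floor, perspective distortion, and trimming variability.
On real data those effects are absorbed by the manual-edit workflow and
by the per-image threshold, and should be monitored through the logged
threshold and object counts.

## Problem sizes and determinism

The shipped tests and the acceptance script use deliberately compact
sizes — ~1 MP scenes with 8–12 objects, populations of 60–119 genotypes,
100–200 simulation replicates, one 10⁶-sample histogram per mixture
check — chosen so the whole suite re-runs in well under a minute of CPU
per module while keeping every estimator's sampling error far below its
asserted tolerance. Every stochastic path is seeded: scenes and
populations reproduce bit-identically under the same seed, the pipeline
writes byte-identical CSVs on reruns, and the subsampling simulation
derives all draws from its `seed` argument.

## Known limitations

* 2-D coverage stands in for volume; the apportioning and the width
  predictor inherit that approximation.
* The shipped prediction coefficients are environment-specific defaults,
  not universal constants.
* Heritability here is clonal repeatability without spatial adjustment;
  it is not comparable to mixed-model estimates with design covariance.
* No instance splitting of touching inflorescences; 8-connectivity plus
  edit masks is the supported path.
* The minimum-error threshold assumes an approximately two-Gaussian
  histogram; multi-modal backgrounds (patterned boards) violate it.
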