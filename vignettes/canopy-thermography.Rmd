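---
title: "Canopy thermography for drought phenotyping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canopy thermography for drought phenotyping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopytherm)
```

## The problem

Drought-stressed plants close their stomata; transpiration falls, evaporative
cooling falls, and leaf temperature rises. Canopy temperature (CT) measured by
an infrared camera is therefore a fast, non-destructive proxy for stomatal
behaviour, and the *drought-induced canopy temperature increase*

$$\Delta CT_g = \overline{CT}_{g,\,\text{drought}} - \overline{CT}_{g,\,\text{control}}$$

ranks genotypes of a crop by how strongly drought heats their canopies. The
practical obstacle is that a thermogram mixes leaf pixels with much warmer
soil and pot pixels, and that combined visible/thermal cameras carry two
sensors that share neither resolution nor alignment. `canopytherm` implements
the full chain from paired images to genotype statistics:

1. **Segmentation** of the canopy in the visible frame: sRGB is converted to
   CIELAB and only the chromaticity channels (a\*, b\*) are clustered by
   mean-shift, which makes the segmentation insensitive to lightness
   differences (shadows, exposure). Green-dominant clusters (mode a\* < 0)
   form the plant mask, and a morphological erosion removes border pixels
   whose temperature would mix plant and background.
2. **Alignment**: a projective transform (homography) from visible to thermal
   coordinates is estimated by least squares from manually annotated
   corresponding points, and the plant mask is warped onto the thermal grid
   with nearest-neighbour sampling.
3. **Radiometry**: apparent temperature is converted to object temperature
   under the greybody assumption (below), and the masked pixel temperatures
   give the per-plant CT summary (mean, median, 5th/95th percentiles).
4. **Statistics**: a two-way fixed-effects ANOVA (treatment × genotype) with
   interaction-dependent Tukey routing, compact letter displays, and a
   Pearson correlation report over the physiological variables.

A synthetic scene generator with exact ground truth makes every stage
testable without field data.

## Coordinate and data conventions

Pixels are addressed 0-based as (row, col) with the origin at the top-left;
homographies act on homogeneous (col, row, 1) triples and map visible
coordinates to thermal coordinates. Visible frames are H×W×3 sRGB arrays in
0–255; thermal frames are matrices of °C wrapped in a `thermal_image` with
acquisition metadata. Extracted pixel vectors are in row-major (raster)
order.

## The radiometric model

A leaf is treated as a greybody: emissivity ε constant over the sensed
waveband (ε = 0.98 by default for plant canopies). Apparent radiance then
mixes emitted and reflected components via the fourth-power law on absolute
temperature,

$$T_{app}^4 = \varepsilon\, T_{obj}^4 + (1 - \varepsilon)\, T_{refl}^4,$$

which `greybody_correct()` solves for \(T_{obj}\) in closed form. Atmospheric
transmission is taken as 1 (short range); full path-radiance modelling is out
of scope. At ε = 1 the correction is the identity, so imagery that was
already compensated in-camera is passed through by setting
`thermal$apparent = FALSE` (the default for the in-memory synthetic runs,
whose generator emits object temperature). Setting a scene's `emissivity`
below 1 renders apparent temperatures through the forward model, and the
pipeline's correction step recovers the truth — this round trip is asserted
in the tests to 10⁻⁹ °C.

The ground sampling distance of a lens with field of view φ at height h over
n pixels is \(GSD = 2h\tan(\varphi/2)/n\); a 25° lens with 320 px flown at
20 m gives 2.8 cm per pixel, small enough to resolve individual leaves of an
adult maize plant.

## Segmentation parameters

* **Bandwidth** (`bandwidth = "auto"`): the paper trail for mean-shift rarely
  states a kernel radius, so the default estimates it as the 0.2 quantile of
  pairwise a\*b\* distances over a seeded random subsample. For a frame
  dominated by two well-separated chromaticities this lands well below half
  the class separation, which is the regime where mean-shift recovers both
  modes.
* **Subsample** (default 1000 pixels, 500 in the pipeline defaults): seeds
  and density support for the shift iterations; the final assignment is
  always full-image. The subsample must be large enough that the rarer class
  keeps a few dozen samples — with canopies covering ~10 % of the frame,
  subsamples below ~300 occasionally leave the canopy so sparsely sampled
  that it fragments below the bandwidth.
* **`min_support`** (default 2 % of the subsample): converged modes supported
  by fewer subsample points are dropped and their pixels assigned to the
  nearest surviving mode. Without this, a seed stranded on an isolated noise
  outlier becomes a spurious cluster that captures chromaticities halfway
  between canopy and soil.
* **Plant rule** (`a_threshold = 0`): clusters whose mode a\* is negative
  (green-dominant) form the plant mask. The original workflow involved human
  annotation, so an explicit `override_labels` path exists for manual
  cluster designation.
* **Erosion** (3×3 square element, 1 iteration by default): pixels outside
  the image count as background, so regions touching the border erode too;
  erosion is anti-extensive and also deletes isolated misclassified pixels,
  which is why single-pixel segmentation errors rarely reach the temperature
  statistics.

## Alignment choices

Estimation uses the normalized DLT: both point sets are centred and scaled to
mean distance √2 (Hartley normalization — required for numeric stability),
the 2N×9 system's least-squares solution is the right singular vector of the
smallest singular value, and the result is scaled to \(H_{33} = 1\). No
RANSAC is used: the points are curated human annotations, and the per-point
reprojection residuals are returned so a bad annotation is visible rather
than silently down-weighted. Estimation needs N ≥ 4 points; a configuration
whose two smallest singular values vanish together (e.g. all points
collinear) is rejected by name. Masks are warped by inverse mapping with
nearest-neighbour sampling — interpolation would create non-binary borders
that erosion has just removed.

## Physiological formulas

* Leaf relative water content `lrwc()`: \(100\,(FW-DW)/(TW-DW)\). Fresh
  weights slightly outside \([DW, TW]\) are a common weighing anomaly: the
  function warns and returns the raw value; reporting stages may cap at 100.
* Maximum PSII quantum yield `fv_fm()`: \((F_m - F_o)/F_m\), in \([0, 1)\).
* Water-use efficiency `iwue()`: the ratio A/E of net CO₂ assimilation to
  transpiration. Much of the gas-exchange literature reserves "intrinsic"
  WUE for A/g_s; this package follows the A/E definition used by the drought
  screening workflow it implements, and keeps the name `iwue` for
  consistency with that usage.
* Gravimetric soil water content `swc_gravimetric()`: \((wet-dry)/dry\).
* Daily water consumption `daily_water_consumption()`: mass lost between the
  previous refill and today's weighing; refilling to a constant target makes
  the series telescope to the total water added.

## The statistical stage

Responses are analysed as a two-way fixed-effects ANOVA,
`y ~ treatment * genotype`. Assumption checks — Cochran's C across the design
cells for variance homogeneity and Shapiro–Wilk on the residuals — are
reported and warn at α but never abort: partially heterogeneous cases are
routine in this kind of experiment and the analysis proceeds with the checks
on record. (The C test is used deliberately: the similarly named Cochran's Q
applies to binary outcomes, which none of these responses are.)

Comparison routing follows the interaction: if treatment × genotype is
significant at α, genotype means are compared within each treatment —
genotypes respond differently, so pooling treatments would average away the
contrast of interest; otherwise treatments are compared within each genotype.
Pairwise p-values use the studentized range at the error degrees of freedom
of the two-way model, and each comparison family is summarised by a compact
letter display: groups share a letter **iff** their pair is non-significant.
Each letter is a clique of the non-significance graph; for up to eight groups
the display uses the exact minimum number of letters (search over maximal
cliques), beyond that the insert-and-absorb construction.

Pearson correlations are reported with the conventional interpretation bands
on |r| — 0.00–0.30 negligible, 0.30–0.50 low, 0.50–0.70 moderate, 0.70–0.90
high, 0.90–1.00 very high — boundaries assigned to the upper band, direction
worded by the sign.

## What the synthetic generator emulates — and what it does not

`generate_scene()` renders canopies as unions of disks of a green
chromaticity over a warm soil background, with i.i.d. Gaussian noise per
pixel and channel, in two pixel grids linked by a known projective transform
(by default 640×480 visible vs 320×240 thermal with scale, shear, translation
and a mild perspective term — different grids on purpose, so the alignment
path is always genuinely exercised). Canopy geometry is analytic, so truth
masks in both frames are exact rather than resampled. `generate_experiment()`
arranges one scene per genotype × treatment × replicate in a completely
randomized design (default 4 genotypes × {control, drought} × 5 replicates)
with canopy temperature drawn from programmed cell means — control 28 °C,
drought offsets 5/3/1/1 °C, replicate SD 0.3 °C — and physiological variables
at realistic maize magnitudes (strong gas-exchange reduction, raised Ci and
Fo, genotype-dependent grain-yield loss under drought).

The generator does **not** emulate: leaf shape or canopy architecture (the
segmentation is colour-based, not shape-based, so disks suffice), shadows or
specular highlights, spatially correlated sensor noise, wind-driven
temperature fluctuation, or radiative transfer in the canopy. Passing tests
therefore demonstrate that the pipeline's operators are correct and that the
statistical machinery recovers programmed effects at realistic noise levels;
they do not certify performance on field imagery with mixed pixels, shadows,
or senescent (non-green) leaves — the known failure mode of any greenness
rule.

All randomness flows from one top-level seed: scene pixel noise uses an
explicit per-scene substream (scenes are independently reproducible), while
the record-level replicate noise uses a single stream per experiment —
drawing each unit's noise as the first variate of a fresh, arithmetically
related stream is subtly correlated and measurably inflates the interaction
false-positive rate.

## Numerical and fixture conventions

* Homography recovery from noise-free points is exact to ~10⁻¹² relative;
  the tests assert 10⁻⁶.
* Histogram bins are uniform, width 0.5 °C by default, left-closed with the
  last bin closed, covering \([\lfloor\min\rfloor, \lceil\max\rceil]\);
  counts always conserve the pixel total.
* Percentiles use linear interpolation (R type 7).
* On-disk fixtures: visible frames and masks as PNG, records as CSV,
  correspondences as CSV (`src_col,src_row,dst_col,dst_row`), and thermal
  frames as single-channel 32-bit float TIFF storing
  \((T - \text{offset})/\text{scale}\) with offset = −50 °C and
  scale = 150 °C recorded in the YAML manifest. The normalized encoding keeps
  the files within the TIFF writer's sample range; round trips are exact to
  float32 resolution (~10⁻⁵ °C). This is a fixture convention of this
  package, not a claim about any camera's raw format.
* Degenerate inputs fail loudly and specifically: empty masks at extraction,
  N < 4 or collinear correspondences, emissivity outside (0, 1], negative
  water consumption named by day, missing design cells named by cell.

## Problem sizes

The test and acceptance workloads run at desk scale by choice: segmentation
fidelity is measured on 192×144/96×72 scenes with two 28-px canopies; the
end-to-end Monte-Carlo (100 pipeline runs of a full 40-unit experiment) uses
96×72 visible / 48×36 thermal frames with one 14-px canopy per pot, a
segmentation subsample of 400, and pixel noise 0.3 °C. At these sizes a full
experiment — 40 scenes through segmentation, alignment, extraction and the
statistical stage — takes a few seconds.

## Known limitations

* The greenness rule fails on senescent, chlorotic or purple foliage; use
  `override_labels` after inspecting the cluster modes.
* The greybody correction ignores atmospheric transmission; at tens of
  metres in humid air the bias is real and must be compensated in-camera.
* CT is the arithmetic mean of masked pixels; outliers are retained (the
  5th/95th percentiles are always reported for auditing), so a poorly eroded
  mask shifts CT rather than being rejected.
* Repeated measures across stress days are analysed separately, not as a
  mixed model; the unit of replication is the pot.
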