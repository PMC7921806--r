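---
title: "Methods: plant-height phenotyping from crop surface models"
author: "phenoheight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plant-height phenotyping from crop surface models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoheight)
```

## The problem

Plant height in wheat breeding trials is traditionally measured by hand: a
ruler against a few culms per plot, at a handful of growth stages. UAV
photogrammetry replaces this with elevation rasters — a digital terrain model
(DTM) from a bare-soil flight and a digital surface model (DSM) per
vegetation flight — from which a per-plot height can be extracted for
hundreds of plots per flight. For the aerial trait to be useful for
*selection*, three things must hold: the rasters must be georeferenced
accurately enough that plot polygons land on the right pixels; the
pixel-to-plot-height reduction must track the canopy top rather than the
canopy bulk; and the resulting trait must carry the same genetic signal as
the manual measurement (similar heritability, concordant genotype ranking).
This package implements that pipeline and, because the field data such
pipelines are tuned on are rarely public, ships a trial simulator with known
ground truth so every stage can be validated end to end.

## Crop surface model

The canopy height raster is the cellwise difference

$$\mathrm{CSM} = \mathrm{DSM} - \mathrm{DTM},$$

computed on the DSM's grid (`compute_csm()`). Cells missing in either input
are missing in the output. By default the two grids must be *identical*
(same origin, cell size, shape); resampling the DTM onto the DSM lattice
(nearest-neighbor or bilinear) is an explicit opt-in, because silent
resampling hides co-registration bugs. Negative CSM values are kept by
default — they are a useful diagnostic of terrain-model error — and clamping
at zero is opt-in.

One coordinate convention is used everywhere: north-up grids, origin at the
top-left corner, pixel-is-area, and half-open cell extents so a point on a
shared edge belongs to the cell to its lower-right. Rasters are read and
written as single-band float32 GeoTIFF (uncompressed, little-endian, with
ModelPixelScale/ModelTiepoint georeferencing and a GDAL-style nodata tag);
the reader rejects multi-band, compressed or non-georeferenced files rather
than guessing.

## Plot extraction

Plot polygons come from the trial layout (GeoJSON). Each polygon is buffered
*inward* by 0.1 m (`build_rois()`, configurable) before extraction: breeding
plots sit 0.5–1 m apart and neighboring canopies shade and overhang, so the
outermost decimeter of pixels is systematically contaminated. Pixels belong
to an ROI when their *center* falls inside the polygon — the common
raster-zonal convention, chosen over partial-coverage weighting because it
is unambiguous and can be verified against a brute-force
point-in-polygon enumeration (the test suite does exactly that, with an
independently implemented winding-number test).

The per-plot height statistic (`plot_height()`) is the **mean of pixels
strictly above the plot's 75th percentile**. Percentiles use linear
interpolation between order statistics (R's default type 7); the choice is
documented and fixed so results are bit-stable. The statistic is a
compromise: the plain mean is dragged down by leaves, gaps and furrow
pixels, while a single high percentile (p95, p99) rides on noise spikes.
Both alternatives (plus mean, median, p90/p95/p99) are available. Two
degenerate rules matter:

* when no value is strictly above the threshold (ties at the top — e.g. a
  constant sample, or a noise-free plateau occupying more than a quarter of
  the ROI), the statistic falls back to the mean of values *at or above* the
  threshold. A constant sample therefore returns the constant, and a
  noise-free simulated plot returns its true height exactly — which is what
  makes the end-to-end zero-noise identity test possible;
* samples below 30 pixels return a missing value with a reason flag instead
  of a noisy estimate. At realistic GSDs a plot has thousands of pixels, so
  this only guards degenerate configurations.

"Top quartile of pixels" and "pixels above the 75th percentile" are treated
as synonyms throughout.

## Georeferencing validation

Ground targets carry surveyed coordinates; checkpoints (CPs) are withheld
from any bundle adjustment and used only for validation. `horizontal_deltas()`
reports per-axis differences (measured − surveyed) with mean, SD and RMSE;
`vertical_accuracy()` regresses CSM-derived target heights (median over the
target footprint — robust to cells straddling the pillar edge) on surveyed
heights and reports slope, intercept, R², residual RMSE and the SD of the
raw errors. Everything operates in projected meters.

Two conventions are fixed deliberately. The SD is **population** (divide by
n), so the identity RMSE² = mean² + SD² is exact and is asserted in the
tests; sample SD is available via a flag. The vertical regression direction
is measured ~ surveyed. Accuracy is then graded in GSD multiples
(`check_accuracy_criteria()`): horizontal SD within 2×GSD per axis, vertical
SD within 3×GSD, with the stricter 1×/2× verdicts reported alongside —
the acceptance bands commonly cited for orthomosaic products.

## Mixed models

Plot heights feed the standard alpha-lattice analysis. With genotype $g_i$,
replicate $r_j$ and incomplete block $b_{k(j)}$ nested in replicate,

$$y_{ijk} = \mu + g_i + r_j + b_{k(j)} + \varepsilon_{ijk},$$

with $r_j \sim N(0,\sigma^2_r)$, $b_{k(j)} \sim N(0,\sigma^2_b)$,
$\varepsilon \sim N(0,\sigma^2_\varepsilon)$. Genotype is **fixed** for BLUEs
(`fit_blue_model()`), **random** with $g_i \sim N(0,\sigma^2_g)$ for BLUPs
and heritability (`fit_blup_model()`). When several flights cover one stage,
`adjust_for_flights()` first collapses them to one value per plot via an
additive plot + flight fixed-effects fit (identity when there is one flight).

### REML algorithm

`fit_reml()` estimates variance components by EM iterations on Henderson's
mixed-model equations: each update is a closed-form expectation step and
cannot decrease the restricted likelihood. EM's linear convergence is
accelerated by Aitken extrapolation every third iteration; an extrapolated
point is accepted only if it does not worsen the restricted likelihood, so
monotonicity is preserved. Iteration stops when the relative parameter
change drops below 1e-8, or when the restricted likelihood is stationary to
1e-9 (relative) — the second criterion matters in degenerate fits where a
variance is pinned at zero and the equations become ill-conditioned enough
that parameters jitter at numerical-noise level. The cap is 2000 iterations;
non-convergence is an error carrying the iteration trace, never a silent
result.

Variances are constrained non-negative by a floor at 1e-10 times the
response variance; estimates at the floor are reported as 0 with a boundary
flag. Fixed effects are GLS solutions at the estimates; BLUPs come from the
same equations. Standard errors of variance components (opt-in, `se = TRUE`)
use the observed information from a central-difference Hessian of the
restricted log-likelihood; heritability SEs are delta-method transforms of
that covariance. The balanced-case closed forms, an independent lme4 fit on
unbalanced data, and a 1000-point random audit of the restricted likelihood
all serve as oracles in the test suite.

### Heritability

"Genotypic over total variance" needs a denominator convention, and the
printed values in field studies rarely say which. Both are implemented and
reported: **entry-mean** basis (default; the repeatability of a genotype
mean over $r$ replicates), $H^2 = \sigma^2_g / (\sigma^2_g +
\sigma^2_\varepsilon / r)$, and **plot** basis, $\sigma^2_g$ over the sum of
all components. Neither is claimed to reproduce any particular published
value; they bracket the conventional choices.

### Pedigree relationships and genotype-by-year models

`additive_relationship()` builds the numerator relationship matrix by the
tabular method (entries are twice the coefficient of parentage): founders
$A_{ii} = 1$; offspring $k$ of parents $s,d$ have
$A_{ki} = (A_{si}+A_{di})/2$ and $A_{kk} = 1 + A_{sd}/2$. Pedigrees are
topologically sorted first; cycles are an error; a parent not in the id
column counts as unknown.

`fit_gxe()` fits the two-cycle model with additive genotype effects
$g \sim N(0, A\sigma^2_a)$, an independent genotype-by-year interaction
$N(0, \sigma^2_{ge})$, year as fixed, and replicates/blocks nested in year.
Correlated effects reduce to the independent-effects machinery by
transforming the genotype design with the Cholesky factor of $A$ (a ridge of
1e-8 is added if factorization fails); with $A = I$ the model collapses
exactly to the independent-genotype fit, which the tests assert to 1e-6.
Narrow-sense heritability uses $\sigma^2_a$ with the same two denominator
bases (entry-mean: $\sigma^2_a + \sigma^2_{ge}/n_{year} +
\sigma^2_\varepsilon/(n_{year} n_{rep})$). Stage- or cycle-specific row
filters (e.g. dropping one stage from one cycle) are the caller's data
subsetting, not hard-coded behavior.

### Rank concordance

`spearman_with_test()` computes rho on average ranks with the t
approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ df. The default
confidence interval uses the Fisher z transform. A second option,
`conf_method = "linear"`, reproduces a half-width formula sometimes printed
alongside prediction-accuracy figures, $1.96(1-\hat\rho)/(n-2)$; it is kept
for comparability only — its width does not behave like a sampling SE, which
is why it is not the default.

## Ground-vs-aerial agreement

`flag_outliers()` implements the screening rule: regress ground on aerial,
compute externally studentized residuals (df $n-3$), Bonferroni-correct the
two-sided p-values and flag below $\alpha = 0.01$; flagged pairs are removed
from both platforms. The regression direction anchors studentization on the
ground values (the platform being screened for recording errors); it can be
flipped. `agreement()` then reports R², slope, intercept, and — deliberately
as two named quantities — the **regression-residual RMSE** (scatter around
the fitted line) and the **raw-difference RMSE**
$\sqrt{\mathrm{mean}((\mathrm{aerial}-\mathrm{ground})^2)}$, which also
absorbs systematic offset. Field studies report both kinds under the same
name "RMSE", with very different magnitudes (a few cm within a stage, 8–15
cm across stages); keeping them distinct avoids that conflation.
`rmse_dev()` pools squared differences over every plot × stage pair, with a
per-stage decomposition.

## The trial simulator

The generator emulates a two-bed alpha-lattice spring-wheat trial as flown
by a UAV, at the product level (rasters), not the photo level — no image
rendering, no structure-from-motion emulation, no bundle adjustment.

* **Design**: 150 genotypes × 2 replicates × 30 incomplete blocks by
  default; assignment uses a cyclic generating permutation per replicate, so
  each genotype appears exactly once per replicate and blocks nest in
  replicates (resolvability is the tested invariant; design optimality is
  irrelevant to validating the estimator).
* **Geometry**: plots two beds wide (2 × 0.8 m beds + 0.36 m inter-bed
  furrow = 1.96 m), 0.24 m inter-row spacing, 2–4 m plot length, 0.6 m
  alleys, targets on the bare margin.
* **Terrain**: white noise on a 2 m lattice, Gaussian-smoothed, bilinearly
  upsampled and rescaled so the peak-to-peak relief is exactly
  `terrain_relief_cm` (default 10 cm); relief 0 gives a flat field.
* **Truth**: per growth stage, genotype/replicate/block effects are centered
  Normal draws with SDs `genotype_sd_cm` (5), `replicate_sd_cm` (1),
  `block_sd_cm` (2); plot truth = stage mean + the three effects. Stage
  means default to 55 (E+40), 85 (booting), 95 (anthesis+7), 90 (maturity)
  cm — heights rise to a maximum after flowering and settle slightly by
  maturity.
* **Canopy surface**: within each bed, culms sit on a jittered grid along
  the four plant rows (6 cm spacing); each culm's height is drawn around the
  plot truth with SD `culm_sd_cm` (4 cm); the surface follows the nearest
  culm with valleys dipping up to 1.5 × `culm_sd_cm` between culms, tapers
  linearly to soil across the inter-bed furrow, and stops at plot edges.
  This is the one place the simulator invents sub-plot structure the field
  protocol does not specify: the bump texture exists so that percentile
  statistics and the mean differ measurably (otherwise the p75 rule would be
  untestable), and its parameters are calibration knobs, not field claims.
  Gaussian elevation noise (`surface_noise_sd_cm`, 1 cm) mimics
  photogrammetric reconstruction error; an optional box blur
  (`wind_smear_px`) mimics plant movement between overlapping images.
* **Ground protocol**: per plot, the mean of 4 random culm draws
  (N(truth, culm_sd²)) plus ruler error (`measurement_sd_cm`, 1 cm) — the
  4-culm manual protocol.
* **Targets**: 9 GCPs + 11 checkpoints on the margin ring, pillar heights
  cycling a 0–120 cm ladder, stamped into the DSM before noise; measured
  coordinates get a configurable systematic shift plus Normal error.
* **Pedigrees**: founders unrelated; each cross samples two distinct earlier
  individuals; acyclic by construction.

Randomness: every stage derives its own 31-bit seed from the root seed and a
purpose label, so outputs are pure functions of (config, seed), stages are
independently reproducible, and adding a stage never perturbs another.

What the simulator does **not** model — and hence what passing tests do not
show about real data: lodging and geometric wind distortion, spatially
correlated photogrammetric error (doming, rolling-shutter artifacts),
DTM error from vegetation present in the bare-soil flight, bed curvature,
emergence gaps, weeds, and cross-stage genotype correlation (genotype
effects are drawn independently per stage, so multi-stage analyses see
uncorrelated stage signals). End-to-end results on simulated trials validate
the *machinery*; they are not evidence about any particular field campaign.

## Problem sizes and numerical choices

The default test and acceptance runs use a scaled-down demo trial — 50
genotypes × 2 reps × 10 blocks, 2 m plots at 3 cm GSD (~100 plots, ~1.5 M
cells per raster) — and the full 150 × 2 × 30 design for layout and
variance-component recovery checks (200 simulated trials at the reference
variance ratios σ²g = 25, σ²b = 4, σ²ε = 9, for which the entry-mean H² is
25/(25 + 4.5) ≈ 0.847). These sizes were chosen to exercise every code path
at field-realistic magnitudes while keeping a full validation run in the
minutes range on one core.

Numerical conventions collected in one place: percentile type 7; strict
center-in-polygon with the lower-right edge rule; population SD in accuracy
reports; variance floor 1e-10 × var(y); relationship-matrix ridge 1e-8;
REML tolerances 1e-8 (parameters) / 1e-9 (likelihood plateau); nodata
sentinel −9999 compared at float32 precision on read; heights in meters
inside rasters and centimeters in all tables and reports, converted only at
the reporting layer.

## Limitations

The GeoTIFF reader supports the subset this pipeline writes (single-band,
uncompressed, little-endian float/integer, strip-organized); it is not a
general GeoTIFF implementation. Polygons are simple (convex buffering);
layouts are rectangular grids. The REML engine targets the handful of
variance components these designs need — it is not a general sparse
mixed-model solver, and very large designs (tens of thousands of effects)
would need the field's dedicated tools. Spatially correlated residual
models, multi-trait models and marker-based relationship matrices are out
of scope.
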