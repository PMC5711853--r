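---
title: "Plot-image vegetation indices and yield statistics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plot-image vegetation indices and yield statistics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopyvi)
```

## The problem this package addresses

Early-vigour phenotyping of row crops scores each field plot from an
overhead image: how much of the plot a young canopy covers, how green
that canopy is, and how those quantities relate to agronomic outcomes
such as grain yield and leaf nutrient status. Two acquisition platforms
are in routine use — a hand-held camera at roughly a metre above the
canopy, and a camera on a small UAV at tens of metres — and they differ
mainly in spatial resolution per plot. This package implements the full
chain: pixel-level colour transformations, plot-level RGB and
multispectral vegetation indices, an explicit resolution-degradation
model for the ground/aerial comparison, a synthetic-trial generator with
known ground truth, and the trial-level statistics (treatment ANOVA,
grouped correlations, forward stepwise yield models).

## Colour models and the RGB indices

Pixels are assumed to be 8-bit sRGB. Three colour models are used:

* **HSI** — hue is the colour angle (red 0°, yellow 60°, green 120°,
  cyan 180°), computed with the arccosine form on the gamma-encoded
  channels; intensity is the channel mean `(r+g+b)/3` on [0, 1] and
  saturation is `1 − min(r,g,b)/I`. Hue is undefined for achromatic
  pixels (`r = g = b`); they are assigned hue 0 with saturation 0 and
  carry zero weight in hue averages.
* **CIELab** and **CIELuv** — computed from gamma-decoded linear RGB
  through CIE XYZ under D65. `a*` and `u*` scale green (negative) to
  red (positive); `b*` scales blue to yellow; `L*` is lightness on
  [0, 100]. The white point is taken as the row sums of the sRGB matrix
  (D65 to seven decimals) so neutral greys collapse to exactly
  `a* = b* = u* = v* = 0`. No chromatic adaptation beyond D65 is
  applied, and no camera calibration is attempted.

A plot image is reduced to ten numbers: mean Intensity and Saturation,
the **circular** mean of hue (angles cannot be averaged linearly; each
chromatic pixel contributes a unit vector), mean `L*`, `a*`, `b*`,
`u*`, `v*`, and two cover fractions:

* **GA** (green area): fraction of pixels with hue in [60°, 180°];
* **GGA** (greener area): fraction with hue in [80°, 180°], excluding
  yellowish-green (chlorotic) tones, so `GGA ≤ GA` always.

Window bounds are inclusive on both ends (a measure-zero choice,
documented for reproducibility), no saturation or lightness floor is
applied before classification, and achromatic pixels are never counted
green.

## Multispectral indices

Band stacks are keyed by centre wavelength over the 11 supported
channels (450–950 nm). Each of the twelve indices (NDVI, SAVI, OSAVI,
RDVI, EVI, PRI, MCARI, TCARI, TCARI/OSAVI, ARI2, CRI2, WBI) is
evaluated exactly from its published formula; tests compare every index
against an independent evaluation of the literal formula strings.
Three documented quirks:

* **SAVI's soil factor L** defaults to 0.5 ("intermediate" vegetation);
  1 and 0.25 are the published low- and high-cover settings. SAVI
  reduces to NDVI as `L → 0`.
* **TCARI** as printed is parenthesis-ambiguous. The default follows
  the canonical cited grouping
  `3[(R700 − R670) − 0.2 (R700 − R550)(R700/R670)]`; the literal parse
  is available via `literal = TRUE`.
* **WBI** as printed has the algebraic shape of RDVI on the red/NIR
  pair rather than the conventional 900/970 nm ratio; it is implemented
  as printed, and `wbi_ratio()` provides a ratio-form NIR water index
  from the available 900/950 nm bands. The canonical 970 nm band is
  simply not in this camera's set.

Per plot, indices are computed by default on the plot-mean reflectances
(**mean-reflectance** mode), matching plot-level reporting; a
per-pixel-then-average mode is provided for sensitivity analysis. The
two agree exactly on uniform scenes. Vanishing denominators yield `NA`
— an explicit undefined-value sentinel, never a silent infinity — and
such cells are written as empty fields with a logged count.

## Emulating the aerial platform

Ground and aerial images of the same plot differ essentially in pixels
per plot (about 4608 × 3072 versus 488 × 193). The emulator degrades a
ground image by **integer block-mean downsampling**: every output pixel
is the mean of an `f × f` block, so plant/soil boundary pixels become
genuine mixed pixels — the mechanism that blurs hue-based
classification at altitude. No optics or point-spread model is
attempted. The default factor is 12, which matches the per-plot pixel
*count* ratio (√(14.2 Mpx / 0.094 Mpx) ≈ 12.3); the two printed axes
have different ratios (9.4 and 15.9) because the platforms' crops are
not geometrically similar, so no single integer matches both axes.
Images are cropped to the largest multiple of the factor first, and
mean image colour is preserved to 8-bit rounding.

## The synthetic-trial generator

No imagery was available to ship, so the generator is a first-class,
tested module that emulates the study design: 26 genotypes × 2
phosphorus arms (52 plots), with the unfertilised arm (NPF) showing
lower cover, more chlorosis, and purpling.

**Scenes.** Canopies are rendered as random elliptical blobs on a
textured soil background — not per-pixel noise — precisely so that
downsampling creates boundary mixed pixels; a resolution comparison on
spatially uncorrelated noise would be meaningless. Blob growth is
controlled (with a bisection step on the last blob) so the realised
cover fraction lands within about 0.5% of target. Leaf pixels draw hue
from a normal distribution whose mean shifts from 115° toward yellow by
up to 40° with chlorosis; purpling darkens the canopy and blends it
mildly toward a red/blue cast. The pixel-aligned band stack mixes two
declared endmember spectra (leaf and soil) with 3% multiplicative
noise; chlorosis raises 670 nm and lowers 840 nm reflectance linearly,
flattening the red edge, so mean-band NDVI falls monotonically with
chlorosis at fixed cover.

**Trial table.** Yields follow
`treatment mean + genotype effect + slope·(cover − arm mean) + residual`.
The calibration is derived from the study's printed treatment tables:
arm mean yields 5.64 and 7.50 t·ha⁻¹; within-arm yield SD
`0.20·√26 ≈ 1.02` t·ha⁻¹ from the printed standard errors; cover means
0.08 (NPF) and 0.21 (OP) with SD ≈ 0.05 from the printed GA summaries.
Reproducing the printed within-arm cover–yield correlations (~0.82)
under this structure then fixes the slope at 16.5 t·ha⁻¹ per unit
cover and the genotype/residual SDs at 0.40/0.42 t·ha⁻¹. (The printed
single-term regression coefficients, 12–14, are not simultaneously
satisfiable with the printed correlations and SDs under this simple
structure; the correlation — the analysis layer's headline quantity —
was preferred.) Leaf traits are drawn per arm around the printed
means, with leaf P, chlorophyll and N partially linked (r ≈ 0.6) to
cover. `planted_cover_yield_correlation()` returns the closed-form
pooled correlation implied by a design (≈ 0.90 for the defaults),
which parameter-recovery tests use as their reference.

**Determinism.** One master seed drives the design-level draws, and
plot *i* renders its scene from seed `master + i`, so any single plot
is reproducible in isolation.

**What the generator does not emulate** — and hence what passing tests
do *not* show about real data: radiative transfer (no PROSAIL), row
structure and plant architecture, illumination and camera
auto-exposure variation, soil moisture gradients, georeferencing and
mosaicking artefacts, and any genotype × treatment interaction beyond
an additive genotype effect. Results on real imagery depend on all of
these.

## Statistical layer

* **Treatment ANOVA** is the one-way treatment contrast with means ±
  standard errors per arm. Two identical groups are reported as
  `F = 0, p = 1` rather than 0/0.
* **Correlation tables** report Pearson r, two-sided p and n per index
  × group cell, for each arm and the pooled sample; pairs with missing
  values are dropped pairwise, and a cell with fewer than 3 complete
  pairs is `NA`, never fabricated. No multiple-testing correction is
  applied, matching the emulated analysis.
* **Forward stepwise regression** uses pure forward entry on the
  partial-F p-value: the best candidate enters while its p-value is
  below `alpha_enter` (default 0.05); there is no removal step. With
  `alpha_enter = 1` it degenerates to a full greedy ordering. Under a
  planted null, the probability of remaining intercept-only is
  `(1 − α)^k` for k independent candidates, which is why the null
  validation suite uses two candidates for its ≥ 90% check.
* **Portion of variance** per selected term is not uniquely defined for
  correlated predictors; the default estimator averages each term's
  incremental R² over all entry orderings (LMG-style, exact
  enumeration up to 8 terms) and normalises the shares to sum to 1,
  which reduces to incremental-R² shares under orthogonality. A
  simpler normalised squared-standardised-coefficient estimator is
  available via `method = "beta_sq"`. This is a documented
  implementation choice, not a claim about the original software.
* **Delta notation** for isotope ratios is the per-mil deviation
  `[(R_sample/R_standard) − 1]·1000`.

## Numerical choices and degenerate inputs

* Achromatic pixels: hue 0 by convention, zero weight in circular
  means, never classified green.
* The circular hue mean equals the arithmetic midpoint for any two
  angles within a 180° arc; for larger sets the vector mean is used
  (the arithmetic mean of several angles differs in general).
* Zero denominators in index formulas produce `NA` sentinels, excluded
  from downstream statistics with pairwise/listwise dropping and a
  logged count in tables.
* Collinear-to-machine-precision designs abort variance decomposition
  with an error naming the terms.
* CSV output: comma-separated, UTF-8, "." decimal, 6 significant
  digits, `NA` as empty cells; rectangular crops are 0-based,
  row-major, half-open.

## Problem sizes used by the validation suite

The shipped tests run trials at reduced scene sizes chosen to exercise
every code path while keeping the suite quick: default scenes are
128 × 192 px (the cover-control contract is stated for 128 × 128 and
larger), full 52-plot trials render in a few seconds, the
formula-oracle suites use 100 random band vectors and 1,000 random
pixels, parameter recovery uses 200 tabular trials plus rendered spot
checks, and the resolution-mechanism check runs one full rendered
trial at the default downsampling factor. These sizes are the
package's own validation design; the pipeline itself has no upper
limit beyond memory.

## Known limitations

Colour conversion assumes sRGB with D65 and ignores camera ICC
profiles and white balance; JPEG input is not supported (PNG/TIFF
only); the aerial emulator models resolution loss only, not
perspective, blur or illumination; the stepwise procedure inherits the
usual caveats of greedy selection (no inference correction for
selection); and the generator's planted effects are additive, so it
cannot probe genotype × environment interactions.
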