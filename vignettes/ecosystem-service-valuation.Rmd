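---
title: "Projecting land-cover change and valuing ecosystem services with landesv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting land-cover change and valuing ecosystem services with landesv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landesv)
```

## The problem

Dryland regions such as Central Asia have seen rapid cropland expansion and
urbanisation alongside shrinking water bodies. Because each land-cover class
supplies a different bundle of ecosystem services — food, raw material, gas,
climate and water regulation, soil formation, waste treatment, biodiversity,
and recreation — the composition of the landscape translates directly into a
monetary flow of services. `landesv` implements the standard analysis chain
for such questions: *where is the landscape heading* (Markov + cellular
automata on categorical rasters, validated with Cohen's kappa) and *what is
that worth* (benefit-transfer valuation with a per-hectare coefficient
matrix, plus an elasticity check on those coefficients).

The packaged fixtures are the published Central Asia inputs: a five-epoch
(1995–2035) area table for seven classes (cropland, forestland, grassland,
wetland, urban, bare land, water bodies), in units of 10⁴ ha as printed, and
a 7 × 9 value-coefficient matrix in US$ ha⁻¹ yr⁻¹ whose class totals are
5,567 / 3,137 / 4,166 / 25,681 / 6,661 / 0 / 12,512.

## Markov projection

Cross-tabulating two co-registered epochs gives transition counts
`n[i, j]`; dividing by row totals gives the row-stochastic matrix `A`, and
composition projects as `s(t+1) = s(t) %*% A`. Conventions worth stating:

* **One step is one inter-epoch interval** (a decade here). Longer horizons
  are matrix powers, matching the chained 2015 → 2025 → 2035 design.
* **A class absent at the first epoch gets an identity row** — an absent
  class cannot be a source, and the matrix stays stochastic without
  inventing transitions.
* **Masks are harmonized first**: the union of the epochs' nodata masks is
  applied to both, so counts are always over common support. With a per-cell
  area grid the cross-tabulation is area-weighted; with the default scalar
  cell area the two are equivalent.

```{r markov}
A <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
project_state(c(0.5, 0.5), transition_matrix(A), steps = 1)
```

## Cellular-automata allocation

The source study ran the MARKOV/CA-Markov modules of a GIS package and
reports no neighborhood, iteration count, or suitability layers, so those
were genuinely open design choices; we fixed them as follows and treat them
as tunables:

* **Suitability = neighborhood class density** over a 5 × 5 window (the
  conventional contiguity filter; edge cells use the truncated window).
  Values lie in [0, 1] and sum to 1 over classes at every data cell. No
  external driver layers (roads, slope, climate) are used because none were
  specified; the `suitability` argument accepts any user-built stack with
  the same shape.
* **10 CA iterations** by default for a decadal step, with demand spread
  evenly across iterations and suitability recomputed from the evolving map
  each time, so change accretes along patch edges rather than landing in
  one pass.
* **Demand-driven greedy reassignment.** Markov target areas are converted
  to integer cell demands (largest-remainder rounding, so totals are
  conserved exactly). Cells are ranked by the suitability gained by
  flipping; ties break by a seeded random shuffle then stable cell index,
  making runs fully deterministic per seed.
* **The transition matrix defines the feasible set**: a cell flips at most
  once per allocation and only from its baseline class `i` to a `j` with
  `A[i, j] > 0`. When no surplus class can feed a deficit directly (for
  example urban can only come from grassland, which is itself in balance),
  the deficit is routed along the shortest feasible chain of classes, one
  distinct cell per hop, so circulations implied by the targets still
  resolve. Residual demand after `max_iter` is reported with a warning and
  attached to the result.

Validation uses Cohen's kappa with chance agreement from both maps'
marginals: `kappa = (p0 - pc) / (1 - pc)`. When both maps are constant and
identical (`pc = 1`) kappa is undefined and flagged rather than silently 0
or 1. The published hindcast (kappa = 0.93 against the 2015 observed map)
requires the external 300 m land-cover product and is therefore out of
scope here; the equivalent in-package check is the hindcast on synthetic
epochs in `analysis/03_project_lulc.R`, which lands in the same range
(≈ 0.9) because the generator's dynamics are strongly spatially
autocorrelated. That agreement shows the machinery is consistent; it says
nothing about accuracy on the real product.

## Benefit-transfer valuation

Valuation is linear: `ESV_k = A_k * sum_f VC_kf`, `ESV_f = sum_k A_k *
VC_kf`, and the total is the sum of either margin — an identity the code
asserts rather than assumes. Areas are accepted in ha or 10⁴ ha with
explicit unit tags because the literature mixes both; values are computed in
US$ and reported in billions at 2 decimals to match the published tables.

The elasticity analysis rescales one class's entire coefficient row by
1 ± 0.5 and recomputes the total. Under a linear valuation the coefficient
of sensitivity equals the class's share of the total value and is
independent of the perturbation size — the tests assert this at δ ∈
{±0.1, ±0.5} — and an all-zero row (bare land) has CS defined as 0, since
the elasticity formula would be 0/0.

```{r value}
a95 <- area_row(central_asia_areas(), 1995)
round(total_esv(a95) / 1e9, 2)
round(coefficient_of_sensitivity(a95, class = "grassland")$cs, 2)
```

## What the synthetic generator does and does not emulate

`generate_initial()` builds a neutral landscape: a seeded uniform noise
field, box-smoothed by the `patchiness` radius, thresholded at the
cumulative target proportions *by rank*. Rank thresholding keeps the
realized composition exact to one cell at any patchiness (the smoothing
only reorders cells spatially), and the construction is O(cells) and
bitwise reproducible per seed. Default proportions are the packaged 1995
shares (grassland ≈ 51%, bare ≈ 24%, cropland ≈ 19%), cell area 9 ha (a
300 m cell), and `patchiness = 3`, which gives patch sizes large enough
that a 5 × 5 suitability window sees real structure.

`evolve()` is the stochastic inverse of `estimate_transition()`: each
cell's next class is sampled from its row of a known `A` (unclustered), or
flip counts are fixed at expected multinomial values with the most suitable
cells flipping first (clustered). This supports recovery tests — the
estimated matrix converges to the generating one as the grid grows (max
error < 0.02 at ~10⁵ cells) — and hindcast tests with known truth.

The generator emulates composition, patchiness and Markov drift. It does
**not** emulate the real product's spatial covariance, the geography of any
actual region, class-confusion structure, or georeferencing beyond a
nominal grid. Passing tests therefore demonstrate the correctness of the
estimators and the allocator, not the accuracy of any real-world
projection.

## Numerical choices and degenerate inputs

* Row-stochasticity and probability-vector checks use a 1e−9 tolerance.
* Zero-baseline change rates are flagged `NA` with an `"undefined"`
  attribute, never 0 or ±Inf.
* Integer cell demands use largest-remainder rounding; totals are conserved
  exactly through projection and allocation.
* Raster I/O uses the plain-text ESRI ASCII grid format; the reader demands
  integer-valued bands and a legend that covers every code it meets
  (unmapped codes are an error naming the code, not a silent drop). The
  packaged legend for 300 m climate-initiative product codes is a
  documented best-effort stand-in, since the source study's exact code
  table is in unpublished supplementary material.
* Problem sizes in the tests and analysis scripts — 200 × 200 landscapes
  for allocation, ~320 × 320 (≈ 10⁵ cells) for recovery — were chosen as
  the smallest grids at which the statistical checks (3σ binomial bands,
  0.02 recovery max-norm, 0.5% allocation residual) are comfortably sharp.

## Known limitations and source-table quirks

A handful of cells in the published tables are not internally consistent
with the published inputs: the printed gas-regulation and soil-formation
function values imply slightly different grassland coefficients than the
printed matrix; the printed 2025 wetland and urban class values disagree
with the printed 2025 areas; two printed sensitivity pairs (wetland
2005/2015) exceed the value share that any linear valuation of the printed
areas can produce; and the printed per-year area rows sum to within ±0.02
× 10⁴ ha of the printed constant total. This package always reports what
the formulas give on the packaged inputs; the reproduction tests document
the agreeing cells and the deviating ones explicitly. Beyond that, the
valuation inherits the usual benefit-transfer caveats — one global
coefficient per class, no cost accounting, no currency-year adjustment —
and the CA uses neighborhood density only, with no external drivers.
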