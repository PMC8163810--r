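---
title: "Methods: canopy structure and carbon dynamics from repeat lidar"
author: "CanopyCarbon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: canopy structure and carbon dynamics from repeat lidar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CanopyCarbon)
```

CanopyCarbon quantifies what a wind disturbance (a *blowdown*) does to the
aboveground carbon balance and canopy structure of a tropical forest
landscape observed by lidar at two points in time, and how detectable and
persistent such an event is. This vignette explains each model in the
chain, the assumptions behind it, the tunable parameters and their
defaults, the numerical choices, and what the synthetic test landscape
does and does not establish about real data.

## From point returns to canopy height

Both survey epochs enter as lidar-style point tables
(`x, y, z, return_number, scan_angle`). Only **first returns** are used —
the earliest echo of each pulse, representing the highest intercepted
surface — because later returns depend strongly on beam divergence and
detector characteristics that differ between instruments. For surveys
with a wide scan-angle range and high native density (typically
drone-borne), two further homogenization steps are applied per epoch,
both configurable: returns beyond ±15° from nadir are discarded, and the
remainder is randomly thinned to a fixed density (10 pts m⁻² is the
conventional target; the synthetic demo uses 1 pt m⁻², still above the
~1 pt m⁻² adequacy threshold reported for forest-structure retrieval).
Heights above ground come from subtracting a digital terrain model,
interpolated bilinearly between cell centres, from point elevations;
negative heights are clamped to zero, since negative canopy height is
physically meaningless and the gap machinery assumes non-negative
heights. A constant per-epoch vertical bias (e.g. +0.7 m in one survey
relative to the other, as estimated from surfaces visible in both) is
removed with `applyVerticalBias()`; estimating such a bias from common
hard surfaces is outside the package's scope and it enters as a
configuration scalar.

Two rasterizations serve different purposes:

* `rasterizeTIN()` (1.25 m pixels) builds the Delaunay triangulation of
  the first returns and evaluates the piecewise-linear surface at every
  pixel centre. This guarantees that *every* pixel inside the convex hull
  has a height — essential for gap delineation, where a pixel without
  returns must not masquerade as a gap. Out-of-hull pixels are nodata and
  excluded downstream. Linear interpolation on any triangulation is exact
  for affine surfaces; the suite verifies ≤ 1e-9 m error against analytic
  planes. For large point sets the extent is triangulated in buffered
  square tiles (default ≤ 25,000 points per tile, 10 m buffer), which
  bounds memory while leaving interior pixels identical to the global
  triangulation at realistic densities.
* `rasterizeMean()` (5 m pixels) takes the arithmetic mean of first-return
  heights per half-open pixel footprint `[x0, x0+res) × [y0, y0+res)`.
  This is the top-of-canopy height (TCH) grid used by the allometry and
  the transition matrix. Pixel footprints are half-open everywhere in the
  package so every point belongs to exactly one pixel.

On-disk rasters use the ESRI ASCII grid format (single band, nodata
-9999, optional one-line CRS sidecar): a plain-text, GDAL-readable format
that keeps every artifact of a run human-inspectable and
version-controllable. The CRS is carried as metadata only and never
validated against an authority database.

## Carbon: the TCH→AGBD power allometry

Aboveground biomass density follows the standard power-law allometry

$$\mathrm{AGBD} = a\,\mathrm{TCH}^{b} + \varepsilon,\qquad
  \varepsilon \sim \mathcal{N}(0, \sigma^2),$$

calibrated on field plots (18 half-hectare plots in the reference
configuration) whose TCH is the mean of the 5 m grid pixels inside each
plot footprint. Residuals are Gaussian on the *biomass* scale, not the
log scale. `fitAllometry()` maximizes this likelihood through its profile
form: for fixed $(a, b)$ the ML residual SD is $\sqrt{SSE/n}$, so
minimizing $\tfrac{n}{2}\log(SSE/n)$ over $(\log a, b)$ by BFGS from a
log–log least-squares start yields the joint ML estimate. The profile
route matters numerically: it stays exact as residuals shrink to zero
(the suite demands 6-digit recovery on noise-free data), where direct
three-parameter optimization or `nls()` degenerate. The asymptotic
covariance of $(\log a, b)$ is $\sigma^2 (J^\top J)^{-1}$ with the
analytic Jacobian.

A single fit is shared by both epochs — the assumption being that the
height–biomass relationship itself did not change through the
disturbance, only the heights did. ACD is 0.47 × AGBD (the conventional
carbon fraction of dry biomass), applied on ~0.5-ha analysis cells. The
cells are built by block-averaging the 5 m TCH grid by an integer factor
(default 14, i.e. 70 m ≈ 0.49 ha): an exactly half-hectare cell
(70.71 m) cannot align with a 5 m grid, and grid alignment was chosen
over exact area.

`monteCarloACD()` propagates uncertainty by parametric bootstrap: each of
1000 draws adds independent $\mathcal{N}(0,\sigma)$ residual noise per
cell (truncated at zero to keep carbon physical — a deliberate, small
deviation from the pure Gaussian model), and per-cell and landscape-mean
95% intervals are the 2.5/97.5 percentiles. By default only the residual
term is resampled. With `perturbParams = TRUE` each draw also samples
$(\log a, b)$ from the ML covariance; the pipeline uses this option for
landscape-level inference because residual noise averages out over cells
(width $\propto 1/\sqrt{n_\text{cells}}$, verified in the suite) while
parameter error does not — at landscape scale the allometry calibration,
not the residual scatter, dominates the uncertainty. Epoch change
(`acdChange()`) differences *paired* draws: both epochs share the
parameter-draw seed (so calibration error cancels exactly where it
should) and use distinct residual seeds (so residual noise stays
independent).

## Gaps: Zeta power law by Metropolis–Hastings

A canopy gap at threshold $h$ is a maximal 8-connected component
(diagonals included) of pixels with height ≤ $h$ on the 1.25 m grid. The
classic field definition uses $h = 2$ m; the analysis ladder extends to
20 m in 2 m steps. Single-pixel gaps count (no minimum-area filter), and
gaps touching the raster edge are *included* by default — excluding them
would bias against exactly the large gaps the analysis cares about in a
bounded study window — with `dropEdgeGaps = TRUE` available.

Gap sizes $k$ (in pixels, not m²) are modelled by the Zeta distribution,
the discrete power law on the positive integers:

$$f(k) = \frac{k^{-\lambda}}{\zeta(\lambda)},$$

where smaller $\lambda$ means relatively more large gaps. The exponent is
estimated by random-walk Metropolis–Hastings: normal proposals with SD
0.1 centred on the current value, a uniform prior on (1.01, 5), a chain
of 100,000 with 5,000 burn-in, thinned by 25 — leaving exactly 3,800
retained samples whose median and central 95% interval are reported.
Three sampler details are deliberate:

* Proposals below 1 are replaced by a fresh draw from the same proposal
  density (redraw-until-≥1); values landing in [1, 1.01) then die on the
  zero prior. The redraw makes the proposal mildly asymmetric near the
  boundary and no Hastings correction is applied — this mirrors the
  field's standard sampler exactly rather than an idealized one. The
  bias is negligible away from the boundary: the suite bounds the
  posterior median against a brute-force grid posterior (step 0.001) to
  within 0.02.
* $\zeta(\lambda)$ is evaluated once per proposal by `pracma::zeta`
  (relative error well below 1e-12 on the prior range), never by naive
  series truncation inside the loop.
* The likelihood needs only $n$ and $\sum \log k_i$, precomputed once.

Two epochs are compared by non-overlap of their 95% credible intervals —
a conservative criterion chosen because interval non-overlap is the
natural significance statement for two independent posteriors.

## Equilibrium canopy height: the transition matrix

Paired 5 m pixels are binned into 1 m height classes (class $c$ covers
$[c-1, c)$ m; heights exactly at the overall maximum fall in the top
class, and the class count is the ceiling of the maximum height over both
epochs). The count matrix $A$ has $a_{ij}$ = pixels starting in class $j$
and ending in class $i$. Column-normalizing $A$ gives a column-stochastic
matrix whose dominant right eigenvector — eigenvalue exactly 1, verified
to 1e-9 rather than silently renormalized — is the *projected
equilibrium*: the height distribution that would persist if the observed
interval's dynamics repeated indefinitely. Mean equilibrium height uses
class midpoints by default (`meanFrom = "edge"` is available; the choice
is a convention, and the difference is exactly half a class width).

Uncertainty: each column is a multinomial sample, so with the
conjugate uninformative Dirichlet prior (all concentration parameters 1 —
transitions a priori uniform over classes) the posterior of column $j$ is
Dirichlet$(a_{\cdot j} + 1)$. `steadyStatePosterior()` draws whole
matrices (10,000 by default), solves each for its stationary
distribution, and reports per-class 2.5/97.5 envelopes and a mean-height
CI. Dirichlet draws are strictly positive, so every sampled chain is
irreducible.

Sparse data need care that dense data never show. The *raw-count* matrix
of a desk-scale landscape routinely contains absorbing singleton classes
(one pixel enters a class and never leaves), making its stationary
distribution a degenerate spike; with several closed classes the
stationary distribution is not even unique, and `steadyState()` then
fails loudly, listing the closed blocks. The posterior routine therefore
anchors its reported point estimate on the *posterior-mean* matrix
(counts + 1, column-normalized), which is strictly positive, always
irreducible, and central in the posterior — with well-populated counts
the two estimates agree to the order of one pseudo-count per column.
Empty start classes under the point estimate get a uniform column with a
warning, which is exactly what the uninformative prior implies.

## Optical detectability: spectral mixture analysis

Whether such an event is visible to a multispectral satellite is tested
by linear spectral mixture analysis. Each pixel's reflectance is
decomposed over three endmembers — photosynthetic vegetation (PV),
non-photosynthetic vegetation (NPV), and shade — by least squares under a
hard sum-to-one equality constraint, solved exactly through the KKT
system. Fractions are *not* constrained non-negative (matching classic
sum-to-one SMA); negative fractions are counted and reported. Tree
mortality exposes dead wood, so the per-pixel change ΔNPV is the
detection signal: a one-sample two-sided t-test of mean ΔNPV = 0, and an
OLS regression of ΔNPV on ACD loss whose $r^2$ measures how well the
optical signal tracks the true carbon loss. ACD cells are paired with the
coarser optical pixels by area-weighted resampling. The package ships a
synthetic endmember set with the qualitative spectral shapes (NIR plateau
for PV, elevated SWIR for NPV, dark shade); real analyses should supply
sensor-specific endmembers via `endmemberSet()` or the CSV interface.

## Recovery bookkeeping

Recovery time is deliberately simple bookkeeping on observed growth
rates, bracketing the truth from two sides:

* **Long-term rule** (over-estimate): lost ACD divided by the long-term
  annual gain (default 0.49 Mg C ha⁻¹ yr⁻¹, an old-growth multi-decade
  trend) — an over-estimate because regrowth immediately after
  disturbance is faster than the long-term trend.
* **Two-phase rule** (under-estimate): an initial fast phase of elevated
  annual gains — estimated by `estimateElevatedGains()` as the mean gain
  in each of the 5 years following any year whose loss exceeds
  11.5 Mg C ha⁻¹ in an annual plot record — followed by the long-term
  gain. An under-estimate because not all of the landscape was disturbed,
  yet the rule applies the fast phase everywhere.

Year counts are the integer part of the continuous recovery time, with
one deliberate exception: any positive loss takes at least one year,
because regrowth is an annual increment, not a continuous flow (a loss
smaller than the first year's gain is still not recovered before that
year ends). A ceiling variant is available behind `rounding =
"ceiling"`. The optional baseline adjustment (`adjustBaseline()`) adds
`0.74 Mg C ha⁻¹ yr⁻¹ × 9 yr` to the loss, extrapolating pre-event carbon
accumulation between the reference survey and the disturbance; it is
additive, so split periods compose exactly.

## The synthetic landscape: what it does and does not establish

`generateCHM()` builds a square landscape of spatially autocorrelated
canopy height — white noise smoothed by a fixed-width moving average
(width 7 pixels by default), rescaled to the requested mean and SD
(defaults 22 m and 5 m, typical of old lowland tropical forest), and
truncated at zero — then carves disk-shaped gaps whose pixel areas are
Zeta-distributed (default exponent 2.3, in the range reported for
undisturbed neotropical canopies). A carved gap is the $k$ nearest pixels
to its centre, so the realized size is exactly the sampled size until
gaps merge; overlapping gaps merge, as coalescing real gaps do, which
also exercises the labeling code. `applyBlowdown()` carves additional
patches (default exponent 1.7 — disturbance shifts the distribution
toward large gaps) until a target fraction of total canopy *volume*
(summed pixel height) is removed; candidates that would overshoot the
target by more than ~4.5% of total volume are redrawn, so the realized
severity lands within ±0.05 of the request, and the true per-pixel
change is returned for use as an oracle. Simulated surveys scatter
uniform points over the surface with small vertical noise, mixed return
numbers and scan angles, so the filtering rules have something to do.

All generator randomness flows from one explicit seed per call through a
private RNG stream; no call touches or depends on global RNG state, and
every generator is bit-reproducible under a fixed seed.

What passing tests on this landscape establish: the estimators recover
known truth (allometry parameters, the Zeta exponent, carved severity,
mixture fractions), the samplers match independent oracles, intervals
have near-nominal coverage, and the full pipeline propagates a known
disturbance with the right signs and magnitudes. What they do not
establish: performance under real-world complications the generator
deliberately omits — terrain-correlated canopy structure, lidar
occlusion and penetration variability, non-Gaussian allometry residuals,
heteroscedasticity, spatially structured reflectance noise, atmospheric
effects, or gap shapes more complex than merged disks. Conclusions about
real data rest on the methods, not on these fixtures.

## Problem sizes and numerical conventions

The shipped demo and the reproduction script use a 210 m × 210 m
landscape (168² CHM pixels, 42² TCH pixels, 3 × 3 analysis cells of
70 m), ~1.8 raw points m⁻², full-length MCMC chains (100,000), 1,000
Monte Carlo carbon draws and 10,000 Dirichlet draws — sizes chosen so a
complete run takes about a minute on one core while every statistical
mechanism operates at its standard settings. The test suite additionally
shortens chains to 20,000 where a property does not depend on chain
length (bookkeeping, determinism, interval overlap), and keeps
full-length chains where calibration is the property under test.

Further conventions: nodata is -9999 on disk and `NA` in memory; grid
origins are lower-left corners and value matrices are stored north-up;
bilinear DTM sampling clamps coordinates in the outer half-pixel margin
to the centre grid (nearest-edge continuation); `aggregateMean()` drops
trailing rows/columns that do not fill a block; ties in the
nearest-pixel gap carving break deterministically by row then column;
and configuration files use the DCF `Key: value` dialect read by base
R, with comma-separated numeric lists.

## Known limitations

* The TIN tiling heuristic can differ from the global triangulation in
  the tile buffer zone when local point density is far below ~1 pt m⁻²;
  the suite checks interior agreement statistically, not exactly.
* The MH sampler reproduces the field-standard redraw rule without a
  Hastings correction; its small boundary asymmetry is bounded by the
  grid-posterior cross-check but not corrected.
* Recovery bookkeeping ignores future disturbance, climate trends and
  compositional change; it is a bracket, not a forecast.
* The equilibrium projection treats one observation interval as
  time-homogeneous dynamics; multi-interval chains are out of scope.
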