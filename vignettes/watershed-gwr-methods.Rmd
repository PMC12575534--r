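---
title: "Methods: upstream-corrected EC and geographically weighted regression over nested sub-watersheds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: upstream-corrected EC and geographically weighted regression over nested sub-watersheds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwrshed)
```

## The problem

River monitoring networks sample water at the pour points of nested
sub-watersheds: everything measured at a downstream site integrates the
signal of every catchment above it. A regression of raw electrical
conductivity (EC, mS/m — a bulk proxy for dissolved-ion load) on local
land use therefore confounds local effects with inherited upstream
signal. `gwrshed` implements an analysis chain that removes that
inheritance and then asks whether the land-use effects that remain are
spatially uniform or vary across the basin.

## The upstream-corrected statistic

For a sub-watershed $i$ with cumulative catchment area $S_i$ (km²) and
direct upstream sampled neighbours $u$,

$$\Delta EC_i \;=\; EC_i \;-\; \frac{\sum_{u} EC_u\, S_u}{S_i},$$

and $\Delta EC_i = EC_i$ at headwaters. The upstream observations are
mixed in proportion to the water volumes they represent (areas proxy
discharge under spatially uniform runoff), and the denominator is the
downstream node's *full* cumulative area, so the weights deliberately
sum to less than one: the shortfall is the dilution contributed by the
node's own drainage increment. We implement the statistic exactly in
this printed form rather than renormalizing the weights.

Two useful exact consequences, both enforced by tests:

* **Telescoping conservation.** On a single-outlet network,
  $\sum_i \Delta EC_i S_i = EC_{\text{outlet}} S_{\text{outlet}}$ —
  every upstream term cancels once, so the corrected values partition
  the outlet load.
* **Invertibility.** Traversing the network in topological order,
  $EC_i = \Delta EC_i + (\sum_u EC_u S_u)/S_i$ reconstructs raw EC from
  any prescribed $\Delta EC$ field (`invert_delta_ec()`); the synthetic
  generator relies on this inverse, and the round trip is exact to
  $10^{-10}$ on 200-node random trees.

Assumptions worth stating: EC mixes conservatively at confluences, area
is an acceptable proxy for discharge, and each node has one downstream
link (a tree, not a braided network). Estuarine sites where tidal
intrusion drives EC can be excluded (`exclude_nodes()`): they are
dropped as regression observations, but when such a site still carries
an EC observation it continues to feed the downstream correction,
because physical flow does not stop at an exclusion. If an excluded
upstream site lacks EC, the downstream node's value is flagged
`"unavailable"` — never silently imputed, since that would fabricate
the dependent variable.

## Land-use predictors

Covariates are grid-cell *counts* of nine land-cover categories per
sub-watershed (water bodies, built-up, paddy, cropland, grassland, bare
land, and three forest types: DBF, EBF, ENF), plus three composites
(evergreen `EBF_ENF`, broadleaved `DBF_EBF`, and total `FOREST`).
Counts can be supplied as a CSV or tallied from an integer-coded Esri
ASCII category raster plus a same-shape node-assignment raster
(`count_categories()`).

Whether counts should cover each node's *incremental* polygon or its
full nested catchment is genuinely open. The package defaults to
incremental polygons: $\Delta EC$ isolates the local increment's
contribution, so the local increment's land use is the consistent
covariate. `accumulate_counts()` provides the cumulative alternative
for sensitivity runs, and `predictor_matrix(..., proportions = TRUE)`
offers area-normalized shares; neither is the default.

## The model space

Forest cover may enter a model under exactly one subdivision scheme —
all three types $\{DBF, EBF, ENF\}$, deciduous/evergreen
$\{DBF, EBF\!+\!ENF\}$, broadleaved/coniferous $\{DBF\!+\!EBF, ENF\}$,
or merged $\{FOREST\}$ — because mixing schemes would double-count
cells. The deduplicated union of all subsets of the four schemes gives
13 admissible forest options (including "no forest term"); crossed with
the $2^6$ subsets of the six non-forest variables and excluding the
empty model, the space has $2^6 \times 13 - 1 = 831$ candidate models
per season. The intercept is always present and not enumerated.
Enumeration order is deterministic (binary order over the canonical
variable list), so scans are exactly reproducible.

## Global model and GWR

The global ("GLM") fit is Gaussian-identity ordinary least squares —
the reported diagnostics (adjusted $R^2$, $t$ values, VIF) are the OLS
toolkit. AIC counts $k = p + 2$ parameters (slopes, intercept, error
variance) and $AICc = AIC + 2k(k+1)/(n-k-1)$. VIF is
$1/(1 - R_j^2)$ from auxiliary regressions; perfect collinearity
reports `Inf` rather than erroring, and values ≥ 5 are the
multicollinearity filter in model selection.

The local model lets every coefficient vary with location:

$$y_i = \beta_0(u_i, v_i) + \sum_j \beta_j(u_i, v_i)\, x_{ij} + \varepsilon_i,$$

fitted at each site by weighted least squares with kernel weights
decaying with distance from that site. Defaults and their reasons:

* **Kernel: fixed-distance Gaussian,** $w = e^{-(d/b)^2/2}$; bisquare
  available. Bandwidths are expressed in metres, which only makes sense
  for fixed (not adaptive) kernels; Gaussian is the common default when
  the family is otherwise unconstrained.
* **Coordinates: polygon centroids** in a projected metric system; pour
  points can be supplied instead. Geographic (lon/lat) coordinates are
  rejected, never silently reprojected.
* **Bandwidth** is chosen by minimizing either the leave-one-out CV
  score (zero self-weight) or the GWR small-sample AICc,
  $$AICc = 2n\log\hat\sigma + n\log 2\pi +
    n\,\frac{n + \mathrm{tr}(S)}{n - 2 - \mathrm{tr}(S)},$$
  with $S$ the hat matrix and $\hat\sigma^2 = RSS/n$. Both criteria are
  computed on request and the configured choice is recorded in every
  output, mirroring analyses that use different criteria per season;
  the package does not guess a rule for choosing between them.
* The optimizer evaluates a 16-point coarse grid between the smallest
  positive and the largest pairwise distance (the objective can be
  multimodal), then refines the bracketing interval with
  golden-section/Brent search to $10^{-3}$ of the bracket width,
  keeping the grid point if refinement does not improve on it. On
  stationary data the effective-parameter penalty makes the AICc
  objective decrease with bandwidth, and the selected bandwidth runs to
  the bracket maximum — the fit degenerates gracefully toward OLS.

**Numerical edge cases.** A bandwidth so narrow that some location has
fewer positively weighted neighbours than coefficients raises a
per-location singularity error naming the site and suggesting a larger
bandwidth; during optimization such bandwidths simply score `Inf`. With
*exactly* noise-free responses the GWR residual sum of squares
underflows to rounding noise ($\sim 10^{-26}$), making
$\log\hat\sigma$ — and hence AICc — numerically meaningless; the
package does not special-case this, and the validation suite uses a
small noise floor where a stable AICc curve is required.

## Diagnostics for nonstationarity and autocorrelation

**Coefficient-variability F test** (after Leung, Mei and Zhang, 2000).
The spatial variance of the $k$-th local coefficient series is a
quadratic form $V_k = y' B_k'(I - J/n)B_k y / n$ in the observations;
under stationarity its expectation is $\sigma^2\,\mathrm{tr}(Q)$ with
$Q = B_k'(I - J/n)B_k/n$. The statistic
$F_3 = (V_k/\mathrm{tr}(Q))/\hat\sigma^2$ is referred to an F
distribution with $(\mathrm{tr}(Q)^2/\mathrm{tr}(Q^2),\;
\delta_1^2/\delta_2)$ degrees of freedom, where
$\delta_r = \mathrm{tr}([(I-S)'(I-S)]^r)$ and
$\hat\sigma^2 = RSS/\delta_1$. p values are reported unadjusted across
coefficients. In the infinite-bandwidth limit both $V_k$ and
$\mathrm{tr}(Q)$ vanish and the ratio is formally $0/0$; a coefficient
series that is numerically constant (relative spread below $10^{-8}$)
therefore reports statistic 0 and p 1, which is the scientifically
correct reading of "no spatial variance". The test suite checks the
test's operating characteristics by simulation: 500 stationary datasets
at $n = 60$ (fixed 25 km bandwidth, half the layout domain) must give a
per-coefficient rejection rate between 0.02 and 0.09 at
$\alpha = 0.05$, and 200 datasets with a slope spanning $-3$ to $3$
across the domain ($n = 100$, noise sd 0.5) must reject for that slope
at least 80% of the time.

**Residual autocorrelation.** Global Moran's I of model residuals,
$I = \frac{n}{\sum w_{ij}} \frac{\sum w_{ij} z_i z_j}{\sum z_i^2}$,
with expectation $-1/(n-1)$ and the randomisation-assumption variance
for the normal z test; a seeded permutation p value is available for
small samples. The weights scheme is an explicit, recorded choice —
row-standardized inverse distance between centroids by default,
k-nearest as an option — because Moran's I values are not comparable
across unstated weight schemes.

## The codified selection rule

"Choose the best of 831 models considering AICc, adjusted $R^2$,
multicollinearity and residual autocorrelation" is not an algorithm, so
the package fixes one defensible reading and logs everything needed to
re-rank under another: discard models with any VIF ≥ 5, prefer models
whose GWR residual Moran p exceeds 0.05, then take the minimum GWR AICc
with lexicographic tie-breaking. Every discarded model is recorded with
its reason; if nothing survives, the result says "no admissible model"
and lists the unfiltered top three rather than throwing.

## What the synthetic generator emulates — and what it does not

The generator (`generate_dataset()`) reproduces the statistical
structure the analysis assumes, at the scale of the kind of basin the
method targets:

* **Topology:** a single-outlet random tree of 54 nodes by default,
  grown with at most two upstream neighbours per node (dendritic
  confluences); incremental areas log-normal (sdlog 0.6) with mean
  $1880/54 \approx 35$ km², so the default basin drains roughly
  1,880 km²; centroids from a recursive fan-out embedding over a
  ~50 × 50 km projected domain.
* **Land use:** per-node category proportions from a Dirichlet with
  concentration $(0.5, 0.8, 1.5, 0.8, 0.5, 0.2, 5, 2.5, 4)$ over
  (water, built-up, paddy, crop, grass, bare, DBF, EBF, ENF) — forest
  holding roughly three quarters of the mass, as in rural Japanese
  mountain basins — converted to integer counts by a multinomial draw
  over the node's cell budget at 0.01 km² (100 m) cells, a coarsened
  stand-in for a 10 m land-cover product.
* **Response:** $\Delta EC$ built from coefficient surfaces (constant,
  linear gradient, or Gaussian bump) with noise sd 1 mS/m and per-
  predictor effect spread 2 mS/m (`effect_sd`), giving fits in the
  adjusted-$R^2$ range such studies report; the two seasons use
  different generating predictor pairs (WATER + PADDY vs WATER + EBF)
  with no temporal model. Raw EC is then produced by the exact
  downstream inversion, so the pipeline's correction step reverses the
  construction identically.

All randomness flows through per-call seeds derived from the single
configured seed; no global RNG state leaks.

What it does **not** emulate: real drainage geometry (no DEM), spatial
autocorrelation in land cover between neighbouring nodes (Dirichlet
draws are independent), measurement error in EC or areas, braided or
multi-outlet networks, and seasonal dependence between the two
responses. Passing the validation suite therefore demonstrates that the
*methods* behave as specified under their own assumptions — not that
those assumptions hold for any particular field dataset.

## Validation problem sizes

The test suite runs the confluence arithmetic on a three-node toy;
round-trip and conservation checks on 200-node random trees; GWR
against brute-force per-location solves at $n = 30$ and leave-one-out
refits at $n = 20$; the OLS limit at bandwidth $10^9$ m on $n = 60$;
F3 calibration with 500 + 200 simulations ($n = 60$ and $100$);
local-coefficient recovery (correlation > 0.9 against ground truth) on
a 200-node gradient-surface dataset; and a full 831-model scan at
$n = 60$ (seed 1) that must rank the generating predictor pair first.
Exhaustive scans over correlated compositional predictors can rank a
small superset of the true pair first at other seeds — AICc is not a
consistent selector — which is why the scan log, not just the winner,
is part of the output.

## Known limitations

* Distances are Euclidean in the projected plane; over-water or
  along-network distances are not offered.
* The GWR engine solves one weighted system per location
  ($O(n^2 p + n p^3)$ per bandwidth evaluation); comfortable into the
  thousands of nodes, not intended for $n \gg 10^4$.
* The F test's F reference is an approximation (moment-matched
  quadratic forms); its size is verified by simulation at the problem
  sizes above, not proven.
* Counts as covariates make coefficients scale-dependent (per grid
  cell); the proportion mode changes their meaning, and users must not
  mix the two within one scan.
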