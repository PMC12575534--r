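# gwrshed

Land use shapes river water quality, but monitoring sites on a river
network are **nested**: everything measured at a downstream station
integrates the signal of every catchment upstream of it. `gwrshed` is an
R package for analysing land-use effects on electrical conductivity (EC,
a bulk dissolved-ion indicator, mS/m) over such nested sub-watershed
hierarchies. It is aimed at watershed ecologists and environmental
statisticians who have per-site EC campaigns, a sub-watershed topology,
and land-cover data, and who want to know *which* land uses matter and
*where*.

## What it computes

**1. Upstream-corrected EC.** For sub-watershed *i* with cumulative
catchment area *Sᵢ* (km²) and direct upstream sampled neighbours *u*,

```
ΔEC_i = EC_i − ( Σ_u EC_u · S_u ) / S_i        (ΔEC = EC at headwaters)
```

The area-weighted mixture removes the inherited upstream signal, so ΔEC
isolates the local sub-watershed's contribution to the ionic load. The
statistic telescopes (Σ ΔECᵢ·Sᵢ equals the outlet load) and is exactly
invertible, which the built-in synthetic generator exploits.

**2. Exhaustive model enumeration.** Predictors are grid-cell counts of
nine land-cover categories plus three forest composites; forest terms
must come from a single subdivision scheme (all types, deciduous/
evergreen, broadleaved/coniferous, or merged). That yields
2⁶ × 13 − 1 = **831 candidate models** per season.

**3. Global and geographically weighted regression.** Each candidate is
fitted globally (OLS with VIF, AIC/AICc/BIC, adjusted R²) and locally by
GWR,

```
y_i = β₀(u_i, v_i) + Σ_j β_j(u_i, v_i)·x_ij + ε_i ,
```

with a fixed-distance Gaussian (or bisquare) kernel whose bandwidth is
optimized by leave-one-out CV or small-sample-corrected AICc.

**4. Diagnostics and selection.** Per-coefficient approximate F tests
for spatial nonstationarity (Leung et al. 2000), global Moran's I on
residuals under an explicit spatial-weights scheme, and a codified
selection rule (VIF filter → residual-autocorrelation preference →
minimum GWR AICc) with a full audit log.

A synthetic dendritic-watershed generator produces networks, land-use
tables and EC fields with known ground truth, so the whole chain is
testable end to end without field data.

## Worked example

```r
library(gwrshed)

cfg <- synthetic_config(n_nodes = 54, seed = 7)
ds  <- generate_dataset(cfg)            # network + land use + 2 seasons of EC

d <- delta_ec(ds$network, "irrigation") # upstream-corrected response
X <- predictor_matrix(ds$landuse, c("WATER", "PADDY"), ids = d$id)
coords <- as.matrix(ds$network$nodes[match(d$id, ds$network$nodes$id),
                                     c("centroid_x", "centroid_y")])

global <- fit_ols(X, d$delta_ec)
bw  <- optimize_bandwidth(X, d$delta_ec, coords, criterion = "cv")
fit <- fit_gwr(X, d$delta_ec, coords, bw$bandwidth)
print(bw)
print(fit)
f3_test(fit, global)
```

```
Optimal bandwidth 8876.657 m (gaussian kernel), minimizing CV score 61.7937
GWR fit: n = 54 , p = 2 , kernel = gaussian , bandwidth = 8876.657 m
effective parameters tr(S) = 10.54  AICc = 170.124  adj R2 = 0.8841
Local coefficient summary:
                 Min.   1st Qu.    Median   3rd Qu.      Max.
(Intercept)  3.458029  3.737258  3.785476  3.863387  4.105902
WATER       -0.009756 -0.009296 -0.007051 -0.005523 -0.004561
PADDY        0.006597  0.007156  0.007577  0.007789  0.008387
  coefficient statistic      df1      df2     p_value
1 (Intercept) 0.2862110 2.599923 44.41813 0.807248404
2       WATER 6.4842568 2.095145 44.41813 0.002981095
3       PADDY 0.4743163 2.836306 44.41813 0.691287926
```

Read: a ~8.9 km kernel; WATER's effect on ΔEC is negative everywhere
but varies significantly across the basin (F₃ p ≈ 0.003), while PADDY's
positive effect is spatially stable (p ≈ 0.69) — exactly the generating
structure of this synthetic season (a WATER gradient, a constant PADDY
surface). The full 831-model workflow is one call:

```r
scan <- run_scan(ds$network, ds$landuse, "irrigation", criterion = "cv")
print(scan)                      # ranked models + selection trace
write_scan_results(scan, "out")  # models_*.csv, local_coefficients_*.csv, ...
```

A thin command-line wrapper with `simulate`, `delta-ec`, `enumerate` and
`scan` subcommands lives at `inst/cli/gwrshed-cli.R`.

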