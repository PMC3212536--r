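# dungsurvey

Before/after analysis of line-transect dung surveys for forest
elephants: how much did a population change between two survey epochs,
and what spatial covariates explain where the animals remain?

The package was built around a two-epoch survey design used in a large
(~13,700 km²) Central African forest reserve: 110 line transects of
2.5–5 km at 51 sampling locations, walked once before and once after a
period of civil conflict, recording the perpendicular distance from the
line to every elephant dung pile. It provides every stage of that
analysis as tested, reusable functions, plus a synthetic
landscape/survey generator so the whole pipeline can be validated
end-to-end against known truth.

## What it computes

**Distance sampling.** A pooled detection function g(x) per epoch —
uniform, half-normal g(x) = exp(−x²/2σ²), or hazard-rate
g(x) = 1 − exp(−(x/σ)^−b) — is fitted by maximum likelihood of
f(x) = g(x)/μ on [0, w] and selected by AIC. The effective strip width
μ = ∫₀ʷ g(x)dx gets a delta-method CV. Dung density is the classical

    D = n / (2 μ L)

with encounter-rate variance from the between-location estimator
(locations are the independent sampling units), the CV decomposition
CV(D)² = CV(n/L)² + CV(μ)², and a log-normal 95% interval
(D/C, D·C), C = exp(1.96·√log(1+CV²)).

**Change inference.** A z-test on the density difference,
z = (D₁−D₂)/√(se₁²+se₂²); a per-location declined/same/increased
classification tested against uniform expectation by chi-square
(df = 2); and the conversion chain from dung to animals,
E = 100·D / (decay_days · defecation_rate) elephants/km², extrapolated
to a reserve population. An ivory-mass-to-carcasses conversion
(default 6.9 kg per elephant) is included.

**Spatial structure.** Ordinary kriging of per-location densities
(empirical semivariogram → weighted-least-squares spherical/exponential
model → exact ordinary-kriging solve with unit-sum weights) and
Getis-Ord Gi\* hotspot z-scores with binary distance-band weights
including the self term.

**Density-surface GAMs.** Quasipoisson GAMs of per-transect counts
nᵢ with offset log(2 μ lᵢ) (the effective area surveyed), cubic
B-spline smooths with curvature penalties, smoothing chosen by GCV
n·D/(n−edf)², Pearson-based dispersion, deviance explained, backward
deletion to the minimal adequate model, and a ranked univariate +
composite model report. Covariates: distances to roads, villages,
towns, the park boundary and headquarters, slope, habitat proportions,
and a composite deforestation index Iₜ = Σⱼ aⱼ/dⱼ (area of non-forest
in grid cell j over distance to it), screened for collinearity at
|r| ≥ 0.6.

## Worked example

Working from a published-style survey summary (counts, effort,
effective strip widths and CVs):

```r
library(dungsurvey)
d1 <- density_estimate_from_summary("1995", n = 460, L = 280, esw = 2.01,
                                    k = 51, cv_encounter = 0.1863,
                                    cv_density = 0.1907)
d2 <- density_estimate_from_summary("2006", n = 286, L = 280, esw = 2.40,
                                    k = 51, cv_encounter = 0.2808,
                                    cv_density = 0.2870)
print(change_report(d1, d2))
```

```
Change 1995 -> 2006: D 4.09 -> 2.13 /ha (48% decline)
  z = 1.978, one-sided p = 0.0239
  elephants/km2 0.47 -> 0.24; population 6439 -> 3288 (loss 3151)
```

That is: dung density fell from 4.09 to 2.13 piles per hectare, a 48%
decline that a one-sided z-test calls significant (p ≈ 0.024);
converted at 19.77 piles/elephant/day and 44-day dung survival this is
0.47 → 0.24 elephants/km², i.e. a loss of 3151 animals over a
13,700 km² reserve.

The full simulated workflow lives under `analysis/`:

```sh
Rscript analysis/01_simulate.R              # synthetic landscape + two surveys
Rscript analysis/02_detection_density.R     # detection fits, density table
Rscript analysis/03_change_inference.R      # z-test, classification, conversions
Rscript analysis/04_spatial_patterns.R      # kriging + Gi* hotspots
Rscript analysis/05_density_surface_models.R# covariates, GAM reports
```

Each stage prints what it found and writes its tables under
`results/`.

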