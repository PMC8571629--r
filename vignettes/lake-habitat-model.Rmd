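---
title: "From water clarity to manatee habitat: the lakesav methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From water clarity to manatee habitat: the lakesav methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lakesav)
```

## The problem

Shallow tropical lakes connected to large sediment-laden rivers can be
nutrient-rich yet nearly bare of submerged aquatic vegetation (SAV),
because suspended sediment — not phytoplankton — controls water clarity
and hence the light reaching the bottom. For herbivorous aquatic mammals
such as manatees, which need both food plants and water at least about
2 m deep, this combination makes habitat quality strongly seasonal: when
the water level recedes, most of a flat, shallow basin becomes too
shallow or dries out entirely.

`lakesav` chains the standard limnological models that quantify this:
station chemistry → trophic state; Secchi depth → light attenuation →
maximum depth of plant colonization; distance-to-outlet → clarity
surface → percent light at the bottom → predicted SAV classes; predicted
vs sonar-observed SAV → confusion-matrix skill; bathymetry − drawdown →
suitable-depth area.

## Model chain and assumptions

**Light attenuation.** Downwelling irradiance is assumed to decay
exponentially (Lambert–Beer): $I_z/I_0 = e^{-KZ}$. Since field surveys
of this kind carry a Secchi disk rather than a light meter, $K$ is
estimated by the Poole–Atkins relation $K = c/\mathrm{SD}$ with
$c = 1.7$ (dimensionless, configurable; sensitivity checks typically
vary it over 1.6–2.0 with little effect when clarity is poor). The
maximum depth of colonization for a plant community persisting at a
fraction $f$ of surface light is then linear in Secchi depth:
$\mathrm{MDC} = -\ln(f)\,\mathrm{SD}/c$, with slope
$-\ln(0.2)/1.7 \approx 0.9467$ for the default $f = 0.2$
(angiosperm-dominated communities; charophytes would use $f = 0.11$).
All light values are kept as fractions in $[0,1]$ internally; percent
formatting happens only in reporting.

**Clarity extrapolation.** Station-mean Secchi depth is regressed on the
straight-line (Euclidean) distance to the lake outlet — the entry point
of turbid river water — and the fitted line (default
$\mathrm{SD} = 0.073X + 0.69$, $X$ in km, SD in m) is applied to a
distance raster. The distance is deliberately geometric, not a
least-cost water path: that is how a GIS Euclidean-distance surface from
a single source cell behaves, and with a compact basin the difference is
negligible. Units matter: with the slope in metres of clarity per
kilometre of distance, basin scales of order 10 km give the observed
0.7–1.65 m clarity range.

**Classification conventions.** Light classes are half-open, closed on
the left: class 1 below 0.15, class 2 in $[0.15, 0.25)$, class 3 at or
above 0.25; biovolume classes use 10% and 25% the same way. The two
interval systems partition their domains, so every cell maps to exactly
one class. "Presence" is class ≥ 2 in both layers. These thresholds are
arguments everywhere they are used.

**Validation.** Predicted and observed presence/absence layers are
compared on a seeded uniform random subsample (default 20%) of the cells
that are non-missing in both layers. The seven metrics are the standard
ones; two conventions deserve a note. First, the error rate is
implemented as $(F_p+F_n)/T$ — the complement of accuracy. (Validation
tables in the applied literature occasionally typeset the numerator as
$T_p+F_n$, which is the observed-positive margin, contradicts the
accuracy complement, and is not what their printed percentages encode.)
Second, the Matthews correlation coefficient evaluates the product under
the square root as a sum of logarithms, so counts from large rasters
cannot overflow; when a marginal is zero MCC falls back to 0 and is
flagged, while ratio metrics with empty denominators are reported as
`NA` and named, never silently zeroed.

**Morphometry and recession.** Area is wet-cell count times cell area;
volume is summed depth times cell area; the hypsographic curve reports
the fraction of wet area strictly shallower than each threshold, with
thresholds extended one step past the maximum depth so the curve closes
at 1. The drawdown simulation subtracts a uniform water-level decrease
(no hydrodynamics), partitioning the original wet area into dried
(≤ 0 m), shallow ($< 2$ m) and suitable ($\ge 2$ m) fractions; the
suitability depth is the conventional minimum for manatees and is a
parameter. Connectivity of the remaining deep cells is *not* assessed —
an isolated deep hole counts as suitable area.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `poole_atkins_k` | 1.7 | — | Secchi-to-attenuation proxy constant |
| `light_fraction_mdc` | 0.20 | fraction | light level defining MDC |
| light thresholds | 0.15, 0.25 | fraction | SAV class edges |
| biovolume thresholds | 10, 25 | % | observed class edges |
| `cell_size` | 16 | m | raster resolution |
| `subsample_fraction` | 0.20 | fraction | validation sample |
| `suitability_depth` | 2 | m | minimum habitat depth |
| drawdowns | 1, 2, 2.5, 3 | m | recession scenarios |

TN/TP limitation uses the mean of per-sample ratios, not the ratio of
mean concentrations: the per-sample ratio is the quantity with the
ecological interpretation, and averaging it is the only convention under
which a published grand mean near 19 is reconcilable with zone-level
nutrient means like 349/28. With constant TP the two conventions
coincide, which the tests exploit as an exact invariant.

Outlier screening discards values farther than 3 pooled standard
deviations from the pooled mean, per variable, across all
station-months, in a single pass. The grouping and the single pass are
design choices: iterating the screen or pooling within zones would
discard more, and with only ~72 records per variable a conservative
screen is appropriate. A consequence worth knowing: one enormous spike
in a small sample inflates the pooled SD enough that the spike itself
may fall *inside* 3 SDs — the screen targets moderate outliers in
reasonably sized samples, not single gross errors in tiny ones.

## The synthetic generator

`lake_sim_config()` defines the study conditions the package is tested
under: an elliptical basin capped at 5 m with a smooth low-order random
depth field, a 9-m channel corridor ending at a southern outlet, 18
stations sampled monthly for 4 months, clarity
$\mathrm{SD} = 0.69 + 0.073\,d_{km} + \mathcal N(0, 0.05^2)$, chemistry
interpolated between south and north zone means (TN 398.9 → 327.5, TP
40.6 → 25.1, TChl 29.9 → 15.2 µg/L) with additive Gaussian noise at 15%
CV truncated at zero, a 16-m cell size and a 2.5-m seasonal amplitude.
Vegetation truth follows the package's own light model: biovolume runs
from 10% at the presence light threshold to 100% in full light, so it
declines with depth. Sonar detection noise adds biovolume jitter
(SD 5 points), false negatives (15% of vegetated cells missed) and
false positives (3% of dark cells given moderate biovolume) — rates
chosen once as plausible single-beam sonar behaviour, since the surveys
this emulates report ground-truthing but not error rates.

Because the observed layer is generated from the same optical model the
predictor uses, a passing pipeline demonstrates *internal consistency*
(with noise off, the confusion matrix is perfect and MCC = 1 exactly),
plus correct propagation of detection noise into the metrics. It does
not demonstrate that real SAV follows the light model, that clarity is
linear in distance beyond the fitted range, or that biovolume has
realistic spatial autocorrelation — the generator's field smoothness is
a free parameter, not an estimate. Real-survey quantities (zone means,
the regression $R^2$ suite, whole-lake vegetated fractions, hectare- and
cubic-metre-scale morphometry, recession percentages) therefore require
the actual deposited survey data; the tests verify their structure and
internal identities on synthetic lakes only.

## Numerical choices and degenerate inputs

- Secchi depths must be strictly positive; zero or negative values are
  domain errors, not silent `NA`s. Simulated Secchi noise is truncated
  at 0.05 m.
- A predicted clarity surface that would go non-positive anywhere stops
  with the offending distance range — a sign the linear model is being
  extrapolated somewhere it cannot go.
- Rasterization snaps cell edges to multiples of the cell size, carries
  coordinates on cell centres, aggregates by mean, and fills empty cells
  from occupied neighbours within one cell (the sonar tracks this
  emulates leave small gaps between transects); filling is disableable.
- Rounding in reports follows the conventions of published validation
  tables (whole percents, MCC to two decimals); machine outputs keep
  full precision. Worked optical values reproduce published ones to one
  unit in the last printed digit — e.g. an MDC of 1.31595… m against a
  printed 1.31, where the final digit depends on the rounding of the
  clarity input itself.
- Test and example problem sizes (grids of 24–96 cells a side, 100-grid
  oracle sweeps, 200-replicate coverage studies) were chosen so the full
  suite runs in well under a minute while keeping every check
  statistically meaningful; the coverage study uses nominal 95% CIs and
  asserts at least 93% empirical coverage over 200 replicates, the
  binomial slack at that sample size.

## Known limitations

- Clarity is modelled from distance alone; wind-driven resuspension,
  seasonal inflow reversal and chlorophyll contributions beyond the
  fitted regression are outside the model.
- The recession simulation ignores hydrology (uniform lowering) and
  habitat connectivity.
- The Euclidean distance crosses land; for strongly lobed lakes a
  water-path distance would differ.
- No reprojection: all coordinates are assumed planar metres.
- The ESRI ASCII raster writer/reader is the only raster I/O; it is
  lossless for these grids but carries no CRS metadata.
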