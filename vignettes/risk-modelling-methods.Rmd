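---
title: "Methods: thermal-envelope risk modelling of western corn rootworm spread"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal-envelope risk modelling of western corn rootworm spread}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dvvrisk)
```

## The modelling problem

The western corn rootworm (*Diabrotica virgifera virgifera*) is a
monophagous maize pest with one generation per year. Its activity,
establishment and generation completion are governed by temperature, so its
potential European range can be approximated by a climate envelope: a cell
is at risk when its temperatures exceed the species' biological thresholds
for long enough. `dvvrisk` implements that envelope end to end — synthetic
climate in, country-level risk classes and spread maps out — with every
stage testable offline.

A climate envelope deliberately ignores dispersal pathways other than
contiguous spread (trade, transport, wind), biotic interactions, soil and
water constraints, and overwintering egg survival. The outputs are
potential thermal limits, not forecasts of realised invasion.

## Synthetic climate generator

No gridded observational product ships with the package; instead the
generator produces fields with the structure the analysis relies on:

* monthly mean `T(lat, m) = a − 0.7·lat + 10·cos(2π(m − 7)/12) + ε`, with
  the intercept `a` fixed so July at 45°N is 22 °C. The 0.7 °C per degree
  latitude gradient and the 10 °C seasonal half-amplitude are round values
  in the range European station climatologies show; they put the July
  12.5 °C isotherm in the right band of latitudes for the suitability
  frontier to be interesting;
* `ε ~ N(0, 0.5² °C)` per cell and month, seeded (default seed 42), so that
  identical parameters reproduce bit-identical grids;
* annual grids add a linear trend `0.04 °C/yr · (year − 2005.5)` — about
  1.3 °C of warming over 1991–2024, consistent with the observed European
  trend — plus a smooth low-frequency anomaly surface built from a seeded
  6-term trigonometric basis, so coherent "regions of stronger warming"
  exist by construction. Centring the trend on 2005.5, the midpoint of the
  1991–2020 reference, makes the reference-period mean equal the
  climatology exactly when noise is zero (a tested identity).

What the generator does **not** emulate: orography, coastlines and maritime
gradients, interannual autocorrelation, extremes beyond a constant
mean-to-max offset. Tests passing on synthetic grids therefore validate the
algorithmic contracts (anomaly arithmetic, threshold logic, monotonicity),
not skill on real climate fields.

Grid conventions, chosen once: WGS84 lon/lat, 0.25° cells, cell-center
registration, half-open cell ownership `[edge, edge + res)`, Europe box
10°W–40°E × 35–70°N. Months are 1-based with the seasonal peak at July.

## Warming schedule and anomalies

Projected warming relative to pre-industrial is an affine schedule:
+1.4 °C at 2024 rising 0.2 °C per 5 years, hence +1.8 °C at 2034, +2.6 °C
at 2054, and — by linear extrapolation, since the third risk horizon needs
it — +3.4 °C at 2074. The schedule is taken from the tabulated 5-year
values. Projection grids are built by shifting
the 2024 synthetic grid by `Δ(h) − Δ(2024)`, i.e. the schedule's increment
beyond the anchor year, so the historical trend is not double-counted.

Historical deviations (DAT) are per-cell differences of period means
against the 1991–2020 reference, computed for six cumulative periods
(1991–1992, 1992–2002, 1992–2012, 1992–2020, 1992–2022, 1992–2024). Annual
means are unweighted means of the 12 monthly means by default; a
day-weighted variant exists behind a flag. Whether map-level anomalies are
annual or warm-season is exposed as a choice: annual is the default,
April–September means are available via `warm_season_mean()` with the
15 °C adult-activity threshold retained for the presence-overlap analysis
only.

## Suitability rules

Beetle thresholds: monthly mean ≥ 12.5 °C for adult activity, ≥ 9 °C for
establishment in colder climates, each required for at least **two
consecutive calendar months** within April–September. Comparisons are
inclusive (≥), and "consecutive" means adjacent calendar months — the data
are monthly, so a 60-day sliding window is not meaningful here. The two
thresholds are ordered, so the activity mask is provably nested in the
establishment mask, and both are monotone under uniform warming; both
properties are asserted cellwise in the tests. The species' own heat-sum
requirement per generation is represented by this persistence proxy rather
than an explicit degree-day total, for which no harmonised European
parameters exist.

Maize: GDD(base 10 °C) ≥ 1000 (the lower bound of the 1000–1400 maturity
range — hybrids at the short end exist, so the envelope uses the permissive
bound), at least one growing-season month ≥ 10 °C (air temperature proxies
soil), and no growing-season monthly maximum above 35 °C. When a grid
carries no maxima, they are proxied as mean + 6 °C, a typical summer
mean-to-max spread; the proxy choice is recorded in the mask metadata.

GDD uses non-leap month lengths: `Σ_m max(0, T_m − base) · days(m)`. No
daily downscaling is attempted — the whole pipeline is monthly.

## Spread model

The infested fraction of suitable area follows the logistic
`P(t) = k/(1 + ((k − p0)/p0) e^{−rt})` with `k = 1`, `p0 = 0.40` at 2024
and `r = 0.1117/yr`. The single calibration condition is that 95% of
suitable area is infested by 2054, so `r` is derived in closed form by
`fit_logistic_rate(0.40, 0.95, 30)`; `p0 = 0.40` represents the roughly
two-fifths of climatically suitable Europe already occupied by 2024. The
growing quantity is the fraction of *suitable area* — the natural percent
scale for an envelope model — rather than absolute area or a country
count, which would need additional normalisations.

Spatially, each year's target cell count `round(P(t) · n_suitable)` is
filled from suitable, uninfested cells within 50 km (haversine, R =
6371 km) of the infestation frontier, nearest first, ties broken
lexicographically by (lat, lon) — deterministic by construction, with a
seeded stochastic variant behind a flag. 50 km/yr is in the upper range of
observed natural front advances and exceeds the 0.25° cell spacing, so the
frontier is never artificially pinned; at coarser test resolutions the
radius must scale with the cell size (150 km at 1°). Infestation is never
revoked — eradication appears in presence records as a data status, not in
the model. If the reachable frontier is exhausted the shortfall is
recorded, never silently filled. Affected-age maps use 5- and 15-year band
edges (newly/recently/longer affected); the bands are display conventions,
recorded in output metadata.

## Country risk classification

The packaged 29-country reference table assigns LR/MR/HR classes per
horizon from centroid coordinates. The package realises this with the
simplest rule consistent with the table's latitude gradient: per horizon,
a high-risk latitude cut at the midpoint between the highest-latitude HR
country and the lowest-latitude MR country, and likewise for MR/LR. The
reference table is perfectly latitude-separable at all three horizons
(verified exhaustively: 87/87 cells reproduced; recalibration on the
reproduced table is idempotent), which is what makes the midpoint rule
well-defined. Longitude is carried but unused by the default rule.
Moldova stays in the risk fixture but is excluded from presence fixtures,
mirroring its exclusion from recent distribution assessments; Turkey's
centroid is kept as a table row even though its European extent is
debatable.

Buffer zones are geodesic circles around HR and MR centroids: 300/200 km
(HR/MR) at 2034, scaled 1.5× at 2054 and 2× at 2074. Risk-zone maps of
this kind carry no canonical radii, so these are package conventions,
logged in the GeoJSON metadata.

## Maize area accounting

Per-country areas are the mean of the last two annual values (million ha),
rounded **half-up** to one decimal and scaled to thousand ha — the rule
that maps a 2.5 Mha average to 2500 k ha. Bands partition areas into
small `[0, 500)`, moderate `[500, 1000)`, large/medium `[1000, 2000]` and
very large `(2000, ∞)` k ha; merging the top two recovers the three-band
intensive/moderate/weak reporting view. The continental projection is
exponential, `6000 · e^{rt}` k ha with `r = ln(20/6)/30`, matching the
6 Mha (2024) and 20 Mha (2054) endpoints; exponential rather than linear
because the joint series depicts accelerating expansion, with a linear
variant available. The packaged per-country table is synthetic (the
package ships no third-party statistics); Nordic rows are set in the small
band without derivation, as no formula for them exists.

## Numerical and testing choices

* All stochastic operations take explicit seeds; per-year anomaly seeds are
  derived from the base seed and the year so a year's field is independent
  of the requested range. Two runs of the full pipeline with one config are
  byte-identical in their CSVs (tested).
* Rasters are exchanged as Esri ASCII grids written at full double
  precision (lossless round trip, NODATA preserved); vectors as GeoJSON;
  configs as flat key-value YAML with a stable round trip.
* Property suites run at 1° resolution: the persistence rule is checked
  against a brute-force run scan on 10⁴ random month-vectors; the logistic
  closed form against forward-Euler integration (dt = 0.01, 50 years,
  relative error < 10⁻³); parameter recovery refits 100 noisy synthetic
  series (σ = 1 percentage point, 31 annual points) and recovers `r`
  within ±10% and `p0` within ±0.05 on every seed; spread containment and
  monotone growth are asserted state by state. The full suite takes about
  two minutes on one CPU.
* Degenerate inputs fail loudly: empty year ranges, non-integer grid
  extents, seeds outside suitability, non-separable calibration tables
  (with the violating countries named), malformed raster headers (with the
  line number).

## Known limitations

The centroid classifier and the gridded suitability masks are parallel
outputs, not reconciled — a country's class does not constrain its cells'
masks. The spread simulation's single-radius kernel cannot reproduce
human-assisted long jumps (e.g. the isolated France 2002 detection).
Suitability is purely thermal: soil, moisture, photoperiod and economics
are out of scope, so northern "suitable" cells indicate thermal envelope
only. And the synthetic climate's idealised geography means map-level
outputs are structurally, not geographically, faithful.
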