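---
title: "Measuring exposure segregation from mobility traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring exposure segregation from mobility traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exposeg)
```

## The measurement problem

Residential segregation indices describe where people sleep, not whom they
meet. The quantity this package estimates — *exposure segregation* — is the
Pearson correlation, within a region, between a person's socioeconomic
status (SES, proxied by the estimated monthly rent of their home) and the
mean SES of the people they physically cross paths with. A value of 0 means
encounters are as diverse as random mixing; 1 means people only ever
encounter others of identical SES. The familiar *neighbourhood sorting
index* (NSI) — the correlation between a person's SES and their home
tract's mean SES — is the special case in which the "exposure network" is
replaced by uniform mixing among tract co-residents, which
`synthetic_tract_network()` makes explicit.

The pipeline runs from raw device pings to estimates:

1. **Trace hygiene** — drop pings with reported accuracy worse than 100 m;
   remove duplicate devices (>80% of pings exactly identical to another
   device's).
2. **Home inference** — linear interpolation of each device's track onto
   hourly epochs; hours in the local 18:00–09:00 window with <50 m
   displacement to the next hour are "stationary night" positions; a home
   requires such positions on ≥3 local dates with ≥60% of them within 50 m
   of their centre, and is the coordinate-wise median of the in-radius
   positions. Devices with fewer than 500 pings are skipped.
3. **SES linking** — nearest property in a rent registry, dropped beyond
   100 m; rents winsorized at $20,000/month; optional percentile-rank and
   block-group-income alternatives.
4. **Exposure network** — a path crossing is a pair of pings from distinct
   devices strictly closer than D = 50 m (great-circle) and T = 5 minutes.
   Edges carry the earlier ping's timestamp and the midpoint of the two
   pings.
5. **Annotation** — at-home (50 m), home-tract component (both/one/neither
   endpoint inside their own home tract), POI and hub polygons (smallest
   containing polygon under overlap), road/rail proximity (20 m).
6. **Estimation** — the attenuation-corrected correlation below, plus
   decompositions by component, tie strength, activity category, 3 h time
   window, and hub.
7. **Bridging index** — residents clustered by nearest hub;
   `sum(|H_k| * Gini(H_k)) / (|V| * Gini(V))`.

## The estimator and its attenuation correction

Let `x_i` be ego `i`'s SES, standardized to unit variance over the egos of
a region, and `y_ij` the raw SES of the `j`-th *distinct* exposure partner
of ego `i` (repeated exposures to the same partner are not upweighted).
The naive estimator correlates `x_i` with the partner mean
`mean_j(y_ij)`. When partner samples are sparse, that mean is a noisy
estimate of the ego's latent exposure-pool mean, and the correlation is
biased towards zero — classical attenuation.

`fit_mixed_model()` instead fits the random-intercept model

    y_ij = a * x_i + b + eps1_i + eps2_ij,
    eps1_i ~ N(0, var1),  eps2_ij ~ N(0, var2)

by REML, and `corrected_exposure_segregation()` reports the model-implied
correlation between `x_i` and the latent pool mean `a * x_i + b + eps1_i`:

    r = a / sqrt(a^2 + var1).

The REML fit profiles the restricted likelihood over the variance ratio
`theta = var1 / var2`; given `theta`, the slope, intercept and `var2` have
closed forms from weighted least squares on ego means (weights
`n_i / (1 + n_i * theta)`), so the optimization is a bounded scalar search
(objective tolerance 1e-8, `var1` constrained to be non-negative). The
suite cross-checks the fit against lme4 and against the closed-form
balanced-design variance-component estimators.

### Degenerate regimes

Two regimes need explicit rules, both discoverable by simulation:

* **Perfect fit** (`var1 = var2 = 0`, e.g. every partner's SES equals the
  ego's): the model is noiseless and the estimate is `sign(a)`.
* **No ego-level signal.** Under complete random mixing the true `a` and
  `var1` are both zero, and the plug-in ratio `a / sqrt(a^2 + var1)`
  becomes 0/0: whenever the REML `var1` lands on its zero boundary (which
  happens with probability ~1/2 under the null) the ratio collapses to
  `sign(a) = ±1`, and otherwise to noise of magnitude ~0.1 — even though
  the estimand is 0. The estimator therefore first tests the fitted model
  against the i.i.d. null (no slope, no ego-level variance) with an ML
  likelihood ratio whose null distribution is the boundary mixture
  `0.5 chi2_1 + 0.5 chi2_2`. If the data are indistinguishable from random
  mixing (p > 0.001), the reported exposure segregation is 0 with note
  `"random_mixing"` — the estimand's value under that model. The level
  0.001 was fixed a priori: with thousands of egos, any substantively
  non-zero segregation rejects this null with power essentially 1, so the
  guard is inert away from the degenerate case.

Estimates are scale-invariant in SES (affine rescaling of rents leaves
them unchanged) and bounded in [-1, 1] by construction.

## The synthetic city

No public device-level mobility data exist at this granularity, so every
stage is exercised on a generator with controllable ground truth
(`city_config()`, `generate_city()`, `generate_traces()`). What it
emulates, and the conditions chosen once for the study:

* **Geometry** — a flat 10 × 10 km rectangle in metric coordinates with a
  declared WGS84 anchor; lat/lon via a local equirectangular inverse
  projection (50 m geometry is projection-insensitive at city scale).
  Tracts partition the rectangle as a grid or a Voronoi tessellation;
  default 25 tracts.
* **Rents** — log-normal with mu = 7.2, sigma = 0.55 log-USD/month
  (median ≈ $1,340, a plausible urban rent distribution). A share
  `tract_ses_autocorrelation` (default 0.6) of log-rent variance is a
  tract-level effect. The tract effect is a spatially smooth field (a
  random linear gradient plus noise) rather than i.i.d. across tracts:
  real cities have coherent richer and poorer sides, and without spatial
  coherence every hub catchment is automatically diverse, which would
  erase the bridging-placement contrast the generator exists to exhibit.
* **Traces** — at most one ping per device-hour (default 24 expected
  pings/day, matching roughly one ping per hour); night hours at home,
  two 2-hour outings per day at venues; positional noise is isotropic
  Gaussian with per-ping scale `accuracy_noise_sd * u` (`u` log-normal,
  mean 1; default 10 m), and the scale is reported as the ping's accuracy.
* **Venue choice** — a softmax over
  `-distance/1km - venue_homophily * |log target SES - log own SES| / sigma`.
  This generative model is the package's own stand-in: the phenomenon
  (SES-differentiated venues attracting SES-matched visitors) is
  documented in the field, but no published generative model or calibrated
  parameters exist; `venue_homophily = 2` was chosen once as a value that
  produces visible but not total venue sorting, and 0 disables SES
  sorting entirely.
* **Hubs** — polygons containing at least one POI. `"embedded"` places
  hubs at tract centroids spanning the SES range and gives their POIs the
  tract's typical rent as target SES (venues adapt to their
  neighbourhood); `"bridging"` places hubs midway between SES-dissimilar
  tract pairs with city-median target SES; `"random"` scatters them.
* **Artifacts** — a `duplicate_device_rate` (default 2%) of extra devices
  clone 90% of a host device's pings verbatim.

What the generator does *not* emulate: road-constrained movement, commute
rhythms, venue capacities and opening hours, device-ownership bias, bursty
ping schedules, multi-city systems. Passing tests therefore demonstrate
correctness of the measurement machinery and the direction of the designed
mechanisms, not calibrated real-world magnitudes.

Ground-truth co-location events are computed from the noiseless true
positions with the brute-force detector (only when the trace is small
enough for it), keeping the oracle independent of the indexed
implementation.

## Numerical and algorithmic choices

* **Thresholds at boundaries** — detection uses strict `< D` and `< T`;
  the accuracy filter keeps exactly-100 m pings; SES linking keeps
  exactly-100 m matches; stationarity is strict `< 50 m`; the at-home and
  road buffers are inclusive. Fixed once for bit-reproducibility.
* **Spatial index** — candidate ping pairs come from a uniform grid over
  locally projected coordinates (cell size `1.05 * D`) crossed with time
  buckets of width `T`, scanning the 3×3×3 neighbourhood; every candidate
  is exact-refined with the haversine distance, so the index changes
  speed, never results (worst case O(n²) when all pings share one cell).
  The suite proves set-equality against an exhaustive all-pairs oracle.
* **Episode collapse** — consecutive qualifying ping pairs of a dyad with
  inter-event gaps `< T` collapse into one exposure event carrying the
  first pair's attributes, avoiding ping-rate artifacts in tie-strength
  counts; `collapse = FALSE` preserves raw ping-pair edges. Whether one
  co-presence episode should count once or many times is genuinely
  underdetermined; both behaviours are first-class.
* **Home centre** — the stationary-night cluster centre is the
  coordinate-wise median (even counts: midpoint of the central order
  statistics), O(k) per device rather than the O(k²) medoid; at 50 m
  scales the two differ negligibly for compact night clusters.
* **Percentile conventions** — rent percentiles are average-rank
  percentiles scaled to [0, 100] (a single tie group maps to 50);
  bootstrap CIs use the Efron `(R+1)·alpha` order-statistic percentile
  interval, and no p-value is ever adjusted for multiple comparisons.
* **NSI convention** — the ego is included in its tract mean (census
  convention); the exposure measure never counts the ego as its own
  partner. The discrepancy vanishes as tract size grows; the
  dense-tract-network equivalence check therefore uses tracts with ~90
  residents, where the gap is well under 0.01.
* **Per-stratum decomposition** — partner deduplication and record
  rebuilding happen within each stratum; region-level standardization of
  `x` is reused (correlations are scale-invariant, so this is
  inconsequential). Strata failing estimator preconditions are reported
  as not-estimable rows, not errors.
* **Bridging index** — residents cluster on hub polygon *centroids*
  (the hub's point representation is otherwise unspecified); Gini is the
  population form computed by the sorted O(n log n) identity, and the
  variance-based variant replaces Gini in the same weighted ratio.
  Splitting clusters can move the index either way, so no
  refinement-monotonicity is asserted anywhere.

## Problem sizes used in validation

The suite's simulations are sized to run on a single CPU: estimator
debiasing uses 200 replicates of 2,000 egos × 3 partners at true
correlation 0.5 (naive bias ≤ −0.05, mixed-model |bias| < 0.02);
detector-oracle equivalence runs 100 random instances up to 5,000 pings;
the mechanism experiments average 10 seeded cities of 250 residents × 7
days per condition; bootstrap coverage is measured with 2,000 outer
replicates of n = 50 at 500 inner resamples (the percentile interval's
true coverage there is ≈ 93.6%); Steiger's Z type-I error uses 5,000
simulated null datasets of n = 200. The full default pipeline (2,000
individuals, 30 days, ~1.4 M pings) runs end-to-end in about 90 seconds.

## Known limitations

* The softmax venue-choice model and its parameters are uncalibrated to
  any published quantity; mechanism results are directional, not
  quantitative.
* Exact floating-point equality defines duplicate-device ping identity
  and identical-home collisions (the underlying rule is stated without a
  precision); real pipelines may need a tolerance.
* Exposure annotations use the event midpoint, not each contributing
  ping's own position — an interpretation, flagged as such.
* The equirectangular index assumes region-scale extents (tens of
  kilometres); continental inputs should be processed per region.
* With very small regions (few egos) the random-mixing guard will report
  0 for weak true segregation — the honest statement that the data cannot
  distinguish it from mixing.
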