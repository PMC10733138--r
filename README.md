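# exposeg

Exposure segregation from GPS mobility traces.

Residential segregation indices describe where people live; they say
nothing about whom people actually encounter at work, in shops, or on the
street. **exposeg** measures *exposure segregation*: within a region, the
Pearson correlation between a person's socioeconomic status (SES, proxied
by the estimated monthly rent of their home) and the mean SES of the
people they physically cross paths with — two devices within *D* = 50 m
and *T* = 5 min of each other. A value of 0 is random mixing; 1 is perfect
sorting. The classic neighbourhood sorting index (NSI) is the special case
in which everyone "meets" only their census-tract co-residents, uniformly
at random.

The package is the full measurement pipeline, for researchers in urban
epidemiology, computational social science and spatial demography:

* **Trace processing** — accuracy filtering, duplicate-device removal,
  home inference from stationary night-time pings, rent linking with the
  standard quality filters, winsorization, alternative SES measures.
* **Exposure network** — indexed space–time path-crossing detection with
  an exhaustive brute-force oracle, co-presence episode collapsing, tie
  strength.
* **Annotation** — at-home, home-tract component (both/one/neither), POI,
  hub, and road proximity tags for every exposure.
* **Estimation** — the core statistic with an attenuation correction.
  With sparse partner samples the naive correlation between `x_i` and the
  observed partner mean is biased towards zero. exposeg fits the
  random-intercept model

  ```
  y_ij = a·x_i + b + ε¹_i + ε²_ij,   ε¹_i ~ N(0, σ₁²),  ε²_ij ~ N(0, σ₂²)
  ```

  by REML (own profile-likelihood implementation, cross-checked against
  lme4) and reports the implied correlation with the latent exposure-pool
  mean, `a / sqrt(a² + σ₁²)` — unbiased even when each ego has only a few
  observed partners. Decompositions by tract component, tie strength,
  activity category, time of day and hub re-estimate per stratum.
* **Bridging index** — residents clustered by their nearest commercial
  hub; `Σ|H_k|·Gini(H_k) / (|V|·Gini(V))` measures whether hubs bridge
  economically diverse neighbourhoods (1) or serve SES-uniform catchments
  (0).
* **Inference** — seeded percentile bootstrap, Spearman tests, Steiger's
  Z for dependent correlations.
* **Synthetic city** — device-level mobility data of this granularity are
  not public, so the package ships a generator with controllable ground
  truth: spatially autocorrelated log-normal rents, night pings at home,
  SES-homophilous venue choice, hub placement regimes (bridging /
  embedded / random), ping noise and duplicate-device artifacts. Every
  pipeline stage is validated against it.

## Worked example

Simulate a 500-person city with SES-targeted venues and hubs embedded in
rich and poor neighbourhoods, then run the whole pipeline:

```r
library(exposeg)

cfg <- city_config(n_individuals = 500, n_tracts = 16, n_pois = 40,
                   n_hubs = 4, venue_homophily = 2,
                   hub_placement = "embedded", seed = 42)
res <- run_pipeline(pipeline_config(city = cfg), quiet = TRUE)
res$estimates
#> # A tibble: 6 × 8
#>   stratum               method estimate ci_low ci_high n_egos n_obs note
#>   <chr>                 <chr>     <dbl>  <dbl>   <dbl>  <int> <int> <chr>
#> 1 overall               mixed     0.856     NA      NA    500 43232 <NA>
#> 2 overall               naive     0.847     NA      NA    500 43232 <NA>
#> 3 overall               nsi       0.729     NA      NA    500    NA <NA>
#> 4 both_in_home_tract    mixed     0.761     NA      NA    376  4544 <NA>
#> 5 neither_in_home_tract mixed     0.863     NA      NA    489 22094 <NA>
#> 6 one_in_home_tract     mixed     0.806     NA      NA    500 18386 <NA>
res$bridging
#> <exposeg_bridging> index = 0.7927 (gini), K = 4 clusters, 500 residents
```

Reading the numbers: from 360,000 retained pings the pipeline inferred
all 500 homes, linked them to rents, and detected 32,581 exposure events.
Overall exposure segregation is 0.86 — venue targeting (`venue_homophily
= 2`) makes encounters strongly SES-sorted, and the corrected estimate
sits slightly above the naive one because partner samples are large here
(≈86 distinct partners per ego; with sparse partners the gap is large —
see the estimator tests). The bridging index 0.79 says the four hub
catchments are somewhat less diverse than the city as a whole, as
expected when hubs are embedded inside SES-coherent neighbourhoods.

`autoplot()` methods exist for estimate tables, bridging results and city
maps; `tidy()`/`glance()` for fitted models and bridging results.

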