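# icesink

Sea-ice presence shapes how much organic carbon sinks out of Arctic surface
waters and which surface microbes ride the sinking aggregates into the deep
sea. `icesink` is an R package for scientists analysing that coupling: it
implements the full computational chain of a sea-ice / carbon-export /
vertical-connectivity study — from Lagrangian backtracking of sinking
particles through gridded ocean fields, via sediment-trap and marine-
aggregate biogeochemistry, to Bayesian microbial source tracking and
differential-abundance analysis of 16S ASV tables — together with a
synthetic-data generator that produces every input with known ground truth,
so the whole pipeline is testable end to end without external data.

## What it computes

* **Transport** — particles released near the seafloor are integrated
  backward through a reversed flow field (horizontal step
  `-(u, v) dt`, vertical rise at the sinking speed `w_s` minus the model
  vertical velocity; explicit Euler at 30-min steps). Surface origins are
  classified against the 15% sea-ice concentration threshold, and
  trajectory statistics (median catchment radius, horizontal path length,
  % ice-covered origin, ice days, distance to the ice edge) are reported.
* **Particle flux** — ellipsoid volumes and equivalent spherical diameters
  (`ESD = (xyz)^(1/3)`), flow-chamber sinking velocities, trap fluxes
  (quantity / area / day), molar C:N, gel-image particle sizing
  (Otsu threshold + connected components at 12 um/px), the exponential
  flux–ice-distance model `y = a e^(bx)` (OLS on log flux, R² on the flux
  scale), Martin power-law attenuation `F(z) = F(z0) (z/z0)^(-b)`, and
  nutrient drawdown across the 50 m pycnocline.
* **Source tracking** — a collapsed Gibbs sampler estimating, for each
  particle-associated community, the mixture of free-living source
  communities plus an Unknown component:
  `P(z_i = v) ∝ (m_tv + n_tv + α)/(m_·v + n_·v + Tα) · (n_v + β)`,
  with α = β = 0.001, 100 burn-in sweeps, 10 restarts, rarefaction to
  5000 reads, and leave-one-out validation of the source set.
* **Enrichment** — per-ASV negative-binomial contrasts between consecutive
  water layers (median-of-ratios size factors, moment dispersions
  moderated by a mean-dispersion trend, exact conditional NB test, BH
  adjustment; enriched = |log2 fold change| > 1 and adjusted p < 0.1),
  family summaries, and the sequence footprint of PA-enriched ASVs in
  deep free-living and sediment communities.
* **Community statistics** — bias-corrected Chao1, Shannon diversity, PCA
  with explained-variance percentages, paired FL–PA Euclidean distances
  with regional rank tests, and permutation PERMANOVA (pseudo-F, R²,
  permutation p).

`run_pipeline()` chains all stages on the synthetic suite and writes
seed-stamped TSV/JSON summary tables in the layouts of the study's result
tables (trajectory summary, flux summary, mixing-proportion layer summary,
enriched-family table, footprint table).

## Worked example

```r
library(icesink)

## exponential POC-flux vs ice-edge-distance model on synthetic data
cfg <- synthetic_config(seed = 42)          # generating model: 13.6 e^(-0.015 x)
series <- make_flux_series(cfg, 200)
fit <- fit_ice_distance_model(series$distance_km, series$flux)
fit
#> flux = 13.4 * exp(-0.01495 * distance_km)   (R2 = 0.58, n = 200)
predict(fit, log(2) / 0.015)                # flux one half-distance away
#> [1] 6.7

## molar C:N of the ice-free drifting-trap fluxes (POC 63, PON 6.5 mg m-2 d-1)
molar_cn(63, 6.5)
#> [1] 11.3

## backtrack aggregates sinking at 52 m/d from 300 m above a 2350 m seafloor
fields <- make_velocity_field(cfg)
rel <- release_spec(lon = -5, lat = 79, seafloor_depth = 2350,
                    sinking_speed_m_d = 52,
                    release_dates = seq(130, 186, by = 7))
traj <- backtrack(fields$field, rel)
traj
#> trajectory_ensemble: 9 particles (surfaced=9); 9 surfaced in window
catchment_radius(traj)$median_km
#> [1] 186.9
classify_origin(traj, fields$ice)$pct_ice_covered
#> [1] 100
```

The fitted intercept (13.4 mg m⁻² d⁻¹ of POC at the ice edge) and decay
(−0.0150 km⁻¹, a flux half-distance of ~46 km) recover the generating
model within sampling error; the station in the ice-covered western half
of the synthetic domain receives particles whose surface origins are 100%
ice-covered, with a median catchment radius of ~190 km at the measured
sinking speed.

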