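# reefugia

Thermal-stress refugia analysis for coral reef climate ensembles.

On shallow reef shelves such as the Great Barrier Reef, tidal and wind
mixing carry surface heat downward and moderate summer temperature
extremes; corals in well-mixed water accumulate less bleaching stress
than their neighbours. `reefugia` provides a tested, reusable pipeline
to identify such thermal-exposure refugia from daily gridded SST
ensembles and to ask whether they survive twenty-first-century warming:

* **Climatology** — per-cell monthly means over 1985–2012, recentred by
  per-month least-squares regression to the epoch 1988.2857; their
  maximum is the Maximum Monthly Mean (MMM).
* **Thermal stress** — HotSpot = max(SST − MMM, 0); degree heating
  weeks DHW(t) = Σ₈₄ days HotSpot·[HotSpot ≥ 1 °C] / 7 (°C-weeks);
  annual maxima over austral years (1 Aug – 31 Jul, labelled by the
  ending year); spatial-median and ensemble trajectories.
* **Refugia** — cells at or below the 20th percentile of the 1999–2019
  mean annual-maximum DHW; multi-model agreement maps (0–5);
  per-year rank-based persistence.
* **Mixing energy** — tidal power P_tide = 4·k_b·ρ·u₀³/(3π) with
  k_b = 0.003, and wind mixing δ·k_s·ρ_a·w³/h with k_s = 6.4×10⁻⁵;
  refugia vs non-refugia comparison with a spatial block bootstrap over
  December–March of the mass-bleaching summers (2002, 2016, 2017).
* **Trajectories vs warming level** — non-refugia minus refugia DHW per
  year against the global-mean warming anomaly (vs 1860–1880), a
  second-degree polynomial fit whose descending zero crossing estimates
  the warming level at which refugia fail, relative-warming slope maps,
  and bleaching-era atmospheric change maps.
* **Synthetic ensemble generator** — 5 pseudo-models × 4 SSP scenarios
  of daily SST 1950–2100 on a GBR-like shelf grid, with seasonal cycle,
  scenario trends, AR(1) weather, episodic heatwaves and a planted
  mixing-protection mechanism that fails at a configurable warming
  level, so the entire pipeline is testable with no data download.

## Worked example

```r
library(reefugia)

g    <- generate_grid(resolution = 1.5, seed = 42)          # desk-scale shelf
f    <- generate_forcing(g, years = 1950:2100, seed = 42)   # tides, winds
s    <- scenario_spec("SSP5-8.5", years = 1950:2100, seed = 42)
x    <- generate_daily_sst(g, f, s)

clim <- mmm_climatology(x)                  # 1985-2012, centred 1988.2857
am   <- annual_max_dhw(dhw(hotspot(x, clim)))
mask <- classify_refugia(climatological_mean_dhw(am))
mask
#> <refugia_mask> 19 of 91 cells at/below the 20th percentile (0.351 degC-weeks)

cmp <- compare_groups(tidal_power(f$u0)$p_tide, mask, g, seed = 42)
sprintf("tidal flux difference: %.3f +/- %.3f W/m2", cmp$difference, cmp$se)
#> "tidal flux difference: 0.276 +/- 0.026 W/m2"

pairs <- merge(dhw_difference(am, mask),
               warming_anomaly(generate_global_tas(s)), by = "year")
names(pairs)[3] <- "warming"
fit_diff_vs_warming(pairs)
#> <quadratic_fit> diff = -0.359 + 2.909 W + -0.907 W^2 (n = 150);
#>   crossing at 3.08 degC warming
```

The mask reports 19 of 91 shelf cells (20 %) as refugia; those cells
carry ~0.28 W/m² more tidal mixing power than the rest of the shelf —
the planted mechanism, recovered. Pairing each year's non-refugia minus
refugia DHW difference with that model's global warming anomaly and
fitting a quadratic puts the refugia-failure point at ≈3.1 °C of
warming, close to the generator's planted 3.0 °C threshold. Per-year
persistence confirms the loss: 84 % of refugia cells are still below
the annual 20th percentile in 2010, none by 2090 under this scenario.

`run_pipeline(pipeline_config(...), out_dir)` executes the whole chain
(simulate → climatology → DHW → refugia → flux → trends) and writes CSV
outputs, figures and a provenance-carrying `summary.json`.

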