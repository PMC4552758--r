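# treecarbon

Quantifies and maps the **supply of and demand for carbon storage and
sequestration by urban trees** at the census-tract level, for urban
foresters, ecosystem-service analysts and planners who want to know where —
and by how much — tree carbon uptake offsets local anthropogenic emissions.

Given a tree inventory (one row per tree: height, crown width, dbh,
land-use stratum, region, jurisdiction — the kind of table LiDAR feature
extraction produces) and a tract table with demographics, the package
computes:

1. **Storage.** Per-tree aboveground dry biomass from the taxon-group
   allometric power law `B = exp(β₀ + β₁ ln dbh)` (dbh in cm, seven species
   groups), scaled to whole-tree carbon by a 0.26 root-to-shoot ratio and
   0.5 carbon fraction, summed per tract.
2. **Sequestration (supply flow).** One simulated year of dynamics,
   `Cs = Cg − Cl + Cp`: growth gain from group-specific dbh increments,
   first-year decomposition loss from size-dependent stochastic mortality
   under three regimes (municipal removal, mulching, natural decay with
   `C_t = 0.5·M·e^(−kt)`, k = 0.062 yr⁻¹), and replanting gain.
3. **Demand.** Sectoral CO₂ emissions (electric, transportation,
   industrial, commercial, agricultural, residential, waste) from tract
   demographics times per-unit intensities, summed and converted to carbon
   mass: `D_net = ΣD · 0.2729`.
4. **Balance.** A per-tract supply-to-demand ratio `R = 100·S/D_net`
   (percent, possibly negative), classified with Jenks natural breaks for
   choropleth mapping, exported as CSV + GeoJSON + JSON summary.

Species labels are assigned by stratified largest-remainder sampling from a
relative-abundance table (land use × region). A seeded synthetic generator
(`synthetic_config()`, `generate_tracts()`, `generate_trees()`) reproduces
the statistical structure of the calibration inventory, so the entire
pipeline runs and is tested without any external data. See the methods
vignette (`vignettes/carbon-supply-demand.Rmd`) for the model, assumptions
and numerical choices.

## Worked example

```r
library(treecarbon)

cfg <- synthetic_config(n_tracts = 12, trees_per_tract_mean = 2000, seed = 7)
res <- run_pipeline(cfg)

res$storage$total_kgC / nrow(res$trees)   # 239.5 kgC per tree
res$balance$summary
#> $S_total_kgC          21827      (net annual sequestration, kgC/yr)
#> $Dnet_total_kgC       1.55e+08   (emissions-based demand, kgC/yr)
#> $R_total_percent      0.0141     (totals-based supply:demand ratio, %)
#> $R_tract_mean_percent 0.0155
#> $R_tract_sd_percent   0.0137
#> $n_tracts             12

head(res$balance$per_tract)
#>   tract_id n_trees storage_kgC Cs_kgC Dnet_kgC R_percent jenks_class
#> 1    T0001    2001      477441   2029 13134737   0.01545           3
#> 2    T0002    2044      486259   3093  9466979   0.03268           5
#> 3    T0003    2042      485959   2879 12701753   0.02267           4
```

Each tract stores ~0.48 million kgC in ~2,000 trees and sequesters a net
1–4 thousand kgC/yr, while its inhabitants emit ~13 million kgC/yr — so
trees offset only a few hundredths of a percent of demand at this reduced
tree density (the ratio scales with trees per tract; at the full calibrated
density of ~32,700 trees/tract it is a few tenths of a percent). The Jenks
class column drives the ratio map. The crown-width accuracy check on 50
synthetic validation pairs with 0.43 m prediction noise returns

```r
validate_crown_width(generate_validation_pairs(50, 0.43, seed = 7))
#> slope 0.995, RMSE 0.433 m, adjusted R² 0.991, mean bias -0.018 m
```

Passing `out_dir =` to `run_pipeline()` additionally writes
`tract_balance.csv`, `tracts.geojson`, `summary.json` and a
`run_manifest.json` recording every seed and parameter. A thin CLI wrapper
with `simulate` and `run` subcommands lives in
`inst/scripts/treecarbon.R`.

Emission intensities default to clearly-labelled illustrative values
(`inst/extdata/intensities_illustrative.yaml`); supply agency figures via
`read_emission_intensities()` for real analyses.

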