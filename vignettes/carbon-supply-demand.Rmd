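---
title: "Urban tree carbon storage and sequestration: supply, demand and the tract-level balance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Urban tree carbon storage and sequestration: supply, demand and the tract-level balance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treecarbon)
```

## The problem

Urban trees store carbon in standing biomass and sequester additional carbon
each year through growth, while mortality and decomposition return carbon to
the atmosphere. The climate benefit of this service can only be judged
against the *demand* for it — the anthropogenic CO~2~ emitted where people
live and work. `treecarbon` implements an integrated accounting of both
sides at the census-tract level: a per-tree allometric model of stored
carbon, a one-year stochastic simulation of net sequestration, a sectoral
emissions proxy for demand, and a supply-to-demand ratio map.

The package is driven by a tree inventory table of the kind produced by
LiDAR feature extraction (one row per tree: height, crown width, dbh,
land-use stratum, region, jurisdiction) together with a tract table carrying
demographics. A seeded synthetic generator reproduces the statistical
structure of such inputs so the full pipeline is testable without any
external download.

## Carbon storage (supply stock)

Aboveground dry biomass follows the taxon-group allometric power law

$$B = \exp(\beta_0 + \beta_1 \ln(\mathrm{dbh}))$$

with dbh in cm (valid from 2.5 cm up) and group-specific coefficients for
seven species groups (soft maple/birch, aspen/alder/cottonwood/willow, hard
maple/oak/hickory/beech, other hardwood, cedar/larch, spruce, pine).
Whole-tree carbon applies a fixed root-to-shoot ratio of 0.26 and a carbon
fraction of 0.5:

$$\mathrm{kgC} = B \cdot (1 + 0.26) \cdot 0.5 .$$

Tree tables store dbh in metres (as inventory products do); the
metre-to-centimetre conversion happens in exactly one function,
`dbh_m_to_cm()`, so the unit boundary cannot drift. Tract storage is the sum
of whole-tree carbon over trees in the tract; sums use R's long-double
accumulator, whose error bound at these problem sizes is far below every
tolerance used in the package.

Because the inventory has no species labels, `assign_species()` draws them
from a relative-abundance table stratified by land use and region. The
number of trees per group in each stratum is fixed deterministically by
largest-remainder apportionment (so realised proportions match the table to
within one tree, and per-stratum counts are invariant to row order); only
*which* tree gets which label is random. The undeveloped-land abundance
column sums to 103 after rounding in the source field surveys; the table is
therefore normalised per stratum before apportionment.

## One year of dynamics (supply flow)

Net annual sequestration per tract is the three-term balance

$$C_s = C_g - C_l + C_p .$$

* **Mortality.** Each tree dies independently with the annual probability of
  its dbh class: 2.1% below 47 cm, 2.9% for 47–61 cm, 3.0% for 62–76 cm,
  5.4% at 77 cm and above. The published class edges leave 1-cm gaps
  (46–47, 61–62, 76–77) and are silent below 16 cm; the schedule here uses
  contiguous classes `[0,47), [47,62), [62,77), [77,∞)`, carrying each rate
  to the nearest boundary, and is configurable.
* **Growth** ($C_g$). Survivors grow by their group's mean annual dbh
  increment (0.152–0.406 cm/yr); the gain is the carbon difference of the
  allometric biomass at the two diameters. Following the published balance,
  only aboveground growth is credited by default; the switch
  `include_root_growth = TRUE` also scales the increment by 1.26, and the
  choice is recorded in the result metadata. Dead trees do not grow in
  their year of death.
* **Decomposition** ($C_l$) counts only first-year releases (the model is a
  single-year snapshot; legacy decay from earlier cohorts is out of scope).
  Three regimes apply, chosen by jurisdiction and land use:
  municipal removal (city jurisdiction; all whole-tree carbon released),
  mulching (developed land elsewhere; 80% of whole-tree carbon), and
  natural decay (undeveloped land elsewhere), where aboveground necromass
  decays exponentially with rate constant $k = 0.062\,\mathrm{yr}^{-1}$
  ($C_t = 0.5\,M e^{-kt}$, so a fraction $1 - e^{-k}$ is released in year
  one) and roots release 20% of their carbon in the first year of a 20-year
  horizon. "Total biomass" in the removal and mulch regimes includes roots
  ($B_{\mathrm{above}} \times 1.26$), consistent with the explicit
  above/belowground split of the natural regime.
* **Replanting** ($C_p$). A fraction of dead trees is replaced by trees of
  the same size and species — 15% under the city forestry jurisdiction, 10%
  on developed land elsewhere, 0% on undeveloped land. Counts are fixed by
  rounding the rate (largest-remainder within each jurisdiction × land-use
  stratum) rather than drawn Bernoulli, which avoids zero-inflation in
  small strata; the selection of individuals is seeded random. Replacements
  contribute their full carbon immediately, a deliberate literal reading of
  the management assumption.

The identity $C_s = C_g - C_l + C_p$ holds exactly (to floating-point) per
tract and in total, and every input tree appears exactly once in the
per-tree fate ledger.

## Demand

Demand is proxied by sectoral anthropogenic CO~2~ emissions. Seven sectors
(electric utility, transportation, industrial, commercial, agricultural,
residential, waste) are driven by tract demographics — population, vehicle
count, industrial and commercial employment, agricultural land area — times
per-unit intensities, with a 0.70 factor restricting the electric sector to
nonrenewable generation. Sector outputs stay in kg CO~2~ until the final
step, where the sum is converted to carbon mass with the molar fraction
0.2729:

$$D_{net} = (D_e + D_t + D_i + D_c + D_a + D_r + D_w) \times 0.2729 .$$

Agency intensity values are not in the public domain of this package; the
shipped `inst/extdata/intensities_illustrative.yaml` (also the defaults of
`emission_intensities()`) is clearly labelled illustrative. The values were
chosen once so that the synthetic study-area demographic totals produce
sectoral emissions of realistic magnitude and ordering (electricity
dominant, then agriculture and transportation). Demand is deterministic.

## The supply-to-demand ratio

Per tract, $R = 100 \cdot S / D_{net}$ (percent), with $S$ the tract's net
annual sequestration. $R$ can be negative where decomposition exceeds
growth, and is undefined (NA, flagged, excluded from classification) where
demand is zero. The study-area summary reports **both** the totals-based
ratio $100 \sum S / \sum D_{net}$ and the mean/SD of tract ratios — these
are different statistics and the package deliberately exposes both.

For mapping, ratios are classified with Jenks natural breaks: Fisher's
optimal partition minimising within-class sum of squared deviations,
computed by dynamic programming over the sorted distinct values (ties never
split; equal-cost partitions resolve toward the lowest upper boundary of
the earliest differing class, making the result deterministic). The class
count is not dictated by the method; the default is `k = 5`, a conventional
choropleth depth, and is configurable.

## The synthetic generator

`synthetic_config()` defaults encode the study conditions the analysis was
calibrated to:

* 223 tracts on a planar grid of 2 km squares (~856 km² of urbanized
  county land), in four region blocks, with the `StPaul_Ramsey` block
  carrying the `st_paul` jurisdiction;
* ~32,700 trees per tract (Poisson), ~7.3 million in all;
* attribute marginals: height mean 11.51 m (SD 4.62), crown width 3.90 m
  (SD 1.07), dbh 0.29 m (SD 0.04) truncated to 0.24–0.83 m;
* per-tract demographics uniform in ranges whose 223-tract totals match the
  study-area census inputs (population ≈ 359,000, ≈ 178,000 vehicles,
  ≈ 400 km² agricultural land);
* developed-land fraction 0.75 per tree (the study area is predominantly
  but not entirely developed), and 0.5% of trees given artifact heights
  above the 45 m cap so the quality filter is exercised the way real
  feature-extraction output requires.

Two numerical choices matter. First, attributes are *moment-matched*
truncated normals: the underlying $(\mu, \sigma)$ are solved (Nelder–Mead on
the closed-form truncated-normal moments, residual < 10⁻⁶ of the target
SD) so the post-truncation mean and SD equal the configured values. Naive
truncation of N(0.29, 0.04) at 0.24 m would shift the realised dbh mean to
~0.298 m and shrink its SD by ~16%, breaking the calibration the defaults
promise. Second, sampling uses the inverse-CDF transform, so draws are
deterministic given the seed with no rejection loop. A single master seed
feeds fixed per-stage substreams (tracts, trees, species, mortality,
replanting, validation pairs), so any stage can be re-run independently and
reproducibly.

The generator emulates marginal distributions only: heights, crowns and dbh
are drawn independently because the calibration source reports no joint
correlations, and tree positions are uniform within tracts with no spatial
autocorrelation of canopy. Passing tests therefore demonstrate correctness
of the accounting arithmetic and the statistical behaviour of the
simulation — not that real urban forests satisfy the independence
assumptions.

Crown-width validation pairs emulate an accuracy assessment against
orthophoto measurement: true widths uniform over the observed 2.6–16.93 m
range ("distributed evenly"), predictions equal to truth plus Gaussian
error. With this even design the expected regression RMSE is
$\sigma\sqrt{(n-2)/n}$ to within 1%, which the test suite verifies by
Monte Carlo against the exact chi-distribution expectation.

## Problem sizes and tolerances

The test suite runs the pipeline at reduced sizes (4–6 tracts, tens to
thousands of trees) chosen so the whole suite completes in well under a
minute while statistical checks retain 3-standard-error power;
`scripts/acceptance.R` runs the full default scale (223 tracts, ~7.3
million trees), which completes in a few minutes on one CPU. Closed-form
identities are asserted to 10⁻¹² relative; stochastic checks use 3-SE
bands over 200 seeds; the Jenks implementation is checked against
exhaustive enumeration for n ≤ 12, k ≤ 4.

## Known limitations

* One parameter pair per species *group*; no within-group species variation
  (allometric curves for the grouped species have very similar shapes, so
  grouping changes biomass predictions little).
* A single decomposition constant for all species and components; no
  distinction between logs, branches and foliage.
* No understory (the 3 m height floor excludes it), no soil carbon, and no
  avoided emissions from shading or evapotranspiration.
* Single-year snapshot: no multi-year projection, no legacy decomposition
  from prior-year mortality.
* The demand proxy is territorial emissions; it does not model risk
  reduction, service flows between tracts, or non-CO~2~ gases.

## A small worked run

```{r example, eval = FALSE}
cfg <- synthetic_config(n_tracts = 12, trees_per_tract_mean = 2000, seed = 7)
res <- run_pipeline(cfg, out_dir = "run7")
res$balance$summary
head(res$balance$per_tract)
```

The exported `run7/` directory then holds `tract_balance.csv`,
`tracts.geojson` (polygons with balance properties and Jenks class),
`summary.json` and `run_manifest.json` recording every seed and parameter.
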