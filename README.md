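# beetoxload

County-level **bee toxic load** analysis in R: turn tables of insecticide
use (kg of active ingredient per county-year), agricultural-census land
use and raw honey-bee acute toxicity records into annual county estimates
of total honey-bee lethal doses, and decompose their change into extent
and intensity components.

The package is written for landscape ecotoxicologists and
agro-environmental analysts who work with public data shaped like the
USGS county pesticide estimates, the Census of Agriculture and
ECOTOX/PPDB toxicity extracts, and who need the whole chain — record
cleaning, consensus LD50 selection, hazard aggregation, trend testing,
trajectory clustering and map classification — as tested, reusable
functions rather than one-off scripts.

## The metric

Bee toxic load is the number of honey-bee lethal doses applied in an
area:

```
toxic load = Σ_ai  Weight_ai / LD50_ai        (kg → µg, i.e. × 1e9)
```

computed separately with contact and oral LD50s (µg/bee), because the two
routes rank compounds very differently. Per land hectare it factors into
the chain

```
load/ha = cropland_frac × prop_cropland_treated × app_rate × potency
          └──────────── extent ───────────────┘  └────── intensity ─────┘
```

which `county_components()` computes and the test suite enforces to
1e-9 relative tolerance at county, regional and national level.

Core pieces:

- `standardize_toxicity_records()`, `consensus_table()` — filter raw
  LD50 records (≤ 4 days, contact/oral, adult bees, µg/bee) and apply a
  six-tier consensus ladder (regulatory points → other points →
  regulatory bounds → other bounds → mode-of-action median → global
  median).
- `compute_toxic_load()`, `fill_missing_series()` — the load equation per
  county-year and chemical class, with linear interpolation of missing
  county-years and zero fill for counties that never report use.
- `impute_census()`, `county_components()`, `regional_summary()`,
  `component_fold_changes()` — extent/intensity decomposition.
- `mann_kendall()`, `fold_change()` — tie-corrected trend test and
  response ratios.
- `normalize_series()`, `ward_cluster()` — fold-change normalization and
  Ward/Euclidean clustering of regional trajectories (hclust-compatible,
  Newick export).
- `jenks_breaks()`, `zero_centered_breaks()` — exact Fisher–Jenks
  classification for level and change maps.
- `scenario_config()`, `generate_scenario()` — a synthetic study system
  with planted ground truth (national oral load ×9, contact ×1,
  neonicotinoid-driven surges in two regions) for end-to-end
  parameter-recovery testing.
- `run_pipeline()` — the whole chain as one configured, logged,
  deterministic run; the `analysis/` scripts run it stage by stage.

## Worked example

The numbered scripts under `analysis/` run the full study on the default
synthetic scenario and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_consensus.R
Rscript analysis/03_toxic_load.R
Rscript analysis/04_components.R
Rscript analysis/05_trends.R
Rscript analysis/06_cluster.R
Rscript analysis/07_classify.R
Rscript analysis/08_sensitivity.R
```

Selected output (seed 42):

```
Planted national fold changes 1997->2012: oral 9.000, contact 1.000.
Planted high-increase regions: Heartland (79x), Northern Great Plains (68x)

National oral toxic load: 1.69e+16 bee LD50s in 1997 -> 1.51e+17 in 2012 (8.9x).
Neonicotinoid share of oral toxic load in 2012: 90.0%.

National Mann-Kendall results:
       series        tau      p_value
           kg -0.9000000 1.454342e-06
 contact_load -0.3333333 7.910922e-02
    oral_load  0.8500000 5.434517e-06

oral tree: top split isolates {Heartland, Northern Great Plains} from the other 7 regions.
```

Reading this: the weight of insecticide applied *falls* monotonically
(tau −0.90) while oral toxic load *rises* nearly 9-fold (tau 0.85) and
contact load stays flat — the "potency paradox" in which less insecticide
by weight is more hazardous by lethal doses, driven here (and visible in
the class series) by the planted post-2006 neonicotinoid adoption. The
pipeline recovers the planted 9× within 1% despite 3% of county-years
being withheld and interpolated, and the clustering's first split finds
exactly the two regions where the surge was planted.

## Scope

Hazard, not risk: no exposure modelling, pesticide fate or half-life
weighting, and no cartography (classification tables join to county
geometries on `fips`; rendering is left to mapping tools). See
`vignettes/bee-toxic-load-methods.Rmd` for the model, conventions and
their rationale.
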