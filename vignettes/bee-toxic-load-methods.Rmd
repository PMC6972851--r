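---
title: "Methods: county-level bee toxic load and its components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: county-level bee toxic load and its components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beetoxload)
```

## The hazard metric

Aggregate insecticide statistics (total kg applied, area treated) hide the
fact that active ingredients differ by orders of magnitude in potency to
insects. `beetoxload` works with *bee toxic load*: the total number of
honey-bee lethal doses represented by the insecticides applied in an area,

$$
\mathrm{toxic\ load} \;=\; \sum_{ai} \frac{W_{ai}}{\mathrm{LD50}_{ai}},
$$

where $W_{ai}$ is the weight of active ingredient $ai$ applied (converted
kg $\to$ µg, i.e. $\times 10^9$) and $\mathrm{LD50}_{ai}$ is its acute
honey-bee LD50 in µg/bee, so the ratio is a count of lethal doses. Contact
and oral toxicity give different rankings of compounds (systemic
seed-applied neonicotinoids are far more potent orally than by contact),
so the load is computed separately per route throughout. Reported
magnitudes are routinely expressed in billions of bee LD50s, obtained by
dividing by $10^9$.

The county-year load factors into an *extent* term (how much land is
treated) and an *intensity* term (how many lethal doses land on each
treated hectare):

$$
\frac{\mathrm{load}}{\mathrm{land\ ha}}
= \underbrace{\frac{\mathrm{cropland}}{\mathrm{land}}
  \times \frac{\mathrm{treated}}{\mathrm{cropland}}}_{\text{extent}}
\times \underbrace{\frac{\mathrm{kg}}{\mathrm{treated\ ha}}
  \times \frac{\mathrm{load}}{\mathrm{kg}}}_{\text{intensity}}
$$

`county_components()` computes every factor of this chain and the identity
is enforced in the tests to $10^{-9}$ relative tolerance. Aggregates
(regions, nation) are always built from sums — $\Sigma$ treated / $\Sigma$
land, $\Sigma$ load / $\Sigma$ kg — never from means of county ratios, so
the chain also holds at every aggregation level and regional loads add up
to the national load. Whether published regional intensities were
sum-based or county-mean-based is not documented anywhere we know of;
sum-based is the only choice under which the multiplicative chain survives
aggregation, and it is what this package implements.

## Consensus LD50 selection

Raw acute-toxicity records are heterogeneous: different exposure routes,
durations, life stages, units, point versus bounded estimates, regulatory
versus literature sources. `standardize_toxicity_records()` keeps records
with (i) exposure of four days or less, (ii) contact or oral route,
(iii) adult bees, and (iv) a positive LD50 expressible in µg/bee (mg/bee
converted $\times 1000$; other units such as dietary concentrations are
dropped rather than guessed at). Rejected rows are returned with reasons,
not silently discarded.

`consensus_table()` then applies a strict six-rule ladder per compound and
route:

1. geometric mean of regulatory point estimates;
2. geometric mean of other point estimates;
3. regulatory unbounded estimates — minimum of "less than" bounds if any
   exist, else maximum of "greater than" bounds;
4. the same for non-regulatory unbounded estimates;
5. median of the tier 1–4 consensus values in the compound's
   mode-of-action (IRAC) group;
6. median of all tier 1–4 consensus values.

The geometric mean is the right pooling for quantities that vary
multiplicatively; duplicates are not collapsed before pooling. Three
conventions had to be fixed where the procedure is otherwise
underdetermined, and each is isolated and documented:

* **Mixed bounds within a tier.** A "less than" bound is an informative
  upper limit on the LD50 and therefore hazard-conservative; it takes
  precedence over "greater than" bounds.
* **Even-count medians** are the arithmetic midpoint of the two central
  values (the standard convention).
* **Tier-5/6 medians** are computed over per-compound consensus values,
  not over raw records; "the median toxicity value for the group" reads
  most naturally as a median of compound-level values, but this is a
  documented choice, not an inference about anyone's intent.

Every compound in the use universe ends up with exactly one contact and
one oral value and a tier recording the rule used — the tier distribution
is a data-quality diagnostic that the pipeline logs on every run.

## Filling gaps in the source tables

Two missingness mechanisms are handled, mirroring the public sources the
synthetic tables emulate:

* **Missing county-years in the use table** (survey coverage gaps).
  County totals of kg, contact load and oral load are interpolated
  linearly and independently across interior gaps; leading and trailing
  gaps are filled by constant extension of the nearest observed value
  (linear interpolation is undefined there, and extrapolating an
  exponential adoption curve would be worse; filled rows carry an
  `interpolated` flag). Counties that never report use are filled with
  zeros — in real data these are highly urban counties.
* **Withheld census cells** (disclosure suppression). Each withheld
  cropland/treated cell is imputed with the mean of the county's other
  census years, or zero if all years are withheld. Imputation can create
  `treated > cropland`; such rows are clamped to keep proportions in
  $[0, 1]$ and flagged.

The low USGS-style estimate is the default everywhere (the conservative
choice); the high estimate sits behind `variant = "high"` and the
`sensitivity_compare()` stage, which verifies that trend direction and
significance are variant-invariant (a provable consequence of linearity
when the low-to-high multiplier is uniform).

## Trend testing and fold changes

Change over 16 annual values is tested with the Mann-Kendall statistic
$S = \sum_{i<j} \mathrm{sign}(x_j - x_i)$, with the standard tie
correction in $\mathrm{var}(S)$ and the tie-corrected tau-b reported. The
p-value uses the normal approximation with a continuity correction
(shrinking $S$ toward zero by one) — standard practice at $n = 16$, and
validated in the tests against exact permutation nulls for all $n \le 8$
(within 0.02, and within 0.01 for the tied case). A constant series has
no defined direction and is flagged rather than given $\tau = 0$.

Magnitude of change is the response ratio
$\mathrm{value}_{t_1}/\mathrm{value}_{t_0}$: 1 is no change, 3 a
tripling, 0.3 a 70% decline. Zero baselines yield a flagged undefined
value, never infinity.

## Regional trajectory clustering

Regions differ by orders of magnitude in absolute load, so each regional
annual series is first normalized to fold change relative to the first
year; clustering then groups *shapes* of trajectories. Trees are built
with Euclidean distances and Ward's minimum-variance linkage via the
Lance–Williams recurrence on squared distances — the ward.D2 convention,
in which merging two singletons has height equal to their Euclidean
distance. The published analyses this design follows do not name their
Ward variant; ward.D2 is the common default of reference implementations
and the in-repo implementation is verified against both `stats::hclust`
and a brute-force minimum-variance oracle. Ties in merge cost are broken
by the lexicographically smallest pair in input order, making the tree
deterministic; contact and oral trees are computed separately.

## Map classification

County values are classed for choropleth mapping with exact Fisher–Jenks
natural breaks: a dynamic program over the sorted *distinct* values
(weighted by multiplicity, so tied values can never straddle a class
boundary) minimizing within-class squared deviation. Change maps need a
diverging scale; "centered on zero" is operationalized as running Jenks
separately on the negative and non-negative values with a forced class
boundary at zero, allocating classes to each side in proportion to its
share of counties (at least one per side). That operationalization is a
design choice — no algorithm is published for it — and it is isolated in
`zero_centered_breaks()`. One-signed inputs fall back to plain Jenks with
a warning. The class count is a parameter (default 5; typical choropleth
practice).

## The synthetic study system

`generate_scenario()` emits the three input tables with the structure the
analysis assumes, plus a planted ground truth:

* 180 counties in the nine Farm Resource Regions (20 each), county land
  areas log-normal around 150k ha, region-typical cropland fractions
  (row-crop-heavy regions higher), cropland contracting 12% over
  1997–2012 while the treated share of cropland grows from 15% to 26%;
* a ten-compound catalog spanning the major chemical classes whose
  composition shifts from organophosphates toward pyrethroids and
  neonicotinoids; neonicotinoid rate curves are zero before 2006 and grow
  exponentially after, emulating seed-treatment adoption. LD50s are
  stylized values of realistic magnitude, not reference toxicity data;
* per-route toxicity records: one regulatory point record at each
  compound's true LD50 plus configurable decoys (noisy literature points,
  unbounded estimates, larval tests, long durations, mg/bee units,
  non-contact/oral routes) that exercise the filters and lower tiers
  without moving the tier-1 consensus;
* missing county-years (default probability 0.03) and withheld census
  cells (default 0.08). Real-world missingness rates are not published;
  these defaults are placeholders chosen once to be small but exercising,
  consistent with reports that interpolation has only minor effects.

Two features are calibrated rather than drawn. First, the national
fold changes of toxic load are planted *exactly*: national load is linear
in any per-class rescaling of rate curves, so the generator solves a
2×2 linear system for a neonicotinoid and a pyrethroid scale factor such
that oral load changes 9-fold and contact load 1-fold from first to last
year (configurable via `calibrate_folds`). Second, regional multipliers
concentrate neonicotinoid use in the Heartland and Northern Great Plains
(where baseline use is low), planting oral increases of roughly 60–80×
there versus ~1× elsewhere — the structure the clustering stage is
designed to detect, with the top split isolating exactly those two
regions.

The generator deliberately omits spatial autocorrelation between
neighboring counties, crop rotations, pesticide fate and any
exposure process. Passing the recovery tests therefore shows that the
*pipeline arithmetic* is faithful — filters, consensus, unit chain,
interpolation and aggregation recover what was planted (exactly with
missingness disabled, within 5% under default missingness) — not that
real-world estimates carry those error bars.

## Numerical choices and problem sizes

All tolerances in tests are relative $10^{-9}$ unless the quantity is a
p-value (absolute 0.01–0.02 against exact enumeration). Test and example
problem sizes are chosen to keep oracles exhaustive: permutation nulls up
to $n = 8$ (40,320 orderings), Jenks against full partition enumeration
for $n \le 12,\ k \le 4$ (200 random instances), Ward against the
brute-force agglomeration oracle at $n = 4$, and the end-to-end scenario
at 180 counties × 16 years × 10 compounds, which runs the full pipeline
in seconds.

## Known limitations

* This is a hazard indicator, not a risk assessment: no exposure, fate,
  degradation or half-life weighting (deliberately — half-lives depend
  on the matrix, and use data carry no application-method information).
* Components are computed only for census years; intercensal component
  interpolation is not attempted.
* Cartography is out of scope: the classification tables join to county
  geometries on `fips`, but no maps are rendered here.
* The consensus ladder's tier-5/6 behaviour on real databases (fallback
  frequencies, group coverage) cannot be reproduced from synthetic data;
  only the rules themselves are verified.
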