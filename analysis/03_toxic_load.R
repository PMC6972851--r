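#!/usr/bin/env Rscript
# Stage 3: county-year bee toxic load.
#
# Converts applied weights to honey-bee lethal doses (kg x 1e9 / LD50),
# aggregates per county-year and chemical class, and fills missing
# county-years (linear interpolation, zero fill for counties that never
# report use).

suppressPackageStartupMessages(library(beetoxload))
suppressPackageStartupMessages(library(dplyr))

use <- read_use_table("results/data/use.csv")
landuse <- read_landuse_table("results/data/landuse.csv")
cons <- readr::read_csv("results/consensus_ld50.csv", show_col_types = FALSE)

years <- min(use$year):max(use$year)
by_class <- compute_toxic_load(use, cons, variant = "low")
totals <- fill_missing_series(
  county_year_totals(by_class), years, all_fips = unique(landuse$fips)
)
readr::write_csv(totals, "results/county_year_load.csv")

region_map <- read_region_map("results/data/regions.csv")
cls <- class_series(by_class, select(region_map, fips, region))
readr::write_csv(cls, "results/class_series.csv")

cat(sprintf(
  "Computed loads for %d county-years (%d interpolated, %d zero-filled counties).\n",
  nrow(totals), sum(totals$interpolated),
  length(setdiff(landuse$fips, use$fips))
))
nat <- totals |>
  group_by(year) |>
  summarise(oral = sum(oral_load), contact = sum(contact_load))
cat(sprintf(
  "National oral toxic load: %.2e bee LD50s in %d -> %.2e in %d (%.1fx).\n",
  nat$oral[1], min(years), nat$oral[nrow(nat)], max(years),
  nat$oral[nrow(nat)] / nat$oral[1]
))
neo <- cls |>
  group_by(year) |>
  summarise(share = 100 * sum(oral_load[class == "NEO"]) / sum(oral_load))
cat(sprintf(
  "Neonicotinoid share of oral toxic load in %d: %.1f%%.\n",
  max(years), neo$share[neo$year == max(years)]
))
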