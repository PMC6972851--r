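#!/usr/bin/env Rscript
# Stage 4: extent and intensity decomposition.
#
# Imputes withheld census cells, joins land use with toxic load on the
# county id for the census years, computes the component chain
# (extent = cropland fraction x proportion treated; intensity =
# application rate x potency) and summarizes it per region and nation.

suppressPackageStartupMessages(library(beetoxload))
suppressPackageStartupMessages(library(dplyr))

landuse <- read_landuse_table("results/data/landuse.csv")
totals <- readr::read_csv("results/county_year_load.csv", show_col_types = FALSE)
region_map <- read_region_map("results/data/regions.csv")

lu <- impute_census(landuse)
cat(sprintf(
  "Imputed %d withheld census cells; clamped %d rows to keep treated <= cropland <= land.\n",
  sum(lu$cropland_imputed) + sum(lu$treated_imputed), sum(lu$clamped)
))

census_years <- sort(unique(lu$year))
comp <- county_components(totals, lu, census_years)
readr::write_csv(comp, "results/county_components.csv")

summ <- regional_summary(comp, select(region_map, fips, region),
  year = max(census_years))
readr::write_csv(summ, "results/regional_summary.csv")

folds <- bind_rows(
  component_fold_changes(comp, min(census_years), max(census_years)),
  component_fold_changes(comp, min(census_years), max(census_years),
    select(region_map, fips, region))
)
readr::write_csv(folds, "results/component_folds.csv")

nat <- summ[summ$region == "Contiguous US", ]
cat(sprintf(
  "In %d, %.1f%% of land (%.1f%% of cropland) was treated; oral intensity %.2e bee LD50s/treated-ha.\n",
  nat$year, nat$extent_pct, nat$pct_cropland_treated, nat$intensity_oral
))
natf <- folds[folds$unit == "national", ]
cat("National component fold changes 1997 -> 2012:\n")
print(as.data.frame(natf[, c("component", "fold_change")]), row.names = FALSE)
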