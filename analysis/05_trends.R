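#!/usr/bin/env Rscript
# Stage 5: monotonic trend tests and load fold changes.
#
# Mann-Kendall tests (tie-corrected, continuity-corrected normal
# approximation) on the national weight and toxic-load series and on the
# regional oral/contact series, plus 1997 -> 2012 response ratios.

suppressPackageStartupMessages(library(beetoxload))
suppressPackageStartupMessages(library(dplyr))

totals <- readr::read_csv("results/county_year_load.csv", show_col_types = FALSE)
region_map <- read_region_map("results/data/regions.csv")
years <- range(totals$year)

national <- totals |>
  group_by(year) |>
  summarise(
    kg = sum(kg), contact_load = sum(contact_load),
    oral_load = sum(oral_load), .groups = "drop"
  ) |>
  arrange(year)

tests <- bind_rows(
  mann_kendall(national$kg) |> mutate(unit = "national", series = "kg"),
  mann_kendall(national$contact_load) |>
    mutate(unit = "national", series = "contact_load"),
  mann_kendall(national$oral_load) |>
    mutate(unit = "national", series = "oral_load")
)
regional <- totals |>
  left_join(select(region_map, fips, region), by = "fips") |>
  group_by(region, year) |>
  summarise(oral_load = sum(oral_load), contact_load = sum(contact_load),
    .groups = "drop")
for (r in unique(regional$region)) {
  d <- arrange(regional[regional$region == r, ], year)
  tests <- bind_rows(
    tests,
    mann_kendall(d$oral_load) |> mutate(unit = r, series = "oral_load"),
    mann_kendall(d$contact_load) |> mutate(unit = r, series = "contact_load")
  )
}
tests <- select(tests, unit, series, dplyr::everything())
readr::write_csv(tests, "results/trend_tests.csv")

folds <- regional |>
  group_by(region) |>
  summarise(
    oral = fold_change(oral_load[year == years[1]], oral_load[year == years[2]]),
    contact = fold_change(
      contact_load[year == years[1]], contact_load[year == years[2]]
    ),
    .groups = "drop"
  )
readr::write_csv(folds, "results/regional_fold_changes.csv")

nat <- tests[tests$unit == "national", ]
cat("National Mann-Kendall results:\n")
print(as.data.frame(nat[, c("series", "tau", "p_value")]), row.names = FALSE)
cat(sprintf(
  "Oral toxic load rose in %d of %d regions; largest increases: %s.\n",
  sum(folds$oral > 1), nrow(folds),
  paste(sprintf(
    "%s (%.0fx)",
    folds$region[order(-folds$oral)][1:2], sort(folds$oral, TRUE)[1:2]
  ), collapse = ", ")
))
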