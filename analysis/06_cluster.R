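#!/usr/bin/env Rscript
# Stage 6: regional time-series clustering.
#
# Normalizes each region's annual toxic-load series to fold change
# relative to the first year and clusters the trajectories (Euclidean
# distance, Ward linkage), oral and contact separately.

suppressPackageStartupMessages(library(beetoxload))
suppressPackageStartupMessages(library(dplyr))

totals <- readr::read_csv("results/county_year_load.csv", show_col_types = FALSE)
region_map <- read_region_map("results/data/regions.csv")

regional <- totals |>
  left_join(select(region_map, fips, region), by = "fips") |>
  group_by(region, year) |>
  summarise(oral_load = sum(oral_load), contact_load = sum(contact_load),
    .groups = "drop") |>
  arrange(region, year)

for (route in c("oral", "contact")) {
  col <- paste0(route, "_load")
  mat <- do.call(rbind, lapply(split(regional, regional$region), function(d) {
    normalize_series(d[[col]])
  }))
  tree <- ward_cluster(mat)
  readr::write_csv(
    merge_table(tree), sprintf("results/cluster_%s_merges.csv", route)
  )
  writeLines(tree_newick(tree), sprintf("results/cluster_%s.nwk", route))
  parts <- top_split(tree)
  small <- parts[[which.min(lengths(parts))]]
  cat(sprintf(
    "%s tree: top split isolates {%s} from the other %d regions.\n",
    route, paste(small, collapse = ", "), nrow(mat) - length(small)
  ))
}
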