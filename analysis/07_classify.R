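#!/usr/bin/env Rscript
# Stage 7: county classification for mapping.
#
# Jenks natural breaks on 2012 oral toxic load per land hectare (level
# map) and zero-centered breaks on the log2 fold change 1997 -> 2012
# (change map). The emitted tables join to county geometries on `fips`.

suppressPackageStartupMessages(library(beetoxload))
suppressPackageStartupMessages(library(dplyr))

comp <- readr::read_csv("results/county_components.csv", show_col_types = FALSE)
y0 <- min(comp$year)
y1 <- max(comp$year)

level <- comp[comp$year == y1, ]
jb <- jenks_breaks(level$load_per_ha_oral, 5)
readr::write_csv(
  tibble::tibble(
    fips = level$fips, load_per_ha_oral = level$load_per_ha_oral,
    class = jb$assignment
  ),
  "results/county_classes_level.csv"
)
cat(sprintf(
  "Level map: 5 classes, gvf %.3f, breaks at %s bee LD50s/ha.\n",
  jb$gvf, paste(signif(jb$breaks, 3), collapse = ", ")
))

chg <- comp |>
  select(fips, year, load_per_ha_oral) |>
  tidyr::pivot_wider(names_from = year, values_from = load_per_ha_oral)
chg$fold <- fold_change(chg[[as.character(y0)]], chg[[as.character(y1)]])
chg <- chg[!is.na(chg$fold) & chg$fold > 0, ]
chg$log2_fold <- log2(chg$fold)
zb <- zero_centered_breaks(chg$log2_fold, 5)
readr::write_csv(
  tibble::tibble(fips = chg$fips, log2_fold = chg$log2_fold,
    class = zb$assignment),
  "results/county_classes_change.csv"
)
cat(sprintf(
  "Change map: %d counties increased, %d decreased; %d classes with a forced boundary at zero (gvf %.3f).\n",
  sum(chg$log2_fold >= 0), sum(chg$log2_fold < 0), zb$k, zb$gvf
))
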