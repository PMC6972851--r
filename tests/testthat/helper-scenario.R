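# Small scenario configurations used across test files.

tiny_config <- function(...) {
  scenario_config(n_counties = 27, n_urban = 1, seed = 11, ...)
}

# Consensus table for a generated scenario, straight from its own
# toxicity records.
scenario_consensus <- function(scen) {
  consensus_table(
    scen$toxicity, unique(scen$use$compound),
    dplyr::select(scen$config$catalog, compound, moa_group)
  )
}

# Filled county-year totals for a generated scenario.
scenario_filled_totals <- function(scen, variant = "low") {
  cons <- scenario_consensus(scen)
  fill_missing_series(
    county_year_totals(compute_toxic_load(scen$use, cons, variant)),
    scen$config$years,
    all_fips = unique(scen$landuse$fips)
  )
}

national_series <- function(totals) {
  totals |>
    dplyr::group_by(year) |>
    dplyr::summarise(
      kg = sum(kg), contact_load = sum(contact_load),
      oral_load = sum(oral_load), .groups = "drop"
    ) |>
    dplyr::arrange(year)
}

# One toxicity record row with sensible defaults, for hand-built fixtures.
tox_record <- function(compound = "cmp", route = "oral", value = 1,
                       units = "ug/bee", bound = "point",
                       source_tier = "regulatory", duration_days = 2,
                       life_stage = "adult", cas = "0-0-0") {
  tibble::tibble(
    compound = compound, cas = cas, route = route, value = value,
    units = units, bound = bound, source_tier = source_tier,
    duration_days = duration_days, life_stage = life_stage
  )
}
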