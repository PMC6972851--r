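# Delimited-text readers for the three input tables. County ids are
# FIPS-like zero-padded strings, so `fips` is always read as character.

#' Read a pesticide-use table
#'
#' @param path CSV file with columns `compound`, `class`, `year`, `fips`,
#'   `kg_low`, `kg_high`, `seed_excluded`.
#' @return Tibble with `fips` as character.
#' @export
read_use_table <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      compound = readr::col_character(), class = readr::col_character(),
      year = readr::col_integer(), fips = readr::col_character(),
      kg_low = readr::col_double(), kg_high = readr::col_double(),
      seed_excluded = readr::col_logical()
    )
  )
}

#' Read a census land-use table
#'
#' @param path CSV file with columns `fips`, `year`, `land_ha`,
#'   `cropland_ha`, `treated_ha`, `cropland_withheld`, `treated_withheld`.
#' @return Tibble with `fips` as character; withheld cells are `NA`.
#' @export
read_landuse_table <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      fips = readr::col_character(), year = readr::col_integer(),
      land_ha = readr::col_double(), cropland_ha = readr::col_double(),
      treated_ha = readr::col_double(),
      cropland_withheld = readr::col_logical(),
      treated_withheld = readr::col_logical()
    )
  )
}

#' Read a raw toxicity-record table
#'
#' @param path CSV file with columns `compound`, `cas`, `route`, `value`,
#'   `units`, `bound`, `source_tier`, `duration_days`, `life_stage`.
#' @return Tibble of raw toxicity records.
#' @export
read_toxicity_table <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      compound = readr::col_character(), cas = readr::col_character(),
      route = readr::col_character(), value = readr::col_double(),
      units = readr::col_character(), bound = readr::col_character(),
      source_tier = readr::col_character(),
      duration_days = readr::col_double(),
      life_stage = readr::col_character()
    )
  )
}

#' Read a county-to-region map
#'
#' @param path CSV file with columns `fips`, `region`.
#' @return Tibble with `fips` as character.
#' @export
read_region_map <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      fips = readr::col_character(), region = readr::col_character(),
      .default = readr::col_guess()
    )
  )
}
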