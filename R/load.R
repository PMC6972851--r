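# Toxic-load computation: honey-bee lethal doses per county-year from
# applied weights and consensus LD50s, with gap filling for missing years.

#' Compute bee toxic load per county, year and chemical class
#'
#' For every use record, the applied weight is converted to micrograms
#' (kg x 1e9) and divided by the compound's consensus LD50 (ug/bee),
#' yielding a count of honey-bee lethal doses; contact and oral loads use
#' the respective consensus values. Results are accumulated per
#' (county, year, chemical class); county-year totals are the sum over
#' classes.
#'
#' @param use Tibble of use records (`fips`, `year`, `compound`, `class`,
#'   `kg_low`, `kg_high`).
#' @param consensus Consensus LD50 table as from [consensus_table()]; must
#'   cover every compound in `use` for both routes.
#' @param variant `"low"` (default, the conservative estimate) or
#'   `"high"`.
#' @return Tibble `fips`, `year`, `class`, `kg`, `contact_load`,
#'   `oral_load`, `estimate_variant`, one row per county-year-class.
#' @export
compute_toxic_load <- function(use, consensus, variant = c("low", "high")) {
  variant <- match.arg(variant)
  kg <- if (variant == "low") use$kg_low else use$kg_high
  if (any(is.na(kg))) abort("use table contains missing kg values")
  bad <- kg < 0
  if (any(bad)) {
    warn(paste0("dropping ", sum(bad), " use rows with negative kg"))
    use <- use[!bad, , drop = FALSE]
    kg <- kg[!bad]
  }
  wide <- consensus %>%
    select("compound", "route", "ld50_ug_per_bee") %>%
    tidyr::pivot_wider(
      names_from = "route", values_from = "ld50_ug_per_bee"
    )
  missing <- setdiff(unique(use$compound), wide$compound)
  if (length(missing) > 0 ||
      any(is.na(wide$contact)) || any(is.na(wide$oral))) {
    abort(paste0(
      "consensus table lacks contact/oral values for: ",
      paste(union(missing, wide$compound[is.na(wide$contact) | is.na(wide$oral)]),
        collapse = ", "
      )
    ))
  }
  i <- match(use$compound, wide$compound)
  use %>%
    mutate(
      kg = kg,
      contact_load = kg * 1e9 / wide$contact[i],
      oral_load = kg * 1e9 / wide$oral[i]
    ) %>%
    group_by(.data$fips, .data$year, .data$class) %>%
    summarise(
      kg = sum(.data$kg),
      contact_load = sum(.data$contact_load),
      oral_load = sum(.data$oral_load),
      .groups = "drop"
    ) %>%
    mutate(estimate_variant = variant)
}

#' County-year totals from a class-level load table
#'
#' @param loads Output of [compute_toxic_load()].
#' @return Tibble `fips`, `year`, `kg`, `contact_load`, `oral_load`,
#'   `estimate_variant`.
#' @export
county_year_totals <- function(loads) {
  loads %>%
    group_by(.data$fips, .data$year, .data$estimate_variant) %>%
    summarise(
      kg = sum(.data$kg),
      contact_load = sum(.data$contact_load),
      oral_load = sum(.data$oral_load),
      .groups = "drop"
    ) %>%
    select(
      "fips", "year", "kg", "contact_load", "oral_load", "estimate_variant"
    )
}

# Fill one county's annual series: linear interpolation for interior gaps,
# constant extension of the nearest observed value at the edges, zeros when
# nothing was ever observed.
fill_one_series <- function(obs_years, obs_values, years) {
  if (length(obs_years) == 0) return(rep(0, length(years)))
  if (length(obs_years) == 1) return(rep(obs_values, length(years)))
  out <- approx(obs_years, obs_values, xout = years, rule = 2)$y
  out[match(obs_years, years)] <- obs_values # observed values untouched
  out
}

#' Fill missing county-years in a load series
#'
#' Counties with records in some years get interior gaps filled by linear
#' interpolation (independently for kg, contact load and oral load) and
#' leading/trailing gaps filled by constant extension of the nearest
#' observed value. Counties present in `all_fips` but absent from `loads`
#' in every year are assumed to have no agricultural insecticide use and
#' are filled with zeros. Observed rows are never altered; filled rows are
#' flagged `interpolated = TRUE`.
#'
#' @param totals County-year totals as from [county_year_totals()].
#' @param years Full study year range to fill to.
#' @param all_fips Optional county universe (e.g. every county in the
#'   land-use table); defaults to the counties present in `totals`.
#' @return Tibble like `totals` plus an `interpolated` flag, one row per
#'   (county, year).
#' @export
fill_missing_series <- function(totals, years, all_fips = NULL) {
  years <- sort(unique(as.integer(years)))
  all_fips <- sort(unique(c(all_fips, totals$fips)))
  variant <- if (nrow(totals) > 0) totals$estimate_variant[[1]] else "low"
  filled <- lapply(all_fips, function(f) {
    obs <- totals[totals$fips == f, , drop = FALSE]
    obs <- obs[order(obs$year), , drop = FALSE]
    obs <- obs[obs$year %in% years, , drop = FALSE]
    tibble(
      fips = f, year = years,
      kg = fill_one_series(obs$year, obs$kg, years),
      contact_load = fill_one_series(obs$year, obs$contact_load, years),
      oral_load = fill_one_series(obs$year, obs$oral_load, years),
      estimate_variant = variant,
      interpolated = !(years %in% obs$year)
    )
  })
  bind_rows(filled)
}

#' Annual class series at national or regional level
#'
#' Annual sums of kg, contact load and oral load per chemical class,
#' optionally broken out by region.
#'
#' @param loads Class-level loads from [compute_toxic_load()].
#' @param region_map Optional tibble `fips`, `region`; when supplied the
#'   series are computed per region.
#' @return Tibble `year`, `class` (and `region` if requested), `kg`,
#'   `contact_load`, `oral_load`.
#' @export
class_series <- function(loads, region_map = NULL) {
  by <- c("year", "class")
  if (!is.null(region_map)) {
    loads <- left_join(loads, region_map, by = "fips")
    if (any(is.na(loads$region))) {
      abort("`region_map` lacks a region for some counties in `loads`")
    }
    by <- c("region", by)
  }
  loads %>%
    group_by(across(all_of(by))) %>%
    summarise(
      kg = sum(.data$kg),
      contact_load = sum(.data$contact_load),
      oral_load = sum(.data$oral_load),
      .groups = "drop"
    )
}
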