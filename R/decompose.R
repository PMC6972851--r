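# Extent/intensity decomposition of bee toxic load: census imputation,
# county components, regional summaries and component fold changes.

#' Impute withheld census cells
#'
#' Each withheld (NA) cropland or treated-area cell is replaced by the
#' arithmetic mean of the county's non-missing values of that field in the
#' other census years, or by zero when the field is missing in all years.
#' After imputation, proportions are kept coherent by clamping
#' `cropland_ha` to `land_ha` and `treated_ha` to `cropland_ha`; clamped
#' rows are flagged. Row order is unchanged.
#'
#' @param landuse Land-use table as from [generate_landuse_table()]
#'   (columns `fips`, `year`, `land_ha`, `cropland_ha`, `treated_ha`, with
#'   `NA` for withheld cells).
#' @return The table with no missing values plus logical flags
#'   `cropland_imputed`, `treated_imputed`, `clamped`.
#' @export
impute_census <- function(landuse) {
  impute_field <- function(x) {
    miss <- is.na(x)
    if (!any(miss)) return(x)
    x[miss] <- if (all(miss)) 0 else mean(x[!miss])
    x
  }
  out <- landuse %>%
    mutate(
      cropland_imputed = is.na(.data$cropland_ha),
      treated_imputed = is.na(.data$treated_ha)
    ) %>%
    group_by(.data$fips) %>%
    mutate(
      cropland_ha = impute_field(.data$cropland_ha),
      treated_ha = impute_field(.data$treated_ha)
    ) %>%
    ungroup()
  clamped_crop <- out$cropland_ha > out$land_ha
  out$cropland_ha <- pmin(out$cropland_ha, out$land_ha)
  clamped_treat <- out$treated_ha > out$cropland_ha
  out$treated_ha <- pmin(out$treated_ha, out$cropland_ha)
  out$clamped <- clamped_crop | clamped_treat
  out
}

#' County-level components of bee toxic load
#'
#' Joins county-year toxic loads with (imputed) census land use on the
#' county id for the census years and computes the decomposition chain:
#' extent (`treated_ha / land_ha`), cropland fraction, proportion of
#' cropland treated, application rate (kg per treated ha), potency (bee
#' LD50s per kg, contact and oral), intensity (rate x potency, bee LD50s
#' per treated ha) and toxic load per land hectare. Counties with zero
#' treated area get `NA` (flagged `undefined_intensity`) for rate, potency
#' and intensity; load per hectare is still computed. Counties present in
#' `loads` but absent from `landuse` are excluded and reported in the
#' `unmatched_fips` attribute.
#'
#' @param loads County-year totals (typically [fill_missing_series()]
#'   output).
#' @param landuse Imputed land-use table from [impute_census()].
#' @param census_years Years to compute components for; defaults to the
#'   years present in `landuse`.
#' @return Tibble with one row per county and census year carrying the raw
#'   sums (`land_ha`, `cropland_ha`, `treated_ha`, `kg`, `contact_load`,
#'   `oral_load`) and the derived component fields.
#' @export
county_components <- function(loads, landuse, census_years = NULL) {
  census_years <- census_years %||% sort(unique(landuse$year))
  lu <- landuse %>% filter(.data$year %in% census_years)
  ld <- loads %>% filter(.data$year %in% census_years)
  unmatched <- setdiff(unique(ld$fips), unique(lu$fips))
  if (length(unmatched) > 0) {
    inform(paste0(
      "county_components(): ", length(unmatched),
      " counties in loads have no land-use record and were excluded"
    ))
  }
  out <- lu %>%
    left_join(
      select(
        ld, "fips", "year", "kg", "contact_load", "oral_load"
      ),
      by = c("fips", "year")
    ) %>%
    mutate(across(
      all_of(c("kg", "contact_load", "oral_load")),
      ~ tidyr::replace_na(.x, 0)
    )) %>%
    mutate(
      extent_land = .data$treated_ha / .data$land_ha,
      cropland_frac = .data$cropland_ha / .data$land_ha,
      prop_cropland_treated = ifelse(
        .data$cropland_ha > 0, .data$treated_ha / .data$cropland_ha, NA_real_
      ),
      undefined_intensity = .data$treated_ha <= 0,
      app_rate = ifelse(.data$treated_ha > 0, .data$kg / .data$treated_ha, NA_real_),
      potency_contact = ifelse(.data$kg > 0, .data$contact_load / .data$kg, NA_real_),
      potency_oral = ifelse(.data$kg > 0, .data$oral_load / .data$kg, NA_real_),
      intensity_contact = ifelse(
        .data$treated_ha > 0, .data$contact_load / .data$treated_ha, NA_real_
      ),
      intensity_oral = ifelse(
        .data$treated_ha > 0, .data$oral_load / .data$treated_ha, NA_real_
      ),
      load_per_ha_contact = .data$contact_load / .data$land_ha,
      load_per_ha_oral = .data$oral_load / .data$land_ha
    )
  attr(out, "unmatched_fips") <- unmatched
  out
}

#' Regional and national summary of toxic-load components
#'
#' Aggregates county components into per-region rows (plus a national
#' row) for one census year. All ratios are computed from regional sums
#' (e.g. total treated / total land, total load / total treated), not as
#' means of county-level ratios, so the multiplicative component chain
#' holds at every aggregation level.
#'
#' @param components County components from [county_components()].
#' @param region_map Tibble `fips`, `region` covering every county.
#' @param year Census year to summarize (default: the latest present).
#' @param national_label Label for the all-region row.
#' @return Tibble with one row per region plus the national row: raw sums,
#'   `extent_pct` (% of land treated), `pct_cropland_treated`, `app_rate`,
#'   potency, intensity (per treated ha) and load per land ha, per route.
#' @export
regional_summary <- function(components, region_map, year = NULL,
                             national_label = "Contiguous US") {
  year_sel <- year %||% max(components$year)
  df <- components %>% filter(.data$year == year_sel)
  df <- left_join(df, region_map, by = "fips")
  if (any(is.na(df$region))) {
    abort("`region_map` lacks a region for some counties in `components`")
  }
  summarize_block <- function(d, label) {
    tibble(
      region = label, year = year_sel,
      n_counties = nrow(d),
      land_ha = sum(d$land_ha), cropland_ha = sum(d$cropland_ha),
      treated_ha = sum(d$treated_ha), kg = sum(d$kg),
      contact_load = sum(d$contact_load), oral_load = sum(d$oral_load)
    ) %>%
      mutate(
        extent_pct = 100 * .data$treated_ha / .data$land_ha,
        pct_cropland_treated = 100 * .data$treated_ha / .data$cropland_ha,
        app_rate = .data$kg / .data$treated_ha,
        potency_contact = .data$contact_load / .data$kg,
        potency_oral = .data$oral_load / .data$kg,
        intensity_contact = .data$contact_load / .data$treated_ha,
        intensity_oral = .data$oral_load / .data$treated_ha,
        load_per_ha_contact = .data$contact_load / .data$land_ha,
        load_per_ha_oral = .data$oral_load / .data$land_ha
      )
  }
  regional <- df %>%
    group_by(.data$region) %>%
    dplyr::group_map(~ summarize_block(.x, .y$region)) %>%
    bind_rows() %>%
    arrange(.data$region)
  bind_rows(regional, summarize_block(df, national_label))
}

#' Component fold changes between two years
#'
#' Response ratios `value(y1) / value(y0)` for the components of bee toxic
#' load - total cropland, cropland treated, application rate, potency
#' (contact and oral) and toxic load (contact and oral) - at national or
#' regional aggregation. Components are aggregated by summation before the
#' ratio is taken. A non-positive baseline leaves the ratio undefined
#' (`NA`, flagged), never infinite.
#'
#' @param components County components from [county_components()].
#' @param y0,y1 Start and end census years.
#' @param region_map Optional tibble `fips`, `region`; when supplied the
#'   ratios are computed per region, otherwise nationally.
#' @return Tibble `unit`, `component`, `value_y0`, `value_y1`,
#'   `fold_change`, `undefined`.
#' @export
component_fold_changes <- function(components, y0, y1, region_map = NULL) {
  if (!all(c(y0, y1) %in% components$year)) {
    abort("both comparison years must be present in `components`")
  }
  df <- components %>% filter(.data$year %in% c(y0, y1))
  if (!is.null(region_map)) {
    df <- left_join(df, region_map, by = "fips")
    if (any(is.na(df$region))) {
      abort("`region_map` lacks a region for some counties")
    }
  } else {
    df$region <- "national"
  }
  agg <- df %>%
    group_by(.data$region, .data$year) %>%
    summarise(
      cropland_ha = sum(.data$cropland_ha),
      treated_ha = sum(.data$treated_ha),
      kg = sum(.data$kg),
      contact_load = sum(.data$contact_load),
      oral_load = sum(.data$oral_load),
      .groups = "drop"
    ) %>%
    mutate(
      app_rate = .data$kg / .data$treated_ha,
      potency_contact = .data$contact_load / .data$kg,
      potency_oral = .data$oral_load / .data$kg
    )
  comps <- c(
    "cropland_ha", "treated_ha", "app_rate", "potency_contact",
    "potency_oral", "contact_load", "oral_load"
  )
  agg %>%
    tidyr::pivot_longer(all_of(comps),
      names_to = "component", values_to = "value"
    ) %>%
    tidyr::pivot_wider(
      id_cols = c("region", "component"),
      names_from = "year", values_from = "value"
    ) %>%
    rename(unit = "region") %>%
    mutate(
      value_y0 = .data[[as.character(y0)]],
      value_y1 = .data[[as.character(y1)]],
      fold_change = fold_change(.data$value_y0, .data$value_y1),
      undefined = is.na(.data$fold_change)
    ) %>%
    select(
      "unit", "component", "value_y0", "value_y1", "fold_change", "undefined"
    )
}
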