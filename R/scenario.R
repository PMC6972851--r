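#' Farm resource region labels
#'
#' The nine USDA Farm Resource Region labels used to group counties in the
#' synthetic scenario and in regional summaries. The first two entries are
#' the regions in which the default scenario plants its large
#' neonicotinoid-driven increases in oral toxic load.
#'
#' @return Character vector of nine region names.
#' @export
farm_resource_regions <- function() {
  c(
    "Heartland", "Northern Great Plains", "Northern Crescent",
    "Prairie Gateway", "Eastern Uplands", "Southern Seaboard",
    "Fruitful Rim", "Basin and Range", "Mississippi Portal"
  )
}

#' Default compound catalog for the synthetic scenario
#'
#' A stylized catalog of ten insecticide active ingredients spanning the
#' major chemical classes (organophosphate, carbamate, pyrethroid,
#' neonicotinoid, phenylpyrazole, biological). Each entry carries a "true"
#' contact and oral acute honey-bee LD50 (ug/bee) and an application-rate
#' curve (kg active ingredient per treated hectare, one value per study
#' year). The class composition shifts over 1997-2012 away from
#' organophosphates and toward pyrethroids and neonicotinoids; the
#' neonicotinoid curves are zero before 2006 and grow exponentially after,
#' emulating the rise of seed treatments in row crops.
#'
#' LD50 values are stylized simulation inputs of realistic magnitude, not
#' reference toxicity data. The `scale_group` column marks which curves are
#' rescaled by the scenario calibration (see [generate_scenario()]):
#' `"neo"` and `"pyr"` curves receive calibrated multipliers so the planted
#' national fold changes in toxic load hit their configured targets exactly.
#'
#' @param years Integer vector of study years the rate curves cover.
#' @return A tibble with columns `compound`, `cas`, `class`, `moa_group`,
#'   `ld50_contact`, `ld50_oral`, `scale_group`, and a list-column
#'   `rate_curve` (kg/treated ha per year).
#' @export
default_compound_catalog <- function(years = 1997:2012) {
  t <- (years - min(years)) / (max(years) - min(years))
  lin <- function(a, b) a + (b - a) * t
  neo <- function(a, r) ifelse(years < 2006, 0, a * exp(r * (years - 2006)))
  tibble(
    compound = c(
      "chlorpyrifos", "malathion", "terbufos", "carbaryl",
      "lambda-cyhalothrin", "bifenthrin", "imidacloprid", "clothianidin",
      "fipronil", "bacillus-thuringiensis"
    ),
    cas = c(
      "2921-88-2", "121-75-5", "13071-79-9", "63-25-2",
      "91465-08-6", "82657-04-3", "138261-41-3", "210880-92-5",
      "120068-37-3", "68038-71-1"
    ),
    class = c("OP", "OP", "OP", "CARB", "PYR", "PYR", "NEO", "NEO", "FIP", "BIO"),
    moa_group = c("1B", "1B", "1B", "1A", "3A", "3A", "4A", "4A", "2B", "11A"),
    ld50_contact = c(0.059, 0.27, 1.5, 1.1, 0.038, 0.015, 0.30, 0.25, 0.0059, 110),
    ld50_oral = c(0.25, 0.38, 1.9, 0.18, 0.91, 0.10, 0.0037, 0.0037, 0.0042, 110),
    scale_group = c(
      "fixed", "fixed", "fixed", "fixed", "pyr", "pyr", "neo", "neo",
      "fixed", "fixed"
    ),
    rate_curve = list(
      lin(1.00, 0.40), lin(0.85, 0.38), lin(0.50, 0.15), lin(0.80, 0.45),
      lin(0.022, 0.055), lin(0.018, 0.070), neo(0.012, 0.45), neo(0.008, 0.50),
      rep(0.010, length(years)), lin(0.040, 0.090)
    )
  )
}

#' Default regional use multipliers
#'
#' Region-level multipliers applied to the per-treated-hectare application
#' rates. `base_mult` scales all non-neonicotinoid compounds and
#' `neo_mult` the neonicotinoids; concentrating neonicotinoid use in the
#' Heartland and Northern Great Plains (where baseline insecticide use is
#' low) plants the large regional oral fold-increases the clustering
#' analysis is designed to detect.
#'
#' @return A tibble with columns `region`, `base_mult`, `neo_mult`.
#' @export
default_region_weights <- function() {
  regions <- farm_resource_regions()
  tibble(
    region = regions,
    base_mult = dplyr::case_when(
      regions == "Heartland" ~ 0.25,
      regions == "Northern Great Plains" ~ 0.28,
      TRUE ~ 1.1
    ),
    neo_mult = dplyr::case_when(
      regions == "Heartland" ~ 11,
      regions == "Northern Great Plains" ~ 11,
      TRUE ~ 0.08
    )
  )
}

#' Scenario configuration for the synthetic data generator
#'
#' Bundles every knob of the synthetic study system: county structure,
#' study years, compound catalog, regional use weights, missingness
#' probabilities, the low-to-high estimate multiplier, toxicity-record noise
#' and the planted national fold-change targets. The same configuration
#' (including `seed`) always produces byte-identical tables.
#'
#' @param n_counties Number of counties, allocated as evenly as possible
#'   across the nine regions. Default 180 (20 per region).
#' @param n_urban Number of counties with no agricultural insecticide use in
#'   any year (exercises the zero-fill rule). Default 3.
#' @param years Inclusive study years. Default 1997:2012.
#' @param census_years Census years with land-use data; must be a subset of
#'   `years`. Default `c(1997, 2002, 2007, 2012)`.
#' @param catalog Compound catalog as produced by
#'   [default_compound_catalog()].
#' @param region_weights Regional multipliers as produced by
#'   [default_region_weights()].
#' @param missing_use_prob Probability that a (county, year) is entirely
#'   absent from the use table. Default 0.03.
#' @param withheld_prob Probability that a census cropland or treated-area
#'   cell is withheld. Default 0.08.
#' @param high_multiplier Factor (>= 1) mapping the low to the high kg
#'   estimate; either a scalar or a named vector by chemical class.
#'   Default 1.3.
#' @param ld50_sigma Log10-scale standard deviation of the log-normal noise
#'   on non-regulatory toxicity point records. Default 0.3.
#' @param decoys_per_compound Number of extra (non-consensus-affecting)
#'   toxicity records emitted per compound and route, cycling through
#'   non-regulatory points, unbounded estimates, larval tests, long
#'   durations, mg/bee units and non-contact/oral routes. Default 3.
#' @param compounds_without_records Compound ids for which no toxicity
#'   records are emitted at all (forces the mode-of-action fallback
#'   downstream). Default none.
#' @param county_factor_sigma Log-scale spread of the per-(county, compound)
#'   use heterogeneity factor. Default 0.3.
#' @param calibrate_folds Named numeric `c(contact = ..., oral = ...)`
#'   giving the planted national 1997 -> 2012 fold changes in toxic load;
#'   `NULL` disables calibration and uses the draft curves as-is.
#'   Default `c(contact = 1, oral = 9)`.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return An object of class `scenario_config` (a named list).
#' @export
scenario_config <- function(n_counties = 180,
                            n_urban = 3,
                            years = 1997:2012,
                            census_years = c(1997, 2002, 2007, 2012),
                            catalog = default_compound_catalog(years),
                            region_weights = default_region_weights(),
                            missing_use_prob = 0.03,
                            withheld_prob = 0.08,
                            high_multiplier = 1.3,
                            ld50_sigma = 0.3,
                            decoys_per_compound = 3,
                            compounds_without_records = character(0),
                            county_factor_sigma = 0.3,
                            calibrate_folds = c(contact = 1, oral = 9),
                            seed = 101) {
  years <- sort(as.integer(years))
  census_years <- sort(as.integer(census_years))
  if (!is_scalar_number(seed)) abort("`seed` must be a single finite number")
  if (!is_scalar_number(n_counties) || n_counties < length(farm_resource_regions())) {
    abort("`n_counties` must be at least one county per region")
  }
  if (n_urban < 0 || n_urban >= n_counties) abort("invalid `n_urban`")
  if (!all(census_years %in% years)) abort("`census_years` must be a subset of `years`")
  if (nrow(catalog) == 0L) abort("compound catalog is empty")
  if (any(catalog$ld50_contact <= 0) || any(catalog$ld50_oral <= 0)) {
    abort("all true LD50 values must be > 0")
  }
  if (any(vapply(catalog$rate_curve, length, 1L) != length(years))) {
    abort("every rate curve must have one value per study year")
  }
  if (any(vapply(catalog$rate_curve, function(r) any(r < 0), TRUE))) {
    abort("adoption curves must be non-negative")
  }
  if (missing_use_prob < 0 || missing_use_prob > 1 ||
      withheld_prob < 0 || withheld_prob > 1) {
    abort("missingness probabilities must lie in [0, 1]")
  }
  if (any(high_multiplier < 1)) abort("`high_multiplier` must be >= 1")
  if (!setequal(region_weights$region, farm_resource_regions())) {
    abort("`region_weights` must cover the nine farm resource regions")
  }
  if (!is.null(calibrate_folds)) {
    if (!all(c("contact", "oral") %in% names(calibrate_folds)) ||
        any(calibrate_folds <= 0)) {
      abort("`calibrate_folds` needs positive `contact` and `oral` entries")
    }
  }
  structure(
    list(
      n_counties = as.integer(n_counties), n_urban = as.integer(n_urban),
      years = years, census_years = census_years, catalog = catalog,
      region_weights = region_weights, missing_use_prob = missing_use_prob,
      withheld_prob = withheld_prob, high_multiplier = high_multiplier,
      ld50_sigma = ld50_sigma,
      decoys_per_compound = as.integer(decoys_per_compound),
      compounds_without_records = compounds_without_records,
      county_factor_sigma = county_factor_sigma,
      calibrate_folds = calibrate_folds, seed = as.integer(seed)
    ),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(
    "<scenario_config> ", x$n_counties, " counties, years ",
    min(x$years), "-", max(x$years), ", ", nrow(x$catalog),
    " compounds, seed ", x$seed, "\n",
    sep = ""
  )
  invisible(x)
}
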