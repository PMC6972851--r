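# Synthetic data generator: emits the three input tables the analysis
# consumes (pesticide use, census land use, raw toxicity records) with the
# statistical structure the pipeline assumes, plus a planted ground truth
# against which parameter recovery is tested.

# Deterministic scenario skeleton: counties, annual land use, per-county
# use heterogeneity, and the calibrated compound catalog. Everything
# downstream (all three tables and the ground truth) derives from this.
scenario_frame <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  regions <- farm_resource_regions()
  n_reg <- length(regions)
  per <- rep(config$n_counties %/% n_reg, n_reg)
  if (config$n_counties %% n_reg > 0) {
    per[seq_len(config$n_counties %% n_reg)] <- per[1] + 1L
  }
  region <- rep(regions, times = per)
  idx_in_region <- unlist(lapply(per, seq_len))
  fips <- sprintf("%02d%03d", match(region, regions), idx_in_region)

  counties <- with_preserved_seed(config$seed + 1L, {
    land_ha <- rlnorm(config$n_counties, meanlog = log(1.5e5), sdlog = 0.4)
    crop_lo <- ifelse(region == "Heartland", 0.55,
      ifelse(region == "Northern Great Plains", 0.35, 0.15)
    )
    crop_hi <- ifelse(region == "Heartland", 0.75,
      ifelse(region == "Northern Great Plains", 0.55, 0.45)
    )
    cropland_frac <- runif(config$n_counties, crop_lo, crop_hi)
    sigma <- config$county_factor_sigma
    factors <- matrix(
      rlnorm(config$n_counties * nrow(config$catalog),
        meanlog = -sigma^2 / 2, sdlog = sigma
      ),
      nrow = config$n_counties
    )
    urban <- seq_len(config$n_counties) > config$n_counties - config$n_urban
    list(
      tbl = tibble(
        fips = fips, region = region, urban = urban,
        seed_excluded = region %in% c("Fruitful Rim", "Basin and Range"),
        land_ha = land_ha,
        cropland_1997 = ifelse(urban, 0.005, cropland_frac) * land_ha
      ),
      factors = factors
    )
  })

  years <- config$years
  t_frac <- (years - min(years)) / max(1L, diff(range(years)))
  # Cropland contracts slightly over the period; the treated share of
  # cropland grows, emulating the documented expansion of insecticide
  # extent. Urban counties have no treated cropland at all.
  cropland <- outer(counties$tbl$cropland_1997, 1 - 0.12 * t_frac)
  treated_frac <- 0.15 + 0.11 * t_frac
  treated <- sweep(cropland, 2, treated_frac, `*`)
  treated[counties$tbl$urban, ] <- 0

  catalog <- calibrate_catalog(config, counties$tbl, counties$factors, treated)

  list(
    config = config, counties = counties$tbl, factors = counties$factors,
    years = years, cropland = cropland, treated = treated, catalog = catalog
  )
}

# Per-compound regional multiplier for each county.
county_multipliers <- function(counties, region_weights, classes) {
  base <- region_weights$base_mult[match(counties$region, region_weights$region)]
  neo <- region_weights$neo_mult[match(counties$region, region_weights$region)]
  vapply(classes, function(cl) if (cl == "NEO") neo else base,
    numeric(nrow(counties))
  )
}

# National kg of each compound in each year implied by the frame
# (counties x years treated matrix, regional multipliers, county factors).
national_kg_matrix <- function(catalog, counties, factors, treated, region_weights) {
  mult <- county_multipliers(counties, region_weights, catalog$class)
  sapply(seq_len(nrow(catalog)), function(i) {
    as.numeric(crossprod(mult[, i] * factors[, i], treated)) *
      catalog$rate_curve[[i]]
  }) # years x compounds
}

# Rescale the NEO- and PYR-class rate curves so the planted national fold
# changes in contact and oral toxic load equal their configured targets
# exactly. Linear 2x2 system: national load is linear in each scale factor.
calibrate_catalog <- function(config, counties, factors, treated) {
  catalog <- config$catalog
  targets <- config$calibrate_folds
  if (is.null(targets)) return(catalog)
  W <- national_kg_matrix(catalog, counties, factors, treated, config$region_weights)
  y0 <- 1L
  y1 <- nrow(W)
  group_load <- function(group, route, yr) {
    sel <- catalog$scale_group == group
    ld <- if (route == "contact") catalog$ld50_contact else catalog$ld50_oral
    sum(W[yr, sel] / ld[sel])
  }
  Fo <- unname(targets[["oral"]])
  Fc <- unname(targets[["contact"]])
  A <- rbind(
    c(
      group_load("neo", "oral", y1) - Fo * group_load("neo", "oral", y0),
      group_load("pyr", "oral", y1) - Fo * group_load("pyr", "oral", y0)
    ),
    c(
      group_load("neo", "contact", y1) - Fc * group_load("neo", "contact", y0),
      group_load("pyr", "contact", y1) - Fc * group_load("pyr", "contact", y0)
    )
  )
  b <- c(
    Fo * group_load("fixed", "oral", y0) - group_load("fixed", "oral", y1),
    Fc * group_load("fixed", "contact", y0) - group_load("fixed", "contact", y1)
  )
  sol <- solve(A, b)
  if (any(!is.finite(sol)) || any(sol <= 0)) {
    abort("scenario calibration has no positive solution; adjust the catalog")
  }
  scale <- c(neo = sol[1], pyr = sol[2], fixed = 1)[catalog$scale_group]
  catalog$rate_curve <- purrr::map2(
    catalog$rate_curve, unname(scale), function(r, s) r * s
  )
  catalog
}

# Full (county, year, compound) kg grid before missingness is applied.
scenario_use_grid <- function(frame) {
  catalog <- frame$catalog
  counties <- frame$counties
  mult <- county_multipliers(counties, frame$config$region_weights, catalog$class)
  rows <- lapply(seq_len(nrow(catalog)), function(i) {
    kg <- (mult[, i] * frame$factors[, i]) %o% catalog$rate_curve[[i]] *
      frame$treated
    tibble(
      compound = catalog$compound[i],
      class = catalog$class[i],
      year = rep(frame$years, each = nrow(counties)),
      fips = rep(counties$fips, times = length(frame$years)),
      seed_excluded = rep(counties$seed_excluded, times = length(frame$years)),
      kg_low = as.numeric(kg)
    )
  })
  bind_rows(rows) %>% filter(.data$kg_low > 0)
}

# Expand a scalar or class-named high multiplier to one value per row.
high_multiplier_for <- function(high_multiplier, class) {
  if (length(high_multiplier) == 1L && is.null(names(high_multiplier))) {
    return(rep(unname(high_multiplier), length(class)))
  }
  m <- unname(high_multiplier[class])
  if (any(is.na(m))) abort("`high_multiplier` lacks an entry for some chemical class")
  m
}

#' Generate the synthetic pesticide-use table
#'
#' One row per (county, year, compound) with a positive applied weight,
#' carrying both the low estimate and the high estimate
#' (`kg_high = kg_low * high_multiplier`). A configured fraction of
#' (county, year) combinations is dropped entirely to exercise downstream
#' interpolation, and counties in the Fruitful Rim and Basin and Range
#' regions carry a flag marking that seed-applied products are excluded from
#' their records (California-style reporting).
#'
#' The pre-missingness national weight of each compound in each year is
#' attached as attribute `intent_kg` so tests can verify conservation.
#'
#' @param config A [scenario_config()].
#' @return Tibble with columns `compound`, `class`, `year`, `fips`,
#'   `kg_low`, `kg_high`, `seed_excluded`.
#' @export
generate_use_table <- function(config) {
  frame <- scenario_frame(config)
  grid <- scenario_use_grid(frame)
  grid$kg_high <- grid$kg_low * high_multiplier_for(
    config$high_multiplier, grid$class
  )
  intent <- grid %>%
    group_by(.data$compound, .data$year) %>%
    summarise(kg = sum(.data$kg_low), .groups = "drop")
  out <- grid
  if (config$missing_use_prob > 0) {
    cy <- expand.grid(
      fips = frame$counties$fips, year = frame$years,
      stringsAsFactors = FALSE
    )
    drop <- with_preserved_seed(
      config$seed + 2L,
      cy[runif(nrow(cy)) < config$missing_use_prob, , drop = FALSE]
    )
    out <- anti_join(out, drop, by = c("fips", "year"))
  }
  out <- out %>%
    select(
      "compound", "class", "year", "fips", "kg_low", "kg_high",
      "seed_excluded"
    ) %>%
    arrange(.data$fips, .data$year, .data$compound)
  attr(out, "intent_kg") <- intent
  out
}

#' Generate the synthetic census land-use table
#'
#' One row per (county, census year) with total land area, cropland area
#' and cropland treated with insecticides (hectares). Within a county the
#' land area is constant across years and, before masking,
#' `treated_ha <= cropland_ha <= land_ha` by construction. A configured
#' fraction of cropland/treated cells is withheld (set to `NA` with the
#' corresponding flag set), emulating census disclosure suppression.
#'
#' @param config A [scenario_config()].
#' @return Tibble with columns `fips`, `year`, `land_ha`, `cropland_ha`,
#'   `treated_ha`, `cropland_withheld`, `treated_withheld`.
#' @export
generate_landuse_table <- function(config) {
  frame <- scenario_frame(config)
  keep <- match(config$census_years, frame$years)
  counties <- frame$counties
  out <- tibble(
    fips = rep(counties$fips, times = length(keep)),
    year = rep(config$census_years, each = nrow(counties)),
    land_ha = rep(counties$land_ha, times = length(keep)),
    cropland_ha = as.numeric(frame$cropland[, keep]),
    treated_ha = as.numeric(frame$treated[, keep])
  )
  withheld <- with_preserved_seed(config$seed + 3L, {
    matrix(runif(2L * nrow(out)) < config$withheld_prob, ncol = 2L)
  })
  out$cropland_withheld <- withheld[, 1]
  out$treated_withheld <- withheld[, 2]
  out$cropland_ha[out$cropland_withheld] <- NA_real_
  out$treated_ha[out$treated_withheld] <- NA_real_
  arrange(out, .data$fips, .data$year)
}

#' Generate synthetic raw honey-bee toxicity records
#'
#' For every compound in the catalog (unless listed in
#' `compounds_without_records`) emits, per route, one regulatory point
#' record at the compound's true LD50 plus `decoys_per_compound` additional
#' records cycling through the record types the standardization and
#' consensus rules must handle: non-regulatory points with log-normal noise,
#' unbounded ("greater than") regulatory estimates, larval tests, exposures
#' longer than four days, mg/bee units and non-contact/oral routes. The
#' decoys exercise the filters and lower consensus tiers without altering
#' the tier-1 consensus, so the consensus table recovers the true LD50s
#' exactly.
#'
#' @param config A [scenario_config()].
#' @return Tibble with columns `compound`, `cas`, `route`, `value`, `units`,
#'   `bound`, `source_tier`, `duration_days`, `life_stage`.
#' @export
generate_toxicity_records <- function(config) {
  catalog <- config$catalog %>%
    filter(!.data$compound %in% config$compounds_without_records)
  if (nrow(catalog) == 0L) return(empty_toxicity_table())
  with_preserved_seed(config$seed + 4L, {
    rows <- purrr::map(seq_len(nrow(catalog)), function(i) {
      purrr::map(c("contact", "oral"), function(route) {
        true <- if (route == "contact") catalog$ld50_contact[i] else catalog$ld50_oral[i]
        base <- tibble(
          compound = catalog$compound[i], cas = catalog$cas[i],
          route = route, value = true, units = "ug/bee", bound = "point",
          source_tier = "regulatory", duration_days = 2, life_stage = "adult"
        )
        decoys <- purrr::map(seq_len(config$decoys_per_compound), function(m) {
          noisy <- true * 10^rnorm(1, 0, config$ld50_sigma)
          switch(((m - 1L) %% 6L) + 1L,
            tibble(
              compound = catalog$compound[i], cas = catalog$cas[i],
              route = route, value = noisy, units = "ug/bee",
              bound = "point", source_tier = "other",
              duration_days = 2, life_stage = "adult"
            ),
            tibble(
              compound = catalog$compound[i], cas = catalog$cas[i],
              route = route, value = 2 * true, units = "ug/bee",
              bound = "greater_than", source_tier = "regulatory",
              duration_days = 2, life_stage = "adult"
            ),
            tibble(
              compound = catalog$compound[i], cas = catalog$cas[i],
              route = route, value = noisy, units = "ug/bee",
              bound = "point", source_tier = "other",
              duration_days = 3, life_stage = "larva"
            ),
            tibble(
              compound = catalog$compound[i], cas = catalog$cas[i],
              route = route, value = noisy, units = "ug/bee",
              bound = "point", source_tier = "other",
              duration_days = 7, life_stage = "adult"
            ),
            tibble(
              compound = catalog$compound[i], cas = catalog$cas[i],
              route = route, value = noisy / 1000, units = "mg/bee",
              bound = "point", source_tier = "other",
              duration_days = 2, life_stage = "adult"
            ),
            tibble(
              compound = catalog$compound[i], cas = catalog$cas[i],
              route = "other", value = noisy, units = "ug/bee",
              bound = "point", source_tier = "other",
              duration_days = 2, life_stage = "adult"
            )
          )
        })
        bind_rows(base, decoys)
      })
    })
    bind_rows(rows)
  })
}

empty_toxicity_table <- function() {
  tibble(
    compound = character(), cas = character(), route = character(),
    value = numeric(), units = character(), bound = character(),
    source_tier = character(), duration_days = numeric(),
    life_stage = character()
  )
}

# County-level toxic-load series implied by the pre-missingness use grid
# and the true catalog LD50s; urban/no-use counties appear with zeros.
scenario_truth <- function(frame) {
  grid <- scenario_use_grid(frame)
  catalog <- frame$catalog
  ldc <- setNames(catalog$ld50_contact, catalog$compound)
  ldo <- setNames(catalog$ld50_oral, catalog$compound)
  series <- grid %>%
    mutate(
      contact_load = .data$kg_low * 1e9 / ldc[.data$compound],
      oral_load = .data$kg_low * 1e9 / ldo[.data$compound]
    ) %>%
    group_by(.data$fips, .data$year) %>%
    summarise(
      kg = sum(.data$kg_low),
      contact_load = sum(.data$contact_load),
      oral_load = sum(.data$oral_load),
      .groups = "drop"
    ) %>%
    tidyr::complete(
      fips = frame$counties$fips, year = frame$years,
      fill = list(kg = 0, contact_load = 0, oral_load = 0)
    ) %>%
    arrange(.data$fips, .data$year)
  region_map <- select(frame$counties, "fips", "region")
  y0 <- min(frame$years)
  y1 <- max(frame$years)
  fold_of <- function(df, by) {
    df %>%
      filter(.data$year %in% c(y0, y1)) %>%
      tidyr::pivot_longer(c("contact_load", "oral_load"),
        names_to = "route", values_to = "load"
      ) %>%
      mutate(route = sub("_load$", "", .data$route)) %>%
      group_by(across(all_of(c(by, "route")))) %>%
      summarise(
        fold_change = sum(.data$load[.data$year == y1]) /
          sum(.data$load[.data$year == y0]),
        .groups = "drop"
      )
  }
  national <- fold_of(series, character(0))
  regional <- fold_of(left_join(series, region_map, by = "fips"), "region")
  list(
    national = national, regional = regional, county_series = series,
    years = c(y0, y1)
  )
}

#' Generate a complete synthetic scenario
#'
#' Runs all three table generators from one configuration and additionally
#' returns the county/region frame and the planted ground truth: the
#' pre-missingness county toxic-load series (true LD50s) and the national
#' and regional 1997 -> 2012 fold changes computed from it. With the default
#' configuration the planted national fold changes are exactly 9 (oral) and
#' 1 (contact).
#'
#' @param config A [scenario_config()].
#' @return A list with elements `use`, `landuse`, `toxicity` (the three
#'   input tables), `regions` (tibble `fips`, `region`, `urban`,
#'   `seed_excluded`, `land_ha`), `truth` (list `national`, `regional`,
#'   `county_series`) and `config`.
#' @export
generate_scenario <- function(config) {
  frame <- scenario_frame(config)
  list(
    use = generate_use_table(config),
    landuse = generate_landuse_table(config),
    toxicity = generate_toxicity_records(config),
    regions = select(
      frame$counties, "fips", "region", "urban", "seed_excluded", "land_ha"
    ),
    truth = scenario_truth(frame),
    config = config
  )
}
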