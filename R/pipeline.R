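# End-to-end orchestration: generate/ingest -> consensus -> toxic load ->
# components -> trends -> clustering -> classification, with every stage
# output materialized as delimited text and a hashed run manifest.

#' Pipeline run configuration
#'
#' Either a synthetic scenario or paths to the three input tables (plus a
#' county-to-region map) drive the run.
#'
#' @param scenario A [scenario_config()], or `NULL` when reading files.
#' @param paths Named list with entries `use`, `landuse`, `toxicity`,
#'   `region_map` when `scenario` is `NULL`.
#' @param out_dir Output directory (created if absent).
#' @param variant `"low"` (default) or `"high"` pesticide estimate.
#' @param k_classes Number of Jenks classes for the map tables. Default 5.
#' @param seed Seed recorded in the manifest; for scenario runs it
#'   overrides the scenario seed so one flag controls all randomness.
#' @return Object of class `run_config`.
#' @export
run_config <- function(scenario = NULL, paths = NULL, out_dir,
                       variant = c("low", "high"), k_classes = 5,
                       seed = NULL) {
  variant <- match.arg(variant)
  if (is.null(scenario) && is.null(paths)) {
    abort("either `scenario` or `paths` must be given")
  }
  if (!is.null(paths)) {
    need <- c("use", "landuse", "toxicity", "region_map")
    if (!all(need %in% names(paths))) {
      abort(paste0("`paths` needs entries: ", paste(need, collapse = ", ")))
    }
    missing <- !vapply(paths[need], file.exists, TRUE)
    if (any(missing)) {
      abort(paste0("input file(s) not found: ",
        paste(unlist(paths[need][missing]), collapse = ", ")))
    }
  }
  if (!is.null(scenario) && !is.null(seed)) {
    scenario$seed <- as.integer(seed)
  }
  structure(
    list(
      scenario = scenario, paths = paths, out_dir = out_dir,
      variant = variant, k_classes = as.integer(k_classes),
      seed = if (is.null(seed)) scenario$seed else as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized keys: `out_dir`, `variant`, `k_classes`, `seed`, either
#' `paths:` (`use`, `landuse`, `toxicity`, `region_map`) or `scenario:`
#' (any argument of [scenario_config()] except the catalog and region
#' weights, which keep their defaults).
#'
#' @param path YAML file.
#' @return A [run_config()].
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  scenario <- NULL
  if (!is.null(y$scenario)) {
    args <- y$scenario
    args <- args[names(args) %in% names(formals(scenario_config))]
    scenario <- do.call(scenario_config, args)
  }
  run_config(
    scenario = scenario, paths = y$paths,
    out_dir = y$out_dir %||% ".",
    variant = y$variant %||% "low",
    k_classes = y$k_classes %||% 5,
    seed = y$seed
  )
}

write_stage <- function(df, out_dir, name) {
  path <- file.path(out_dir, name)
  readr::write_csv(df, path)
  path
}

#' Run the full bee toxic load pipeline
#'
#' Executes every stage in order - simulate/ingest, toxicity consensus,
#' toxic-load computation with gap filling, census imputation and
#' component decomposition, regional summary, component fold changes,
#' Mann-Kendall trends, regional time-series clustering (contact and oral
#' separately) and Jenks map classification - writing each stage's output
#' as CSV (trees additionally as Newick) into `config$out_dir`, followed
#' by a manifest with an md5 hash per file and a `run_info.json` with the
#' configuration hash and run diagnostics (imputed cells, interpolated
#' county-years, clamped rows, consensus tier usage). Identical
#' configuration and seed give identical manifest hashes.
#'
#' A stage failure aborts the run with the failing stage named and leaves
#' a `FAILED_<stage>` marker file next to any partial outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results of every stage
#'   plus the `manifest` tibble.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  current_stage <- "setup"
  run_stage <- function(name, expr) {
    current_stage <<- name
    tryCatch(expr, error = function(e) {
      file.create(file.path(out_dir, paste0("FAILED_", name)))
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  files <- character(0)
  diag <- list()

  inputs <- run_stage("ingest", {
    if (!is.null(config$scenario)) {
      scen <- generate_scenario(config$scenario)
      files <- c(
        files,
        write_stage(scen$use, out_dir, "use.csv"),
        write_stage(scen$landuse, out_dir, "landuse.csv"),
        write_stage(scen$toxicity, out_dir, "toxicity.csv"),
        write_stage(scen$regions, out_dir, "regions.csv")
      )
      scen
    } else {
      list(
        use = read_use_table(config$paths$use),
        landuse = read_landuse_table(config$paths$landuse),
        toxicity = read_toxicity_table(config$paths$toxicity),
        regions = read_region_map(config$paths$region_map),
        truth = NULL, config = NULL
      )
    }
  })
  region_map <- select(inputs$regions, "fips", "region")
  years <- sort(unique(inputs$use$year))
  census_years <- sort(unique(inputs$landuse$year))

  consensus <- run_stage("consensus", {
    std <- standardize_toxicity_records(inputs$toxicity)
    moa <- if (!is.null(config$scenario)) {
      select(config$scenario$catalog, "compound", "moa_group")
    } else {
      # without an external map, chemical class stands in for the
      # mode-of-action group
      distinct(select(inputs$use, "compound", moa_group = "class"))
    }
    cons <- consensus_table(std, unique(inputs$use$compound), moa,
      standardized = TRUE
    )
    files <- c(files, write_stage(cons, out_dir, "consensus.csv"))
    diag$consensus_tier_usage <- as.list(table(cons$tier))
    diag$toxicity_records_dropped <- nrow(attr(std, "rejections"))
    cons
  })

  loads <- run_stage("load", {
    by_class <- compute_toxic_load(inputs$use, consensus, config$variant)
    totals <- fill_missing_series(
      county_year_totals(by_class), years,
      all_fips = unique(inputs$landuse$fips)
    )
    diag$interpolated_county_years <- sum(totals$interpolated)
    files <- c(
      files,
      write_stage(totals, out_dir, "county_year_load.csv"),
      write_stage(
        class_series(by_class, region_map), out_dir, "class_series.csv"
      )
    )
    list(by_class = by_class, totals = totals)
  })

  components <- run_stage("components", {
    lu <- impute_census(inputs$landuse)
    diag$imputed_census_cells <-
      sum(lu$cropland_imputed) + sum(lu$treated_imputed)
    diag$clamped_landuse_rows <- sum(lu$clamped)
    comp <- county_components(loads$totals, lu, census_years)
    summ <- regional_summary(comp, region_map, year = max(census_years))
    folds <- component_fold_changes(
      comp, min(census_years), max(census_years)
    )
    folds_regional <- component_fold_changes(
      comp, min(census_years), max(census_years), region_map
    )
    files <- c(
      files,
      write_stage(comp, out_dir, "county_components.csv"),
      write_stage(summ, out_dir, "regional_summary.csv"),
      write_stage(
        bind_rows(folds, folds_regional), out_dir, "component_folds.csv"
      )
    )
    list(county = comp, regional = summ,
      folds = bind_rows(folds, folds_regional))
  })

  trends <- run_stage("trends", {
    national <- loads$totals %>%
      group_by(.data$year) %>%
      summarise(
        kg = sum(.data$kg), contact_load = sum(.data$contact_load),
        oral_load = sum(.data$oral_load), .groups = "drop"
      ) %>%
      arrange(.data$year)
    regional <- loads$totals %>%
      left_join(region_map, by = "fips") %>%
      group_by(.data$region, .data$year) %>%
      summarise(oral_load = sum(.data$oral_load),
        contact_load = sum(.data$contact_load), .groups = "drop")
    rows <- bind_rows(
      mann_kendall(national$kg) %>% mutate(unit = "national", series = "kg"),
      mann_kendall(national$contact_load) %>%
        mutate(unit = "national", series = "contact_load"),
      mann_kendall(national$oral_load) %>%
        mutate(unit = "national", series = "oral_load"),
      bind_rows(lapply(split(regional, regional$region), function(d) {
        d <- arrange(d, .data$year)
        bind_rows(
          mann_kendall(d$oral_load) %>%
            mutate(unit = d$region[1], series = "oral_load"),
          mann_kendall(d$contact_load) %>%
            mutate(unit = d$region[1], series = "contact_load")
        )
      }))
    ) %>%
      select("unit", "series", everything())
    national_folds <- tibble(
      route = c("contact", "oral"),
      fold_change = c(
        fold_change(
          national$contact_load[national$year == min(years)],
          national$contact_load[national$year == max(years)]
        ),
        fold_change(
          national$oral_load[national$year == min(years)],
          national$oral_load[national$year == max(years)]
        )
      )
    )
    regional_folds <- regional %>%
      group_by(.data$region) %>%
      summarise(
        contact = fold_change(
          .data$contact_load[.data$year == min(years)],
          .data$contact_load[.data$year == max(years)]
        ),
        oral = fold_change(
          .data$oral_load[.data$year == min(years)],
          .data$oral_load[.data$year == max(years)]
        ),
        .groups = "drop"
      ) %>%
      tidyr::pivot_longer(c("contact", "oral"),
        names_to = "route", values_to = "fold_change"
      )
    files <- c(
      files,
      write_stage(rows, out_dir, "trend_tests.csv"),
      write_stage(
        bind_rows(
          mutate(national_folds, unit = "national"),
          rename(regional_folds, unit = "region")
        ) %>% select("unit", "route", "fold_change"),
        out_dir, "load_fold_changes.csv"
      )
    )
    list(
      tests = rows, national_series = national,
      national_folds = national_folds, regional_folds = regional_folds,
      regional_series = regional
    )
  })

  clusters <- run_stage("cluster", {
    mats <- lapply(c(oral = "oral_load", contact = "contact_load"),
      function(col) {
        wide <- trends$regional_series %>%
          select("region", "year", value = all_of(col)) %>%
          arrange(.data$region, .data$year) %>%
          tidyr::pivot_wider(names_from = "year", values_from = "value")
        m <- as.matrix(wide[, -1])
        rownames(m) <- wide$region
        t(apply(m, 1, normalize_series))
      }
    )
    trees <- lapply(mats, ward_cluster)
    for (route in names(trees)) {
      files <- c(
        files,
        write_stage(
          merge_table(trees[[route]]), out_dir,
          paste0("cluster_", route, "_merges.csv")
        )
      )
      nwk <- file.path(out_dir, paste0("cluster_", route, ".nwk"))
      writeLines(tree_newick(trees[[route]]), nwk)
      files <- c(files, nwk)
    }
    trees
  })

  classes <- run_stage("classify", {
    y1 <- max(census_years)
    y0 <- min(census_years)
    comp <- components$county
    level <- comp %>% filter(.data$year == y1)
    jb <- jenks_breaks(level$load_per_ha_oral, config$k_classes)
    chg <- comp %>%
      filter(.data$year %in% c(y0, y1)) %>%
      select("fips", "year", "load_per_ha_oral") %>%
      tidyr::pivot_wider(
        names_from = "year", values_from = "load_per_ha_oral"
      )
    chg$fold <- fold_change(chg[[as.character(y0)]], chg[[as.character(y1)]])
    chg <- chg[!is.na(chg$fold) & chg$fold > 0, , drop = FALSE]
    chg$log2_fold <- log2(chg$fold)
    zb <- if (any(chg$log2_fold < 0) && any(chg$log2_fold >= 0)) {
      zero_centered_breaks(chg$log2_fold, config$k_classes)
    } else {
      jenks_breaks(chg$log2_fold, min(config$k_classes, dplyr::n_distinct(chg$log2_fold)))
    }
    out <- list(
      level = tibble(
        fips = level$fips, year = y1,
        load_per_ha_oral = level$load_per_ha_oral,
        class = jb$assignment
      ),
      level_breaks = jb,
      change = tibble(
        fips = chg$fips, log2_fold = chg$log2_fold,
        class = zb$assignment
      ),
      change_breaks = zb
    )
    files <- c(
      files,
      write_stage(out$level, out_dir, "county_classes_level.csv"),
      write_stage(out$change, out_dir, "county_classes_change.csv")
    )
    out
  })

  manifest <- run_stage("manifest", {
    man <- tibble(
      file = basename(files),
      md5 = unname(tools::md5sum(files)),
      bytes = file.size(files)
    )
    info <- list(
      config_hash = rlang::hash(config),
      variant = config$variant, seed = config$seed,
      n_files = nrow(man), diagnostics = diag
    )
    jsonlite::write_json(
      info, file.path(out_dir, "run_info.json"),
      auto_unbox = TRUE, pretty = TRUE
    )
    readr::write_csv(man, file.path(out_dir, "manifest.csv"))
    man
  })

  invisible(list(
    inputs = inputs, consensus = consensus, loads = loads,
    components = components, trends = trends, clusters = clusters,
    classes = classes, manifest = manifest, diagnostics = diag
  ))
}

#' Low-versus-high estimate sensitivity comparison
#'
#' Recomputes county-year toxic loads under both the low and the high
#' pesticide estimate and reports (i) the per-county-year relative
#' difference `(high - low) / low` for kg and both loads and (ii) whether
#' the national Mann-Kendall trend direction and significance agree
#' between variants for each series.
#'
#' @param use Use table with both `kg_low` and `kg_high`.
#' @param consensus Consensus LD50 table covering the compounds in `use`.
#' @param years Full study year range.
#' @param all_fips Optional county universe for zero filling.
#' @param alpha Significance threshold for the agreement indicator.
#' @return List with `differences` (tibble per county-year) and
#'   `trend_agreement` (tibble per national series).
#' @export
sensitivity_compare <- function(use, consensus, years, all_fips = NULL,
                                alpha = 0.05) {
  both <- lapply(c("low", "high"), function(v) {
    fill_missing_series(
      county_year_totals(compute_toxic_load(use, consensus, v)),
      years, all_fips
    )
  })
  names(both) <- c("low", "high")
  diff <- left_join(
    both$low, both$high,
    by = c("fips", "year"), suffix = c("_low", "_high")
  ) %>%
    mutate(
      kg_rel_diff = ifelse(.data$kg_low > 0,
        (.data$kg_high - .data$kg_low) / .data$kg_low, NA_real_),
      contact_rel_diff = ifelse(.data$contact_load_low > 0,
        (.data$contact_load_high - .data$contact_load_low) /
          .data$contact_load_low, NA_real_),
      oral_rel_diff = ifelse(.data$oral_load_low > 0,
        (.data$oral_load_high - .data$oral_load_low) /
          .data$oral_load_low, NA_real_)
    ) %>%
    select(
      "fips", "year", "kg_rel_diff", "contact_rel_diff", "oral_rel_diff"
    )
  national <- lapply(both, function(d) {
    d %>%
      group_by(.data$year) %>%
      summarise(
        kg = sum(.data$kg), contact_load = sum(.data$contact_load),
        oral_load = sum(.data$oral_load), .groups = "drop"
      ) %>%
      arrange(.data$year)
  })
  agreement <- bind_rows(lapply(
    c("kg", "contact_load", "oral_load"),
    function(col) {
      lo <- mann_kendall(national$low[[col]])
      hi <- mann_kendall(national$high[[col]])
      tibble(
        series = col,
        tau_low = lo$tau, tau_high = hi$tau,
        p_low = lo$p_value, p_high = hi$p_value,
        direction_agrees = sign(lo$S) == sign(hi$S),
        significance_agrees = (lo$p_value < alpha) == (hi$p_value < alpha)
      )
    }
  ))
  list(differences = diff, trend_agreement = agreement)
}
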