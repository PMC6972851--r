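# Census imputation, the extent/intensity component chain, regional
# summaries and component fold changes.

landuse_fixture <- function() {
  tibble::tibble(
    fips = rep(c("00001", "00002"), each = 4),
    year = rep(c(1997L, 2002L, 2007L, 2012L), 2),
    land_ha = rep(c(1000, 2000), each = 4),
    cropland_ha = c(400, 420, 380, 400, 900, NA, 880, 860),
    treated_ha = c(100, 120, 140, NA, 200, 220, NA, 260),
    cropland_withheld = c(rep(FALSE, 5), TRUE, rep(FALSE, 2)),
    treated_withheld = c(rep(FALSE, 3), TRUE, FALSE, FALSE, TRUE, FALSE)
  )
}

test_that("withheld cells impute to the county mean of other years, else zero", {
  imp <- impute_census(landuse_fixture())
  expect_equal(imp$treated_ha[imp$fips == "00001" & imp$year == 2012], 120)
  expect_equal(imp$cropland_ha[imp$fips == "00002" & imp$year == 2002],
    mean(c(900, 880, 860)))
  all_na <- tibble::tibble(
    fips = "00003", year = c(1997L, 2002L), land_ha = 500,
    cropland_ha = NA_real_, treated_ha = NA_real_,
    cropland_withheld = TRUE, treated_withheld = TRUE
  )
  imp2 <- impute_census(all_na)
  expect_equal(imp2$cropland_ha, c(0, 0))
  expect_equal(imp2$treated_ha, c(0, 0))
  # no withheld cells: identity apart from the flag columns
  clean <- generate_landuse_table(tiny_config(withheld_prob = 0))
  imp3 <- impute_census(clean)
  expect_equal(imp3$treated_ha, clean$treated_ha)
  expect_false(any(imp3$clamped))
})

test_that("imputation clamps treated above cropland and flags it", {
  lu <- tibble::tibble(
    fips = "00009", year = c(1997L, 2002L), land_ha = 1000,
    cropland_ha = c(100, NA), treated_ha = c(90, 400),
    cropland_withheld = c(FALSE, TRUE), treated_withheld = FALSE
  )
  imp <- impute_census(lu)
  expect_equal(imp$cropland_ha[2], 100) # mean of the single other year
  expect_equal(imp$treated_ha[2], 100) # clamped from 400
  expect_true(imp$clamped[2])
  expect_true(all(imp$treated_ha <= imp$cropland_ha))
})

test_that("county components reproduce the worked magnitudes", {
  # 48 treated ha of 1000 land ha, oral load 720e9 LD50s:
  # extent 0.048, oral intensity 15e9 per treated ha, 0.72e9 per land ha
  lu <- tibble::tibble(
    fips = "00001", year = 2012L, land_ha = 1000, cropland_ha = 300,
    treated_ha = 48, cropland_withheld = FALSE, treated_withheld = FALSE
  )
  loads <- tibble::tibble(
    fips = "00001", year = 2012L, kg = 24, contact_load = 240e9,
    oral_load = 720e9, estimate_variant = "low", interpolated = FALSE
  )
  comp <- county_components(loads, impute_census(lu))
  expect_equal(comp$extent_land, 0.048)
  expect_equal(comp$intensity_oral, 15e9)
  expect_equal(comp$load_per_ha_oral, 0.72e9)
  expect_equal(comp$app_rate, 0.5)
  expect_equal(comp$potency_oral, 30e9)
})

test_that("zero treated area flags intensity undefined but keeps load per ha", {
  lu <- tibble::tibble(
    fips = "00001", year = 2012L, land_ha = 1000, cropland_ha = 0,
    treated_ha = 0, cropland_withheld = FALSE, treated_withheld = FALSE
  )
  loads <- tibble::tibble(
    fips = "00001", year = 2012L, kg = 5, contact_load = 1e9,
    oral_load = 2e9, estimate_variant = "low", interpolated = FALSE
  )
  comp <- county_components(loads, impute_census(lu))
  expect_true(comp$undefined_intensity)
  expect_true(is.na(comp$app_rate))
  expect_true(is.na(comp$intensity_oral))
  expect_equal(comp$load_per_ha_oral, 2e6)
})

test_that("the multiplicative component chain holds on synthetic county-years", {
  scen <- generate_scenario(tiny_config())
  comp <- county_components(
    scenario_filled_totals(scen), impute_census(scen$landuse),
    scen$config$census_years
  )
  ok <- !comp$undefined_intensity & comp$kg > 0
  lhs <- comp$load_per_ha_oral[ok]
  rhs <- comp$cropland_frac[ok] * comp$prop_cropland_treated[ok] *
    comp$app_rate[ok] * comp$potency_oral[ok]
  expect_equal(lhs, rhs, tolerance = 1e-9)
  expect_equal(
    comp$intensity_contact[ok],
    comp$app_rate[ok] * comp$potency_contact[ok],
    tolerance = 1e-9
  )
  expect_true(all(comp$extent_land >= 0 & comp$extent_land <= 1))
})

test_that("counties without land use are excluded and reported", {
  lu <- impute_census(landuse_fixture())
  loads <- tibble::tibble(
    fips = c("00001", "77777"), year = 2012L, kg = 1,
    contact_load = 1e9, oral_load = 1e9,
    estimate_variant = "low", interpolated = FALSE
  )
  expect_message(
    comp <- county_components(loads, lu, 2012L),
    "no land-use record"
  )
  expect_false("77777" %in% comp$fips)
  expect_equal(attr(comp, "unmatched_fips"), "77777")
})

test_that("regional summaries are sum-based, not means of county ratios", {
  scen <- generate_scenario(tiny_config())
  comp <- county_components(
    scenario_filled_totals(scen), impute_census(scen$landuse),
    scen$config$census_years
  )
  region_map <- dplyr::select(scen$regions, fips, region)
  summ <- regional_summary(comp, region_map, year = 2012)
  # oracle: direct sums for one region
  r1 <- comp[comp$year == 2012 &
    comp$fips %in% region_map$fips[region_map$region == "Heartland"], ]
  expect_equal(
    summ$intensity_oral[summ$region == "Heartland"],
    sum(r1$oral_load) / sum(r1$treated_ha)
  )
  expect_equal(
    summ$extent_pct[summ$region == "Heartland"],
    100 * sum(r1$treated_ha) / sum(r1$land_ha)
  )
  # single-county region equals the county row
  single_map <- tibble::tibble(fips = comp$fips[1], region = "solo")
  single <- regional_summary(
    comp[comp$fips == comp$fips[1], ], single_map, year = 2012
  )
  row <- comp[comp$fips == comp$fips[1] & comp$year == 2012, ]
  expect_equal(
    single$load_per_ha_oral[single$region == "solo"], row$load_per_ha_oral
  )
  # two identical counties leave the ratios unchanged
  twin <- dplyr::bind_rows(row, dplyr::mutate(row, fips = "twin0"))
  twin_map <- tibble::tibble(fips = twin$fips, region = "pair")
  twin_sum <- regional_summary(twin, twin_map, year = 2012)
  expect_equal(
    twin_sum$intensity_oral[twin_sum$region == "pair"], row$intensity_oral
  )
  # national row is the sum over everything
  expect_equal(
    summ$contact_load[summ$region == "Contiguous US"],
    sum(comp$contact_load[comp$year == 2012])
  )
  # regional loads sum to the national load
  expect_equal(
    sum(summ$load_per_ha_oral[summ$region != "Contiguous US"] *
      summ$land_ha[summ$region != "Contiguous US"]),
    summ$oral_load[summ$region == "Contiguous US"],
    tolerance = 1e-9
  )
  expect_error(
    regional_summary(comp, region_map[-1, ], year = 2012), "region"
  )
})

test_that("component fold changes multiply out to the load fold change", {
  scen <- generate_scenario(tiny_config())
  comp <- county_components(
    scenario_filled_totals(scen), impute_census(scen$landuse),
    scen$config$census_years
  )
  folds <- component_fold_changes(comp, 1997, 2012)
  get <- function(x) folds$fold_change[folds$component == x]
  # load ratio = extent-and-intensity component ratios multiplied:
  # treated * rate * potency (treated = cropland * proportion treated)
  expect_equal(
    get("oral_load"),
    get("treated_ha") * get("app_rate") * get("potency_oral"),
    tolerance = 1e-9
  )
  # all-unchanged series give ratio one
  same <- component_fold_changes(
    dplyr::bind_rows(
      dplyr::filter(comp, year == 1997),
      dplyr::mutate(dplyr::filter(comp, year == 1997), year = 2012L)
    ), 1997, 2012
  )
  expect_true(all(abs(same$fold_change - 1) < 1e-12))
  # a 10 -> 3 decline is a ratio of 0.3
  expect_equal(fold_change(10, 3), 0.3)
  # zero baseline is flagged undefined, not infinite
  zero_base <- comp
  zero_base$oral_load[zero_base$year == 1997] <- 0
  zb <- component_fold_changes(zero_base, 1997, 2012)
  expect_true(zb$undefined[zb$component == "oral_load"])
  expect_true(is.na(zb$fold_change[zb$component == "oral_load"]))
})
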