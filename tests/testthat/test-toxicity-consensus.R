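# Standardization filters and the tiered consensus ladder.

test_that("the four selection criteria are applied", {
  records <- dplyr::bind_rows(
    tox_record(value = 5, duration_days = 7), # (i) too long
    tox_record(value = 5, route = "other"), # (ii) wrong route
    tox_record(value = 5, life_stage = "larva"), # (iii) not adult
    tox_record(value = 0), # (iv) non-positive
    tox_record(value = 5, units = "other"), # unit not convertible
    tox_record(value = 0.01, units = "mg/bee", duration_days = 2), # keep, x1000
    tox_record(value = 5, duration_days = 4) # keep (4 days inclusive)
  )
  out <- standardize_toxicity_records(records)
  expect_equal(nrow(out), 2)
  expect_equal(out$value, c(10, 5))
  expect_true(all(out$units == "ug/bee"))
  rej <- attr(out, "rejections")
  expect_equal(nrow(rej), 5)
  expect_setequal(
    rej$reason,
    c(
      "exposure longer than 4 days", "route not contact/oral",
      "not an adult-bee test", "non-positive LD50",
      "units not convertible to ug/bee"
    )
  )
})

test_that("standardization is idempotent and order-preserving", {
  tox <- generate_toxicity_records(tiny_config(decoys_per_compound = 6))
  once <- standardize_toxicity_records(tox)
  twice <- standardize_toxicity_records(once)
  attr(once, "rejections") <- NULL
  attr(twice, "rejections") <- NULL
  expect_identical(once, twice)
})

test_that("consensus ladder applies rules strictly in order", {
  # two regulatory points -> geometric mean, tier 1
  r <- consensus_ld50(
    dplyr::bind_rows(tox_record(value = 1), tox_record(value = 4)), "oral"
  )
  expect_equal(r$ld50_ug_per_bee, 2)
  expect_equal(r$tier, 1L)
  expect_equal(r$n_records, 2L)
  # a single regulatory "greater than 11" -> 11, tier 3
  r <- consensus_ld50(
    tox_record(value = 11, bound = "greater_than"), "oral"
  )
  expect_equal(r$ld50_ug_per_bee, 11)
  expect_equal(r$tier, 3L)
  # non-regulatory point (rule 2) beats regulatory unbounded (rule 3)
  r <- consensus_ld50(
    dplyr::bind_rows(
      tox_record(value = 5, source_tier = "other"),
      tox_record(value = 2, bound = "less_than")
    ), "oral"
  )
  expect_equal(r$ld50_ug_per_bee, 5)
  expect_equal(r$tier, 2L)
  # within an unbounded tier, "less than" bounds win (minimum), else max
  r <- consensus_ld50(
    dplyr::bind_rows(
      tox_record(value = 8, bound = "greater_than"),
      tox_record(value = 3, bound = "less_than"),
      tox_record(value = 2, bound = "less_than")
    ), "oral"
  )
  expect_equal(r$ld50_ug_per_bee, 2)
  expect_equal(r$tier, 3L)
  # routes are independent
  r <- consensus_ld50(tox_record(value = 7, route = "contact"), "contact")
  expect_equal(r$ld50_ug_per_bee, 7)
})

test_that("adding a regulatory point estimate never increases the tier", {
  set.seed(404)
  bounds <- c("point", "less_than", "greater_than")
  for (rep in 1:20) {
    n <- sample(0:4, 1)
    recs <- if (n == 0) {
      tox_record(value = 1)[0, ]
    } else {
      dplyr::bind_rows(lapply(seq_len(n), function(i) {
        tox_record(
          value = runif(1, 0.1, 10),
          bound = sample(bounds, 1),
          source_tier = sample(c("regulatory", "other"), 1)
        )
      }))
    }
    moa <- tibble::tibble(moa_group = "g", route = "oral", median_ld50 = 1)
    before <- consensus_ld50(recs, "oral",
      compound = "cmp", moa_group = "g",
      moa_medians = moa, global_median = 1
    )
    after <- consensus_ld50(
      dplyr::bind_rows(recs, tox_record(value = 1)), "oral",
      compound = "cmp", moa_group = "g",
      moa_medians = moa, global_median = 1
    )
    expect_lte(after$tier, before$tier)
    expect_equal(after$tier, 1L)
  }
})

test_that("mode-of-action medians use tier 1-4 values and drop empty groups", {
  consensus <- tibble::tibble(
    compound = c("a", "b", "c", "d", "e", "f"),
    route = "oral",
    ld50_ug_per_bee = c(1, 10, 100, 1, 100, 7),
    tier = c(1L, 2L, 3L, 1L, 4L, 5L),
    n_records = c(1L, 1L, 1L, 1L, 1L, 0L)
  )
  moa <- tibble::tibble(
    compound = c("a", "b", "c", "d", "e", "f"),
    moa_group = c("g1", "g1", "g1", "g2", "g2", "g3")
  )
  med <- moa_median_table(consensus, moa)
  expect_equal(med$median_ld50[med$moa_group == "g1"], 10) # odd count
  expect_equal(med$median_ld50[med$moa_group == "g2"], 50.5) # midpoint
  expect_false("g3" %in% med$moa_group) # only a tier-5 member
})

test_that("a full fixture exercises all six tiers with hand-computed values", {
  records <- dplyr::bind_rows(
    # t1: regulatory points 1 and 4 -> geometric mean 2
    tox_record("t1", value = 1), tox_record("t1", value = 4),
    # one contact record anchors the contact route's fallback medians
    tox_record("t1", value = 1, route = "contact"),
    # t2: non-regulatory points 2 and 8 -> geometric mean 4
    tox_record("t2", value = 2, source_tier = "other"),
    tox_record("t2", value = 8, source_tier = "other"),
    # t3: regulatory bounds: less_than 6 wins over greater_than 9
    tox_record("t3", value = 6, bound = "less_than"),
    tox_record("t3", value = 9, bound = "greater_than"),
    # t4: non-regulatory greater_than bounds 5 and 12 -> max 12
    tox_record("t4", value = 5, bound = "greater_than", source_tier = "other"),
    tox_record("t4", value = 12, bound = "greater_than", source_tier = "other"),
    # t5: only unusable records (larval) -> falls to MoA median
    tox_record("t5", value = 3, life_stage = "larva")
    # t6: no records at all, and its group has no tier 1-4 member
  )
  moa <- tibble::tibble(
    compound = paste0("t", 1:6),
    moa_group = c("A", "A", "A", "B", "A", "C")
  )
  cons <- consensus_table(
    records, paste0("t", 1:6), moa
  ) |> dplyr::filter(route == "oral")
  got <- setNames(cons$ld50_ug_per_bee, cons$compound)
  tiers <- setNames(cons$tier, cons$compound)
  expect_equal(unname(got[paste0("t", 1:4)]), c(2, 4, 6, 12))
  expect_equal(unname(tiers[paste0("t", 1:4)]), 1:4)
  # t5: median of tier 1-4 values in group A = median(2, 4, 6) = 4
  expect_equal(unname(got["t5"]), 4)
  expect_equal(unname(tiers["t5"]), 5L)
  # t6: global median over all tier 1-4 values = median(2, 4, 6, 12) = 5
  expect_equal(unname(got["t6"]), 5)
  expect_equal(unname(tiers["t6"]), 6L)
  expect_true(all(cons$ld50_ug_per_bee > 0))
  expect_true(all(cons$n_records[cons$tier <= 4] >= 1))
})

test_that("every compound in the universe gets exactly one value per route", {
  scen <- generate_scenario(tiny_config())
  cons <- scenario_consensus(scen)
  compounds <- unique(scen$use$compound)
  expect_equal(nrow(cons), 2 * length(compounds))
  counts <- dplyr::count(cons, compound, route)
  expect_true(all(counts$n == 1))
  # default scenario: tier-1 records exist for all, so consensus == truth
  truth <- scen$config$catalog
  merged <- dplyr::left_join(
    cons, truth, by = "compound"
  )
  oral <- merged[merged$route == "oral", ]
  expect_equal(oral$ld50_ug_per_bee, oral$ld50_oral, tolerance = 1e-12)
  expect_true(all(cons$tier == 1L))
})

test_that("a compound with no records anywhere falls back through the ladder", {
  cfg <- tiny_config(compounds_without_records = "fipronil")
  scen <- generate_scenario(cfg)
  cons <- scenario_consensus(scen)
  fip <- cons[cons$compound == "fipronil", ]
  # fipronil is alone in its MoA group, so tier 5 is impossible: tier 6
  expect_true(all(fip$tier == 6L))
  others <- cons[cons$compound != "fipronil" & cons$route == "oral", ]
  expect_equal(fip$ld50_ug_per_bee[fip$route == "oral"],
    median(others$ld50_ug_per_bee))
})

test_that("an empty tier 1-4 universe is an explicit error", {
  records <- tox_record("only", value = 3, life_stage = "larva")
  moa <- tibble::tibble(compound = "only", moa_group = "g")
  expect_error(
    consensus_table(records, "only", moa),
    "tier 1-4"
  )
})
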