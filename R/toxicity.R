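# Standardization, filtering and tiered consensus of raw honey-bee acute
# toxicity records into one contact and one oral LD50 per compound.

toxicity_vocab <- list(
  route = c("contact", "oral", "other"),
  units = c("ug/bee", "mg/bee", "other"),
  bound = c("point", "less_than", "greater_than"),
  source_tier = c("regulatory", "other"),
  life_stage = c("adult", "larva", "other")
)

#' Standardize and filter raw toxicity records
#'
#' Applies the four selection criteria used to clean raw acute honey-bee
#' toxicity records: (i) exposure time four days or less, (ii) contact or
#' oral exposure, (iii) tests on adult bees, and (iv) a positive LD50 in
#' ug/bee. Records reported in mg/bee are converted to ug/bee (x 1000)
#' before the unit criterion is applied; records in any other unit, or with
#' route or life stage outside the recognized vocabularies, are dropped.
#' Row order of retained records is preserved.
#'
#' Rejected rows are not an error: they are returned (with a reason) in the
#' `rejections` attribute of the result, and a summary is emitted via
#' [rlang::inform()].
#'
#' @param records Tibble of raw toxicity records with columns `compound`,
#'   `route`, `value`, `units`, `bound`, `source_tier`, `duration_days`,
#'   `life_stage` (extra columns pass through).
#' @param quiet Suppress the rejection-count message. Default `TRUE`.
#' @return Tibble of retained records, all in ug/bee, with attribute
#'   `rejections` (tibble `row`, `reason`).
#' @export
standardize_toxicity_records <- function(records, quiet = TRUE) {
  records <- as_tibble(records)
  needed <- c(
    "compound", "route", "value", "units", "bound", "source_tier",
    "duration_days", "life_stage"
  )
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "toxicity records lack columns: ", paste(missing_cols, collapse = ", ")
    ))
  }
  value <- records$value
  units <- records$units
  mg <- !is.na(units) & units == "mg/bee"
  value[mg] <- value[mg] * 1000
  units[mg] <- "ug/bee"

  reason <- rep(NA_character_, nrow(records))
  flag <- function(cond, why) {
    ifelse(is.na(reason) & cond, why, reason)
  }
  reason <- flag(!records$bound %in% toxicity_vocab$bound |
    !records$source_tier %in% toxicity_vocab$source_tier,
  "unknown vocabulary entry"
  )
  reason <- flag(is.na(value) | !is.finite(value) | value <= 0, "non-positive LD50")
  reason <- flag(!units %in% "ug/bee", "units not convertible to ug/bee")
  reason <- flag(!records$route %in% c("contact", "oral"), "route not contact/oral")
  reason <- flag(is.na(records$duration_days) | records$duration_days > 4,
    "exposure longer than 4 days"
  )
  reason <- flag(!records$life_stage %in% "adult", "not an adult-bee test")

  keep <- is.na(reason)
  out <- records[keep, , drop = FALSE]
  out$value <- value[keep]
  out$units <- units[keep]
  rejections <- tibble(row = which(!keep), reason = reason[!keep])
  if (!quiet && nrow(rejections) > 0) {
    inform(paste0(
      "standardize_toxicity_records(): dropped ", nrow(rejections),
      " of ", nrow(records), " records"
    ))
  }
  attr(out, "rejections") <- rejections
  out
}

# Tier 1-4 value for one compound and route from standardized records;
# returns NULL when no point or unbounded estimate exists.
consensus_point <- function(records, route) {
  rec <- records[records$route == route, , drop = FALSE]
  for (tier in 1:4) {
    src <- if (tier %in% c(1, 3)) "regulatory" else "other"
    wants_point <- tier %in% c(1, 2)
    sub <- rec[rec$source_tier == src &
      (rec$bound == "point") == wants_point, , drop = FALSE]
    if (nrow(sub) == 0) next
    if (wants_point) {
      return(list(value = geometric_mean(sub$value), tier = tier, n = nrow(sub)))
    }
    # Unbounded estimates: a "less than" bound is an informative upper
    # limit and takes precedence (minimum); otherwise the maximum of the
    # "greater than" bounds.
    lt <- sub$value[sub$bound == "less_than"]
    gt <- sub$value[sub$bound == "greater_than"]
    if (length(lt) > 0) {
      return(list(value = min(lt), tier = tier, n = length(lt)))
    }
    if (length(gt) > 0) {
      return(list(value = max(gt), tier = tier, n = length(gt)))
    }
  }
  NULL
}

#' Consensus LD50 for a single compound and route
#'
#' Applies the tiered consensus ladder strictly in order: (1) geometric
#' mean of regulatory point estimates; (2) geometric mean of other point
#' estimates; (3) regulatory unbounded estimates, using the minimum of
#' "less than" bounds if any exist, else the maximum of "greater than"
#' bounds; (4) the same for non-regulatory unbounded estimates; (5) the
#' median of tier 1-4 consensus values in the compound's mode-of-action
#' group; (6) the median of all tier 1-4 consensus values. The returned
#' tier records which rule produced the value.
#'
#' @param records Standardized records for one compound (see
#'   [standardize_toxicity_records()]).
#' @param route `"contact"` or `"oral"`.
#' @param compound Compound id (used when `records` is empty).
#' @param moa_group Mode-of-action group of the compound; needed only when
#'   rules 1-4 fail.
#' @param moa_medians Tibble (`moa_group`, `route`, `median_ld50`) as
#'   produced by [moa_median_table()].
#' @param global_median Per-route fallback median over all compounds with
#'   tier 1-4 values; needed only when rule 5 also fails.
#' @return One-row tibble `compound`, `route`, `ld50_ug_per_bee`, `tier`,
#'   `n_records`.
#' @export
consensus_ld50 <- function(records, route,
                           compound = NULL, moa_group = NULL,
                           moa_medians = NULL, global_median = NULL) {
  route <- match.arg(route, c("contact", "oral"))
  if (nrow(records) > 0) {
    compound <- compound %||% records$compound[[1]]
    if (length(unique(records$compound)) > 1) {
      abort("consensus_ld50() expects records for a single compound")
    }
  }
  if (is.null(compound)) abort("`compound` must be supplied when `records` is empty")
  hit <- consensus_point(records, route)
  if (!is.null(hit)) {
    return(tibble(
      compound = compound, route = route, ld50_ug_per_bee = hit$value,
      tier = as.integer(hit$tier), n_records = as.integer(hit$n)
    ))
  }
  if (!is.null(moa_medians) && !is.null(moa_group)) {
    m <- moa_medians$median_ld50[
      moa_medians$moa_group == moa_group & moa_medians$route == route
    ]
    if (length(m) == 1 && is.finite(m)) {
      return(tibble(
        compound = compound, route = route, ld50_ug_per_bee = m,
        tier = 5L, n_records = 0L
      ))
    }
  }
  if (!is.null(global_median) && is.finite(global_median)) {
    return(tibble(
      compound = compound, route = route, ld50_ug_per_bee = global_median,
      tier = 6L, n_records = 0L
    ))
  }
  abort(paste0(
    "no consensus LD50 obtainable for ", compound, " (", route,
    "): no usable records and no fallback median available"
  ))
}

#' Per-group median LD50 table
#'
#' Median of the tier 1-4 consensus values within each mode-of-action
#' group, per route. Groups with no tier 1-4 member are absent from the
#' output. An even number of values yields the arithmetic midpoint of the
#' two central values (the standard median convention).
#'
#' @param consensus Tibble of consensus rows (only tiers 1-4 are used).
#' @param moa_table Tibble mapping `compound` to `moa_group`.
#' @return Tibble `moa_group`, `route`, `median_ld50`, `n_compounds`.
#' @export
moa_median_table <- function(consensus, moa_table) {
  consensus %>%
    filter(.data$tier <= 4L) %>%
    left_join(moa_table, by = "compound") %>%
    filter(!is.na(.data$moa_group)) %>%
    group_by(.data$moa_group, .data$route) %>%
    summarise(
      median_ld50 = median(.data$ld50_ug_per_bee),
      n_compounds = dplyr::n(),
      .groups = "drop"
    )
}

#' Consensus LD50 table for a compound universe
#'
#' Standardizes raw records (unless already standardized) and produces
#' exactly one contact and one oral consensus LD50 for every compound in
#' `compounds`, applying the tier 1-6 ladder. Tier 5 medians are computed
#' from the tier 1-4 consensus values within each mode-of-action group;
#' tier 6 from all tier 1-4 values of the route. If a route has no tier
#' 1-4 value for any compound anywhere, the fallback is undefined and an
#' error is raised.
#'
#' @param records Raw or standardized toxicity records.
#' @param compounds Character vector: the compound universe (e.g. every
#'   compound in the use table).
#' @param moa_table Tibble mapping `compound` to `moa_group`; must cover
#'   `compounds`.
#' @param standardized Set `TRUE` if `records` already passed
#'   [standardize_toxicity_records()].
#' @return Tibble `compound`, `route`, `ld50_ug_per_bee`, `tier`,
#'   `n_records`, one row per compound x route.
#' @export
consensus_table <- function(records, compounds, moa_table,
                            standardized = FALSE) {
  if (!standardized) records <- standardize_toxicity_records(records)
  if (!all(compounds %in% moa_table$compound)) {
    abort("`moa_table` must cover every compound in the universe")
  }
  compounds <- unique(compounds)
  direct <- bind_rows(lapply(compounds, function(cmp) {
    rec <- records[records$compound == cmp, , drop = FALSE]
    bind_rows(lapply(c("contact", "oral"), function(rt) {
      hit <- consensus_point(rec, rt)
      if (is.null(hit)) {
        return(tibble(
          compound = cmp, route = rt, ld50_ug_per_bee = NA_real_,
          tier = NA_integer_, n_records = 0L
        ))
      }
      tibble(
        compound = cmp, route = rt, ld50_ug_per_bee = hit$value,
        tier = as.integer(hit$tier), n_records = as.integer(hit$n)
      )
    }))
  }))
  resolved <- direct %>% filter(!is.na(.data$tier))
  medians <- moa_median_table(resolved, moa_table)
  globals <- resolved %>%
    group_by(.data$route) %>%
    summarise(global = median(.data$ld50_ug_per_bee), .groups = "drop")
  fallback <- direct %>% filter(is.na(.data$tier))
  if (nrow(fallback) > 0) {
    fallback <- bind_rows(lapply(seq_len(nrow(fallback)), function(i) {
      cmp <- fallback$compound[i]
      rt <- fallback$route[i]
      g <- globals$global[globals$route == rt]
      if (length(g) == 0) {
        abort(paste0(
          "no compound has a tier 1-4 ", rt,
          " value; the global fallback median is undefined"
        ))
      }
      consensus_ld50(
        records[0, , drop = FALSE], rt, compound = cmp,
        moa_group = moa_table$moa_group[match(cmp, moa_table$compound)],
        moa_medians = medians, global_median = g
      )
    }))
  }
  bind_rows(resolved, fallback) %>%
    arrange(.data$compound, .data$route)
}
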