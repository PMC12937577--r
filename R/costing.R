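#' Published annual cost-component calibration targets
#'
#' Group mean (SD) annual government cost, in 2023 AUD, for each reported
#' cost component by diagnosis-delay group, as printed in the source survey
#' analysis. These are the calibration targets of the synthetic-cohort
#' generator and the reference values for aggregation identities. The
#' professional-visit `subtotal` rows are the printed subtotals, which are
#' smaller than the sum of their printed component rows (participant-level
#' missingness in the source data); the printed group totals equal
#' investigations + professional-visit subtotal + hospitalizations +
#' medications.
#'
#' @return A data frame with columns `component`, `category`, `item`,
#'   `mean_lt6`, `sd_lt6`, `mean_ge6`, `sd_ge6`.
#' @export
reference_cost_components <- function() {
  data.frame(
    component = c("investigations",
                  "primary_care", "specialist", "rheum_nurse",
                  "allied_health",
                  "hosp_fracture", "hosp_infection", "hosp_injection",
                  "hosp_mental", "hosp_pain", "hosp_surgery",
                  "csDMARDS", "bDMARDS", "tsDMARDS", "oral_corticosteroid"),
    category = c("investigation",
                 rep("professional_visit", 4),
                 rep("hospitalization", 6),
                 rep("medication", 4)),
    item = c("diagnostics",
             "primary_care", "specialist", "rheum_nurse", "allied_health",
             "hosp_fracture", "hosp_infection", "hosp_injection",
             "hosp_mental", "hosp_pain", "hosp_surgery",
             NA, NA, NA, NA),
    mean_lt6 = c(1694, 459, 984, 464, 1153,
                 0, 811, 4750, 398, 1510, 28,
                 397, 5489, 943, 148),
    sd_lt6 = c(621, 230, 1132, 791, 1649,
               0, 4262, 8358, 4015, 4524, 288,
               242, 6033, 4176, 189),
    mean_ge6 = c(1753, 575, 1080, 421, 1831,
                 480, 2612, 5657, 0, 7299, 281,
                 430, 6080, 1262, 153),
    sd_ge6 = c(824, 295, 863, 1007, 2203,
               3751, 10164, 9543, 0, 26726, 1071,
               315, 6980, 4804, 191)
  )
}

#' Published category subtotals
#'
#' The printed per-category subtotal means by delay group (see
#' [reference_cost_components()] for why the professional-visit subtotal is
#' not the sum of its printed components).
#'
#' @export
reference_cost_subtotals <- function() {
  data.frame(
    category = c("investigation", "professional_visit", "hospitalization",
                 "medication", "total"),
    mean_lt6 = c(1694, 2596, 7498, 6978, 18765),
    sd_lt6 = c(621, 2754, 12152, 7446, 16416),
    mean_ge6 = c(1753, 3487, 16329, 7925, 29494),
    sd_ge6 = c(824, 2976, 31275, 9549, 37034)
  )
}

# Standard dosing assumptions for the medications captured by the survey.
# Doses/frequencies follow the published dosing notes (e.g. oral or
# subcutaneous methotrexate 15 mg weekly, adalimumab 40 mg fortnightly,
# prednisone 25 mg daily). Pack sizes and government pack costs are
# plausible placeholder schedule entries; the official subsidy schedule can
# be swapped in as data.
default_drug_table <- function() {
  data.frame(
    drug = c("methotrexate_oral", "methotrexate_sc", "hydroxychloroquine",
             "sulfasalazine", "leflunomide",
             "adalimumab", "etanercept", "infliximab", "tocilizumab",
             "abatacept", "secukinumab",
             "tofacitinib", "upadacitinib", "baricitinib",
             "prednisone"),
    class = c(rep("csDMARD", 5), rep("bDMARD", 6), rep("tsDMARD", 3),
              "oral_corticosteroid"),
    route = c("oral", "subcutaneous", "oral", "oral", "oral",
              rep("subcutaneous", 2), "infusion", rep("subcutaneous", 3),
              rep("oral", 3), "oral"),
    dose_mg = c(15, 15, 1400, 7000, 140,
                20, 50, 30, 162, 125, 150,
                70, 105, 28, 175),          # mg per week
    pack_mg = c(300, 60, 20000, 50000, 600,
                80, 200, 120, 648, 500, 600,
                280, 420, 112, 750),
    pack_cost = c(16.5, 92, 24, 22, 33,
                  1150, 1320, 760, 1210, 1530, 1480,
                  1080, 1190, 1130, 14.5),
    mix_weight = c(0.45, 0.30, 0.10, 0.08, 0.07,
                   0.40, 0.25, 0.10, 0.10, 0.08, 0.07,
                   0.5, 0.3, 0.2,
                   1)
  )
}

#' Default unit-cost schedule
#'
#' A bundled schedule of per-unit government costs in 2023 AUD: one priced
#' item per non-medication cost component (schedule fees for investigations
#' and professional visits, efficient-price-style per-admission costs for
#' hospitalizations), a per-drug dispensing table with standard dosing
#' assumptions, and Medicare Safety Net parameters (annual threshold plus
#' the additional government rebate fraction above it). Unit prices are
#' plausible placeholders: calibration targets are published component
#' means, not individual item fees, and any official schedule CSV can be
#' loaded in its place with [load_cost_schedule()].
#'
#' @return A `cost_schedule` object.
#' @export
default_cost_schedule <- function() {
  items <- data.frame(
    item = c("diagnostics",
             "primary_care", "care_plan", "specialist", "rheum_nurse",
             "allied_health",
             "hosp_fracture", "hosp_infection", "hosp_injection",
             "hosp_mental", "hosp_pain", "hosp_surgery"),
    category = c("investigation",
                 rep("professional_visit", 5),
                 rep("hospitalization", 6)),
    component = c("investigations",
                  "primary_care", "primary_care", "specialist",
                  "rheum_nurse", "allied_health",
                  "hosp_fracture", "hosp_infection", "hosp_injection",
                  "hosp_mental", "hosp_pain", "hosp_surgery"),
    unit_cost = c(160,
                  42, 147, 91, 28, 58,
                  5500, 5200, 1150, 7800, 5400, 8800)
  )
  new_cost_schedule(items, default_drug_table(),
                    safety_net = list(threshold = 2414,
                                      rebate_fraction = 0.8))
}

new_cost_schedule <- function(items, drugs, safety_net) {
  assert_nonneg(items$unit_cost, "unit_cost")
  assert_nonneg(drugs$pack_cost, "pack_cost")
  assert_prob(safety_net$rebate_fraction, "safety_net$rebate_fraction")
  assert_nonneg(safety_net$threshold, "safety_net$threshold")
  if (anyDuplicated(items$item)) {
    stop("duplicate item codes in schedule", call. = FALSE)
  }
  structure(list(items = items, drugs = drugs, safety_net = safety_net),
            class = "cost_schedule")
}

#' Load a unit-cost schedule
#'
#' @param items A data frame (or CSV path) with columns `item`, `category`,
#'   `component`, `unit_cost`.
#' @param drugs Optional drug dispensing table (columns as in the bundled
#'   default: `drug`, `class`, `route`, `dose_mg` per week, `pack_mg`,
#'   `pack_cost`, `mix_weight`); defaults to the bundled table.
#' @param safety_net List with `threshold` (AUD/year) and `rebate_fraction`.
#' @return A `cost_schedule`.
#' @export
load_cost_schedule <- function(items, drugs = default_drug_table(),
                               safety_net = list(threshold = 2414,
                                                 rebate_fraction = 0.8)) {
  if (is.character(items)) items <- utils::read.csv(items,
                                                    stringsAsFactors = FALSE)
  req <- c("item", "category", "component", "unit_cost")
  if (!all(req %in% names(items))) {
    stop("schedule needs columns item, category, component, unit_cost",
         call. = FALSE)
  }
  new_cost_schedule(items, drugs, safety_net)
}

#' @export
print.cost_schedule <- function(x, ...) {
  cat("Unit-cost schedule:", nrow(x$items), "items,",
      nrow(x$drugs), "priced drugs\n")
  cat("  safety net: threshold", x$safety_net$threshold, "AUD, rebate",
      x$safety_net$rebate_fraction, "\n")
  invisible(x)
}

#' Construct a medication regimen
#'
#' @param drug Drug code present in the schedule's drug table.
#' @param dose_mg Dose in mg per administration-week (total weekly mg);
#'   defaults to the standard dosing assumption for the drug.
#' @param schedule A `cost_schedule` used for defaults and validation.
#' @return A `medication_regimen` list with drug, class, route and weekly
#'   dose.
#' @export
medication_regimen <- function(drug, dose_mg = NULL,
                               schedule = default_cost_schedule()) {
  row <- schedule$drugs[schedule$drugs$drug == drug, ]
  if (nrow(row) == 0) {
    stop("unpriced drug code: ", drug, call. = FALSE)
  }
  dose_mg <- dose_mg %||% row$dose_mg
  if (dose_mg <= 0) stop("dose must be strictly positive", call. = FALSE)
  structure(list(drug = drug, class = row$class, route = row$route,
                 dose_mg = dose_mg), class = "medication_regimen")
}

medication_rows <- c("csDMARDS", "bDMARDS", "tsDMARDS", "oral_corticosteroid")

# Annual dispensed cost of one regimen: whole packs are dispensed, so packs
# per year round up.
regimen_annual_cost <- function(drug, dose_mg, schedule) {
  row <- schedule$drugs[match(drug, schedule$drugs$drug), ]
  if (anyNA(row$drug)) {
    stop("unpriced drug code(s): ",
         paste(unique(drug[is.na(row$drug)]), collapse = ", "),
         call. = FALSE)
  }
  annual_mg <- dose_mg * 52
  ceiling(annual_mg / row$pack_mg) * row$pack_cost
}

#' Annual medication cost by class
#'
#' Aggregates a participant's regimens into the four reported medication
#' rows (csDMARDs, bDMARDs, tsDMARDs, oral corticosteroids). Dispensing is
#' whole-pack: packs per year are rounded up. Corticosteroid injections and
#' infusions are not costed here -- they are included in hospitalization
#' costs -- so only oral corticosteroids contribute to the corticosteroid
#' row.
#'
#' @param regimens A list of [medication_regimen()] objects (possibly empty).
#' @param schedule A `cost_schedule`.
#' @return Named numeric vector over the four medication rows, AUD/year.
#' @export
annual_medication_cost <- function(regimens,
                                   schedule = default_cost_schedule()) {
  out <- setNames(numeric(4), medication_rows)
  if (length(regimens) == 0) return(out)
  for (reg in regimens) {
    stopifnot(inherits(reg, "medication_regimen"))
    if (reg$class == "oral_corticosteroid" && reg$route != "oral") next
    cost <- regimen_annual_cost(reg$drug, reg$dose_mg, schedule)
    row <- switch(reg$class,
                  csDMARD = "csDMARDS", bDMARD = "bDMARDS",
                  tsDMARD = "tsDMARDS",
                  oral_corticosteroid = "oral_corticosteroid")
    out[row] <- out[row] + cost
  }
  out
}

#' Construct a utilization record
#'
#' @param counts Named annual counts over schedule item codes (visits,
#'   investigations, admissions); must be non-negative integers.
#' @param medications List of [medication_regimen()] objects.
#' @param safety_net_reached Survey flag: participant reported reaching the
#'   Medicare Safety Net.
#' @param care_plan Survey flag: chronic disease care plan in place (assumed
#'   for participants using allied health).
#' @export
utilization_record <- function(counts = c(), medications = list(),
                               safety_net_reached = FALSE,
                               care_plan = FALSE) {
  counts <- unlist(counts)
  if (length(counts)) {
    if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
    if (any(counts != round(counts))) {
      stop("visit/admission counts must be integer-valued", call. = FALSE)
    }
  }
  structure(list(counts = counts, medications = medications,
                 safety_net_reached = isTRUE(safety_net_reached),
                 care_plan = isTRUE(care_plan)),
            class = "utilization_record")
}

#' Annual cost breakdown for one participant
#'
#' Per-component cost = annual count x unit cost (medications via
#' [annual_medication_cost()]). When the care-plan flag is set and any
#' allied-health use is recorded, one annual care-plan rebate item is added
#' to the primary-care component. When the safety-net flag is set, the
#' additional government rebate (`rebate_fraction` of schedule-fee spend
#' above the annual threshold) is allocated proportionally across the
#' schedule-fee components (investigations and professional visits).
#'
#' @param utilization A [utilization_record()].
#' @param schedule A `cost_schedule`.
#' @return A `cost_breakdown`: `components` data frame (component, category,
#'   cost), named `subtotals` by category, and `total`. Total equals the sum
#'   of subtotals, each subtotal the sum of its components.
#' @export
annual_cost_breakdown <- function(utilization,
                                  schedule = default_cost_schedule()) {
  stopifnot(inherits(utilization, "utilization_record"))
  items <- schedule$items
  counts <- utilization$counts
  if (length(counts)) {
    unknown <- setdiff(names(counts), items$item)
    if (length(unknown)) {
      stop("unknown schedule item(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  full <- setNames(numeric(nrow(items)), items$item)
  full[names(counts)] <- counts
  if (utilization$care_plan && "allied_health" %in% names(full) &&
      full[["allied_health"]] > 0 && "care_plan" %in% items$item) {
    full[["care_plan"]] <- full[["care_plan"]] + 1
  }
  cost_by_item <- full * items$unit_cost

  # Safety-net top-up on schedule-fee categories, allocated proportionally.
  fee_cat <- items$category %in% c("investigation", "professional_visit")
  if (utilization$safety_net_reached) {
    spend <- sum(cost_by_item[fee_cat])
    extra <- schedule$safety_net$rebate_fraction *
      max(0, spend - schedule$safety_net$threshold)
    if (extra > 0 && spend > 0) {
      cost_by_item[fee_cat] <- cost_by_item[fee_cat] * (1 + extra / spend)
    }
  }

  comp <- stats::aggregate(cost ~ component + category,
                           data = data.frame(component = items$component,
                                             category = items$category,
                                             cost = cost_by_item),
                           FUN = sum)
  med <- annual_medication_cost(utilization$medications, schedule)
  comp <- rbind(comp,
                data.frame(component = names(med),
                           category = "medication", cost = unname(med)))
  subtot <- tapply(comp$cost, comp$category, sum)
  subtot <- subtot[c("investigation", "professional_visit",
                     "hospitalization", "medication")]
  subtot[is.na(subtot)] <- 0
  names(subtot) <- c("investigation", "professional_visit",
                     "hospitalization", "medication")
  structure(list(components = comp, subtotals = subtot,
                 total = sum(subtot)),
            class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat("Annual government cost (AUD):", format(round(x$total)), "\n")
  for (cat_ in names(x$subtotals)) {
    cat(sprintf("  %-20s %10.0f\n", cat_, x$subtotals[[cat_]]))
  }
  invisible(x)
}

# Vectorized costing over a cohort data frame; equivalent to calling
# annual_cost_breakdown() row by row (asserted in tests) but fast enough for
# large synthetic cohorts.
#' Annual costs for every participant in a cohort
#'
#' @param cohort Cohort data frame with `n_<item>` count columns,
#'   `med_<class>` drug-code columns, and `safety_net_reached`/`care_plan`
#'   flags (see [generate_cohort()]).
#' @param schedule A `cost_schedule`.
#' @return Data frame, one row per participant: component cost columns,
#'   category subtotal columns (`subtotal_*`) and `total`.
#' @export
cohort_costs <- function(cohort, schedule = default_cost_schedule()) {
  items <- schedule$items
  n <- nrow(cohort)
  count_cols <- paste0("n_", items$item)
  have <- count_cols %in% names(cohort)
  counts <- matrix(0, n, nrow(items), dimnames = list(NULL, items$item))
  for (i in which(have)) counts[, i] <- cohort[[count_cols[i]]]
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if ("care_plan" %in% items$item && "care_plan" %in% names(cohort)) {
    allied <- if ("n_allied_health" %in% names(cohort)) {
      cohort$n_allied_health
    } else 0
    counts[, "care_plan"] <- counts[, "care_plan"] +
      as.numeric(cohort$care_plan & allied > 0)
  }
  item_cost <- sweep(counts, 2, items$unit_cost, `*`)

  fee_cat <- items$category %in% c("investigation", "professional_visit")
  if ("safety_net_reached" %in% names(cohort)) {
    flagged <- which(as.logical(cohort$safety_net_reached))
    if (length(flagged)) {
      spend <- rowSums(item_cost[flagged, fee_cat, drop = FALSE])
      extra <- schedule$safety_net$rebate_fraction *
        pmax(0, spend - schedule$safety_net$threshold)
      scale <- ifelse(spend > 0, 1 + extra / spend, 1)
      item_cost[flagged, fee_cat] <-
        item_cost[flagged, fee_cat, drop = FALSE] * scale
    }
  }

  out <- data.frame(matrix(nrow = n, ncol = 0))
  for (cmp in unique(items$component)) {
    out[[cmp]] <- rowSums(item_cost[, items$component == cmp, drop = FALSE])
  }

  # medications: per-class annual cost looked up from the drug code
  drug_cost <- setNames(
    regimen_annual_cost(schedule$drugs$drug, schedule$drugs$dose_mg,
                        schedule),
    schedule$drugs$drug)
  med_map <- c(med_csdmard = "csDMARDS", med_bdmard = "bDMARDS",
               med_tsdmard = "tsDMARDS", med_steroid = "oral_corticosteroid")
  for (col in names(med_map)) {
    v <- numeric(n)
    if (col %in% names(cohort)) {
      codes <- as.character(cohort[[col]])
      on_drug <- !is.na(codes) & codes != ""
      if (any(on_drug)) {
        unknown <- setdiff(codes[on_drug], names(drug_cost))
        if (length(unknown)) {
          stop("unpriced drug code(s): ", paste(unknown, collapse = ", "),
               call. = FALSE)
        }
        v[on_drug] <- drug_cost[codes[on_drug]]
      }
    }
    out[[med_map[[col]]]] <- v
  }

  cat_of <- c(setNames(items$category, items$component),
              setNames(rep("medication", 4), medication_rows))
  for (cat_ in c("investigation", "professional_visit", "hospitalization",
                 "medication")) {
    cols <- names(out)[!startsWith(names(out), "subtotal_") &
                         cat_of[names(out)] == cat_]
    out[[paste0("subtotal_", cat_)]] <-
      rowSums(out[, cols, drop = FALSE])
  }
  out$total <- rowSums(out[, paste0("subtotal_",
                                    c("investigation", "professional_visit",
                                      "hospitalization", "medication"))])
  out
}

#' Group cost summary table
#'
#' Component-level mean (SD) per delay group with Welch t-test p-values,
#' shaped like the published annual-cost table, plus recomputed category
#' subtotals and total.
#'
#' @param cohort Cohort data frame.
#' @param schedule A `cost_schedule`.
#' @return Data frame with one row per component/subtotal/total.
#' @export
cost_summary_table <- function(cohort, schedule = default_cost_schedule()) {
  costs <- cohort_costs(cohort, schedule)
  grp <- cohort$delay_group
  rows <- names(costs)
  do.call(rbind, lapply(rows, function(r) {
    a <- costs[[r]][grp == "lt6"]
    b <- costs[[r]][grp == "ge6plus"]
    p <- if (length(a) >= 2 && length(b) >= 2 &&
             (stats::var(a) + stats::var(b)) > 0) {
      stats::t.test(a, b)$p.value
    } else NA_real_
    data.frame(row = r, mean_lt6 = mean(a), sd_lt6 = stats::sd(a),
               mean_ge6 = mean(b), sd_ge6 = stats::sd(b), p_value = p)
  }))
}
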