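#' Descriptive characteristics table by delay group
#'
#' Group summaries with hypothesis tests in the style of a baseline
#' characteristics table: continuous characteristics get mean (SD), median
#' (IQR) and a Welch t-test; categorical/logical characteristics get counts
#' (with percentages recomputed at render time) and a chi-squared test,
#' falling back to Fisher's exact test (flagged) when an expected cell is
#' small. Missing values are excluded row-wise and counted.
#'
#' @param cohort Cohort data frame.
#' @param characteristics Column names to summarize.
#' @param correct Continuity correction for the chi-squared test (default
#'   `FALSE`).
#' @return Data frame, one row per characteristic level, with columns for
#'   both groups, the p-value and the test used. Constant characteristics
#'   are flagged with `test = "skipped"` and `p_value = NA`.
#' @export
descriptive_table <- function(cohort, characteristics, correct = FALSE) {
  if (nrow(cohort) == 0) stop("cohort must be nonempty", call. = FALSE)
  miss <- setdiff(characteristics, names(cohort))
  if (length(miss)) {
    stop("characteristic(s) absent from cohort: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  grp <- cohort$delay_group
  rows <- list()
  push <- function(df) rows[[length(rows) + 1]] <<- df
  for (ch in characteristics) {
    x <- cohort[[ch]]
    ok <- !is.na(x)
    a <- x[ok & grp == "lt6"]
    b <- x[ok & grp == "ge6plus"]
    if (is.numeric(x)) {
      constant <- (length(unique(c(a, b))) < 2)
      p <- if (!constant && length(a) >= 2 && length(b) >= 2) {
        stats::t.test(a, b)$p.value
      } else NA_real_
      push(data.frame(
        characteristic = ch, level = "",
        summary_lt6 = sprintf("%.1f (± %.1f); median %.1f (%.1f-%.1f)",
                              mean(a), stats::sd(a),
                              stats::median(a),
                              stats::quantile(a, 0.25),
                              stats::quantile(a, 0.75)),
        summary_ge6 = sprintf("%.1f (± %.1f); median %.1f (%.1f-%.1f)",
                              mean(b), stats::sd(b),
                              stats::median(b),
                              stats::quantile(b, 0.25),
                              stats::quantile(b, 0.75)),
        n_missing = sum(!ok),
        p_value = p,
        test = if (constant) "skipped" else "welch-t"))
    } else {
      xf <- factor(x[ok])
      if (nlevels(xf) < 2) {
        push(data.frame(characteristic = ch, level = levels(xf)[1] %||% "",
                        summary_lt6 = sprintf("%d (100.0%%)", length(a)),
                        summary_ge6 = sprintf("%d (100.0%%)", length(b)),
                        n_missing = sum(!ok), p_value = NA_real_,
                        test = "skipped"))
        next
      }
      tab <- table(xf, droplevels(factor(grp[ok],
                                         levels = c("lt6", "ge6plus"))))
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        p <- stats::fisher.test(tab)$p.value
        test <- "fisher"
      } else {
        p <- suppressWarnings(
          stats::chisq.test(tab, correct = correct)$p.value)
        test <- "chi-squared"
      }
      for (lv in levels(xf)) {
        na_ <- sum(a == lv); nb_ <- sum(b == lv)
        push(data.frame(
          characteristic = ch, level = lv,
          summary_lt6 = sprintf("%d (%.1f%%)", na_,
                                100 * na_ / max(length(a), 1)),
          summary_ge6 = sprintf("%d (%.1f%%)", nb_,
                                100 * nb_ / max(length(b), 1)),
          n_missing = sum(!ok), p_value = p, test = test))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Concordance of the two time-to-diagnosis measures
#'
#' Pearson correlation (with Fisher-z 95% CI) between the binned
#' seeking-to-diagnosis delay (mapped to bin midpoints) and the
#' onset-to-diagnosis delay computed from ages. With `measure = "reported"`
#' the delay uses the survey-reported (coarsened) ages, as in the source
#' analysis; `"exact"` uses the generator's pre-coarsening ages.
#'
#' @param cohort Cohort data frame.
#' @param measure Which onset-to-diagnosis delay to correlate against.
#' @return List with `r`, `ci_low`, `ci_high`, `n`.
#' @export
time_measure_concordance <- function(cohort,
                                     measure = c("reported", "exact")) {
  measure <- match.arg(measure)
  x <- cohort$delay_seek_years
  y <- if (measure == "reported") {
    cohort$age_diagnosis - cohort$age_onset
  } else {
    cohort$delay_onset_dx_exact
  }
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("too few observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in a delay measure; correlation undefined",
         call. = FALSE)
  }
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), ci_low = ct$conf.int[1],
       ci_high = ct$conf.int[2], n = length(x))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (optional) -> CHU9D scoring -> costing -> lifetime
#' projection -> incremental cost-utility/NMB -> one-way sensitivity ->
#' budget impact, and optionally writes every table plus a run log (seed
#' and all parameters in effect) to an output directory. With a fixed seed
#' the whole bundle is byte-identical across reruns.
#'
#' @param config A list (or path of a YAML file) with optional entries:
#'   `cohort` (a cohort data frame, or CSV path readable by
#'   [read_cohort()]), `cohort_params` (arguments for [cohort_params()],
#'   used when no cohort is given), `econ` (arguments for [econ_params()]),
#'   `value_set`, `schedule`, `life_table` (objects or CSV paths),
#'   `scenarios`, `budget` (arguments for [budget_impact()] other than
#'   `nmb_per_child`), `n_boot` and `boot_seed` for the CEA plane, and
#'   `out_dir`.
#' @return A list of results: `cohort`, `calibration`, `descriptives`,
#'   `chu9d`, `costs`, `utility_unadjusted`, `utility_adjusted`,
#'   `cost_unadjusted`, `pv`, `nmb`, `cea`, `sensitivity`, `budget`,
#'   `concordance`, `log`.
#' @export
run_full_analysis <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", what, conditionMessage(e)),
           call. = FALSE)
    })
  }
  value_set <- stage("value_set", {
    vs <- config[["value_set"]] %||% default_chu9d_value_set()
    if (is.character(vs)) vs <- load_value_set(vs) else vs
  })
  schedule <- stage("schedule", {
    sc <- config[["schedule"]] %||% default_cost_schedule()
    if (is.character(sc)) load_cost_schedule(sc) else sc
  })
  life_table <- stage("life_table", {
    lt <- config[["life_table"]] %||% default_life_table()
    if (is.character(lt)) load_life_table(lt) else lt
  })
  eparams <- stage("econ_params",
                   do.call(econ_params, config[["econ"]] %||% list()))
  cparams <- NULL
  cohort <- stage("cohort", {
    if (!is.null(config[["cohort"]])) {
      if (is.character(config[["cohort"]])) read_cohort(config[["cohort"]])
      else config[["cohort"]]
    } else {
      cparams <- do.call(cohort_params, config[["cohort_params"]] %||% list())
      generate_cohort(cparams, value_set, schedule)
    }
  })
  cparams <- cparams %||% attr(cohort, "params")

  calibration <- if (!is.null(cparams)) {
    stage("calibration",
          calibration_report(cohort, cparams, value_set, schedule))
  }
  descriptives <- stage("descriptives", descriptive_table(
    cohort, c("age_onset", "age_diagnosis", "age_survey", "sex",
              "uveitis")))
  concordance <- stage("concordance", time_measure_concordance(cohort))
  chu <- stage("chu9d", dimension_summary(cohort, value_set))
  costs <- stage("costing", cost_summary_table(cohort, schedule))
  utility <- score_cohort_utilities(cohort, value_set)
  total_cost <- cohort_costs(cohort, schedule)$total
  grp <- cohort$delay_group
  utility_unadj <- stage("utility", incremental_mean(
    utility[grp == "lt6"], utility[grp == "ge6plus"],
    outcome = "CHU9D utility"))
  utility_adj <- stage("utility_adjusted",
                       adjusted_difference(cohort, utility))
  cost_unadj <- stage("cost", incremental_mean(
    total_cost[grp == "lt6"], total_cost[grp == "ge6plus"],
    sign = "ge6_minus_lt6", outcome = "annual cost savings"))
  pv <- stage("projection", cohort_present_values(
    cohort, value_set, schedule, life_table, eparams))
  nmb <- stage("nmb", incremental_nmb(pv, eparams))
  cea <- stage("cea_plane", cea_plane(pv, config[["n_boot"]] %||% 2000,
                                      config[["boot_seed"]] %||% 1))
  sens <- stage("sensitivity", one_way_sensitivity(
    cohort, config[["scenarios"]] %||% default_scenarios(), eparams,
    value_set, schedule, life_table))
  budget_args <- config[["budget"]] %||% list()
  budget_args$nmb_per_child <- nmb$aud$difference
  budget <- stage("budget", do.call(budget_impact, budget_args))

  log_lines <- c(
    "jiacea run log",
    sprintf("n_participants: %d", nrow(cohort)),
    sprintf("seed: %s", if (!is.null(cparams)) cparams$seed else "external"),
    sprintf("discount_rate: %g", eparams$discount_rate),
    sprintf("wtp_per_qaly: %g", eparams$wtp_per_qaly),
    sprintf("aud_usd_rate: %g", eparams$aud_usd_rate),
    sprintf("exclusion_window: %g", eparams$exclusion_window),
    sprintf("use_sex_specific: %s", eparams$use_sex_specific),
    sprintf("value_set: %s", value_set$name),
    sprintf("n_excluded_missing_chu9d: %d", attr(pv, "n_excluded")),
    sprintf("boot: n=%d seed=%d", config[["n_boot"]] %||% 2000,
            config[["boot_seed"]] %||% 1))

  out <- list(cohort = cohort, calibration = calibration,
              descriptives = descriptives, concordance = concordance,
              chu9d = chu, costs = costs,
              utility_unadjusted = utility_unadj,
              utility_adjusted = utility_adj,
              cost_unadjusted = cost_unadj,
              pv = pv, nmb = nmb, cea = cea, sensitivity = sens,
              budget = budget, log = log_lines)

  if (!is.null(config[["out_dir"]])) {
    dir.create(config[["out_dir"]], recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) {
      utils::write.csv(df, file.path(config[["out_dir"]],
                                     paste0(name, ".csv")),
                       row.names = FALSE, quote = FALSE)
    }
    write_cohort(cohort, file.path(config[["out_dir"]], "cohort.csv"))
    if (!is.null(calibration)) wr(calibration, "calibration")
    wr(descriptives, "descriptives")
    wr(chu, "chu9d_dimensions")
    wr(costs, "cost_components")
    wr(sens, "sensitivity")
    wr(cea$points, "cea_plane_points")
    inc_df <- function(r) data.frame(
      outcome = r$outcome, mean_lt6 = r$mean_lt6, mean_ge6 = r$mean_ge6,
      difference = r$difference, ci_low = r$ci_low, ci_high = r$ci_high,
      p_value = r$p_value)
    wr(rbind(inc_df(utility_unadj), inc_df(utility_adj),
             inc_df(cost_unadj), inc_df(nmb$qalys),
             inc_df(nmb$cost_savings), inc_df(nmb$aud), inc_df(nmb$usd)),
       "incremental_results")
    wr(data.frame(incident_children = budget$incident_children,
                  affected_children = budget$affected_children,
                  total_benefit_forgone = budget$total_benefit_forgone),
       "budget_impact")
    writeLines(log_lines, file.path(config[["out_dir"]], "run_log.txt"))
  }
  out
}
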