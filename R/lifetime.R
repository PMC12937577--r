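#' Default synthetic life table
#'
#' A smooth synthetic period life table built from a Gompertz-Makeham
#' hazard, with the Makeham and shape constants fixed and the Gompertz level
#' solved so that life expectancy at birth equals the target (84.5 years
#' unisex by default, with optional female/male columns at 86.5/82.5).
#' This is a synthetic stand-in with contemporary high-income-country life
#' expectancy; any official national life table can be substituted via
#' [load_life_table()].
#'
#' @param e0 Named life expectancies at birth per sex column.
#' @param max_age Oldest tabulated age (whole years).
#' @return A `life_table` data frame with columns `age`, `sex`,
#'   `expectancy`.
#' @export
default_life_table <- function(e0 = c(unisex = 84.5, female = 86.5,
                                      male = 82.5),
                               max_age = 105) {
  A <- 2e-4   # Makeham background hazard
  C <- 0.095  # Gompertz shape
  grid <- seq(0, 120, by = 0.05)
  ex_for <- function(B) {
    # survival and remaining expectancy on a fine grid, trapezoid rule
    H <- A * grid + B / C * (exp(C * grid) - 1)
    S <- exp(-H)
    area <- rev(cumsum(rev((S[-1] + S[-length(S)]) / 2 * diff(grid)))) # from x up
    area <- c(area, 0)
    area / S
  }
  tabs <- lapply(names(e0), function(sx) {
    B <- stats::uniroot(function(b) ex_for(b)[1] - e0[[sx]],
                        c(1e-9, 1e-2), tol = 1e-14)$root
    ex <- ex_for(B)
    idx <- match(0:max_age, grid)
    data.frame(age = 0:max_age, sex = sx, expectancy = ex[idx])
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  class(out) <- c("life_table", "data.frame")
  out
}

#' Load and validate a life table
#'
#' @param table Data frame (or CSV path) with columns `age` (whole years),
#'   `sex`, `expectancy` (remaining life expectancy in years).
#' @return A `life_table` data frame. Expectancy must be non-negative and
#'   weakly decreasing in age within sex, except below age 2 where the usual
#'   infant-mortality rise of full tables is allowed.
#' @export
load_life_table <- function(table) {
  if (is.character(table)) table <- utils::read.csv(table,
                                                    stringsAsFactors = FALSE)
  req <- c("age", "sex", "expectancy")
  if (!all(req %in% names(table))) {
    stop("life table needs columns age, sex, expectancy", call. = FALSE)
  }
  if (any(table$expectancy < 0)) {
    stop("remaining life expectancy must be non-negative", call. = FALSE)
  }
  for (sx in unique(table$sex)) {
    sub <- table[table$sex == sx, ]
    sub <- sub[order(sub$age), ]
    inc <- diff(sub$expectancy) > 1e-9
    if (any(inc & sub$age[-1] >= 2)) {
      stop("expectancy must be weakly decreasing in age (sex ", sx, ")",
           call. = FALSE)
    }
  }
  class(table) <- c("life_table", "data.frame")
  table
}

#' Remaining life expectancy at an exact age
#'
#' Linear interpolation between whole-year life-table rows.
#'
#' @param age Exact age(s) in years.
#' @param sex Sex column of the table to use; recycled. Defaults to
#'   `"unisex"`.
#' @param life_table A `life_table`.
#' @return Remaining life expectancy in years.
#' @export
remaining_life_years <- function(age, sex = "unisex",
                                 life_table = default_life_table()) {
  if (any(age < 0)) stop("age must be non-negative", call. = FALSE)
  n <- max(length(age), length(sex))
  age <- rep_len(age, n)
  sex <- rep_len(sex, n)
  out <- numeric(n)
  for (sx in unique(sex)) {
    sub <- life_table[life_table$sex == sx, ]
    if (nrow(sub) == 0) {
      stop("life table has no rows for sex '", sx, "'", call. = FALSE)
    }
    sel <- sex == sx
    if (any(age[sel] < min(sub$age) | age[sel] > max(sub$age))) {
      stop("age outside life-table range [", min(sub$age), ", ",
           max(sub$age), "]", call. = FALSE)
    }
    out[sel] <- stats::approx(sub$age, sub$expectancy, xout = age[sel])$y
  }
  out
}

#' Economic evaluation parameters
#'
#' @param discount_rate Annual discount rate applied to future costs and
#'   QALYs (default 0.05).
#' @param wtp_per_qaly Willingness to pay for one QALY, AUD (default
#'   50,000).
#' @param aud_usd_rate AUD per USD exchange rate for reporting (default
#'   1.51, the 2023 rate).
#' @param horizon Only `"lifetime"` is supported: annual differences are
#'   held constant over each participant's remaining life expectancy.
#' @param exclusion_window Years since diagnosis below which participants
#'   are dropped in the short-term-effects sensitivity scenario (default 1).
#' @param use_sex_specific Project with sex-specific life-table columns
#'   instead of the unisex column (default `FALSE`).
#' @return An `econ_params` list.
#' @export
econ_params <- function(discount_rate = 0.05, wtp_per_qaly = 50000,
                        aud_usd_rate = 1.51, horizon = "lifetime",
                        exclusion_window = 1, use_sex_specific = FALSE) {
  assert_nonneg(discount_rate, "discount_rate")
  assert_nonneg(wtp_per_qaly, "wtp_per_qaly")
  if (aud_usd_rate <= 0) stop("exchange rate must be positive",
                              call. = FALSE)
  horizon <- match.arg(horizon, "lifetime")
  structure(list(discount_rate = discount_rate,
                 wtp_per_qaly = wtp_per_qaly,
                 aud_usd_rate = aud_usd_rate, horizon = horizon,
                 exclusion_window = exclusion_window,
                 use_sex_specific = isTRUE(use_sex_specific)),
            class = "econ_params")
}

#' Present-value annuity factor
#'
#' Present value of a level annual stream of 1 paid at the end of each of
#' `years` years, discounted at `rate` per annum:
#' \eqn{(1 - (1+r)^{-n})/r} for whole years, with a fractional final year
#' prorated at its end-of-year discount factor. At `rate = 0` the factor is
#' simply `years`; as `years` grows it is bounded by the perpetuity value
#' `1/rate`.
#'
#' @param rate Annual discount rate (>= 0).
#' @param years Horizon in years (>= 0, may be fractional). Vectorized.
#' @export
annuity_factor <- function(rate, years) {
  if (any(rate < 0) || any(years < 0)) {
    stop("rate and years must be non-negative", call. = FALSE)
  }
  n <- max(length(rate), length(years))
  rate <- rep_len(rate, n)
  years <- rep_len(years, n)
  m <- floor(years)
  frac <- years - m
  out <- ifelse(rate == 0, years,
                (1 - (1 + rate)^(-m)) / ifelse(rate == 0, 1, rate) +
                  frac * (1 + rate)^(-(m + 1)))
  out
}

#' Present-valued lifetime QALYs and costs per participant
#'
#' Applies the constant-difference lifetime projection: each participant's
#' measured annual utility and annual cost are held constant over their
#' remaining life expectancy (from age at survey) and discounted annually.
#' `pv_qalys = utility x annuity`, `pv_costs = annual_cost x annuity`.
#'
#' @param age_survey Age(s) at survey completion, years.
#' @param sex Participant sex, used only when
#'   `params$use_sex_specific = TRUE`.
#' @param utility CHU9D utility value(s); `NA` excludes the participant.
#' @param annual_cost Annual government healthcare cost(s), AUD.
#' @param life_table A `life_table`.
#' @param params An [econ_params()] object.
#' @return Data frame with `years_remaining`, `annuity`, `pv_qalys`,
#'   `pv_costs` and logical `included`; excluded rows (missing utility or
#'   cost) carry NA present values, and the exclusion count is stored in
#'   attribute `n_excluded`.
#' @export
participant_present_values <- function(age_survey, sex = "unisex",
                                       utility, annual_cost,
                                       life_table = default_life_table(),
                                       params = econ_params()) {
  stopifnot(inherits(params, "econ_params"))
  sex_used <- if (params$use_sex_specific) sex else "unisex"
  yrs <- remaining_life_years(age_survey, sex_used, life_table)
  af <- annuity_factor(params$discount_rate, yrs)
  included <- !is.na(utility) & !is.na(annual_cost)
  out <- data.frame(years_remaining = yrs, annuity = af,
                    pv_qalys = ifelse(included, utility * af, NA_real_),
                    pv_costs = ifelse(included, annual_cost * af, NA_real_),
                    included = included)
  attr(out, "n_excluded") <- sum(!included)
  out
}

#' Present values for a whole cohort
#'
#' Convenience wrapper scoring utilities and costs from a cohort data frame
#' and projecting them with [participant_present_values()].
#'
#' @param cohort Cohort data frame.
#' @param value_set CHU9D value set used for scoring.
#' @param schedule Unit-cost schedule used for costing.
#' @param life_table A `life_table`.
#' @param params An [econ_params()].
#' @return Data frame with `id`, `delay_group`, `utility`, `annual_cost`,
#'   present-value columns, and `included`.
#' @export
cohort_present_values <- function(cohort,
                                  value_set = default_chu9d_value_set(),
                                  schedule = default_cost_schedule(),
                                  life_table = default_life_table(),
                                  params = econ_params()) {
  utility <- score_cohort_utilities(cohort, value_set)
  costs <- cohort_costs(cohort, schedule)
  pv <- participant_present_values(cohort$age_survey, cohort$sex,
                                   utility, costs$total, life_table, params)
  out <- cbind(data.frame(id = cohort$id, delay_group = cohort$delay_group,
                          utility = utility, annual_cost = costs$total),
               pv)
  attr(out, "n_excluded") <- attr(pv, "n_excluded")
  out
}
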