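#' Synthetic cohort parameters
#'
#' Calibration targets and design parameters of the synthetic survey-cohort
#' generator. Defaults reproduce the published group structure of the
#' source survey: 163 respondents, 61/163 diagnosed 6+ months after actively
#' seeking treatment, CHU9D utility means 0.59 / 0.44 (SD 0.29), annual
#' government cost means 18,765 / 29,494 AUD (SD 16,416 / 37,034), symptom
#' onset ages 4.4 / 5.7 years (SD 3.8 / 3.6), diagnosis-to-survey gaps
#' 6.3 / 5.1 years, 113/163 female, uveitis prevalence 34/102 vs 6/61, and
#' an 11.4% (21/184) incomplete-CHU9D fraction assigned independently of
#' group.
#'
#' @param n_total Number of participants to generate.
#' @param p_delayed Probability of the 6+ months (delayed) group.
#' @param group_utility_means,utility_sd CHU9D utility calibration targets
#'   `(lt6, ge6plus)`; a single SD applies to both groups.
#' @param group_cost_means,cost_sds Annual cost calibration targets in AUD.
#' @param onset_age_means,onset_age_sds Age at symptom onset, years.
#' @param survey_gap_means,survey_gap_sds Years from diagnosis to survey.
#' @param p_female Probability of female sex (independent of group).
#' @param uveitis_probs Uveitis prevalence `(lt6, ge6plus)`.
#' @param p_incomplete Fraction with incomplete CHU9D (excluded from
#'   utility analyses), assigned independently of group.
#' @param p_safety_net Prevalence of the reported Medicare-Safety-Net flag.
#'   Default 0: the published cost means the generator calibrates to already
#'   embed safety-net effects.
#' @param target_delay_correlation Pearson correlation targeted between the
#'   binned seeking-to-diagnosis delay (bin midpoints) and the
#'   onset-to-diagnosis delay computed from reported ages.
#' @param delay_lag_mean Mean lag (years) from symptom onset to actively
#'   seeking treatment.
#' @param delay_bin_probs Within-group probabilities over the delay bins.
#' @param bin_midpoints_months Midpoints (months) assigned to the delay
#'   bins.
#' @param seed RNG seed; generation is fully reproducible given the seed.
#' @return A `cohort_params` list.
#' @export
cohort_params <- function(n_total = 163,
                          p_delayed = 61 / 163,
                          group_utility_means = c(lt6 = 0.59,
                                                  ge6plus = 0.44),
                          utility_sd = 0.29,
                          group_cost_means = c(lt6 = 18765,
                                               ge6plus = 29494),
                          cost_sds = c(lt6 = 16416, ge6plus = 37034),
                          onset_age_means = c(lt6 = 4.4, ge6plus = 5.7),
                          onset_age_sds = c(lt6 = 3.8, ge6plus = 3.6),
                          survey_gap_means = c(lt6 = 6.3, ge6plus = 5.1),
                          survey_gap_sds = c(lt6 = 4.9, ge6plus = 4.8),
                          p_female = 113 / 163,
                          uveitis_probs = c(lt6 = 34 / 102,
                                            ge6plus = 6 / 61),
                          p_incomplete = 21 / 184,
                          p_safety_net = 0,
                          target_delay_correlation = 0.80,
                          delay_lag_mean = 0.2,
                          delay_bin_probs = list(
                            lt6 = c("<1mo" = 0.25, "1-2mo" = 0.35,
                                    "3-5mo" = 0.40),
                            ge6plus = c("6-8mo" = 0.35, "9-12mo" = 0.25,
                                        "1-2y" = 0.20, "3-4y" = 0.12,
                                        ">5y" = 0.08)),
                          bin_midpoints_months = c("<1mo" = 0.5,
                                                   "1-2mo" = 1.5,
                                                   "3-5mo" = 4,
                                                   "6-8mo" = 7,
                                                   "9-12mo" = 10.5,
                                                   "1-2y" = 18,
                                                   "3-4y" = 42,
                                                   ">5y" = 72),
                          seed = 1L) {
  if (!is.numeric(n_total) || n_total < 2) {
    stop("`n_total` must be at least 2", call. = FALSE)
  }
  assert_prob(c(p_delayed, p_female, p_incomplete, p_safety_net,
                uveitis_probs, target_delay_correlation),
              "probabilities")
  assert_nonneg(c(utility_sd, cost_sds, onset_age_sds, survey_gap_sds),
                "standard deviations")
  assert_nonneg(group_cost_means, "group_cost_means")
  for (g in names(delay_bin_probs)) {
    p <- delay_bin_probs[[g]]
    assert_prob(p, paste0("delay_bin_probs$", g))
    if (abs(sum(p) - 1) > 1e-8) {
      stop("delay_bin_probs$", g, " must sum to 1", call. = FALSE)
    }
  }
  structure(list(n_total = as.integer(n_total), p_delayed = p_delayed,
                 group_utility_means = group_utility_means,
                 utility_sd = utility_sd,
                 group_cost_means = group_cost_means, cost_sds = cost_sds,
                 onset_age_means = onset_age_means,
                 onset_age_sds = onset_age_sds,
                 survey_gap_means = survey_gap_means,
                 survey_gap_sds = survey_gap_sds,
                 p_female = p_female, uveitis_probs = uveitis_probs,
                 p_incomplete = p_incomplete,
                 p_safety_net = p_safety_net,
                 target_delay_correlation = target_delay_correlation,
                 delay_lag_mean = delay_lag_mean,
                 delay_bin_probs = delay_bin_probs,
                 bin_midpoints_months = bin_midpoints_months,
                 seed = as.integer(seed)),
            class = "cohort_params")
}

delay_bin_levels <- c("<1mo", "1-2mo", "3-5mo", "6-8mo", "9-12mo",
                      "1-2y", "3-4y", ">5y")

#' Coarsen an exact age to its survey-reported value
#'
#' Ages were captured in months for children up to 1 year, in half years up
#' to 4 years, and in full years above that; each reported value is the
#' nearest grid point. The rule is idempotent on already-coarsened values.
#'
#' @param age_exact Non-negative age(s) in years.
#' @return Coarsened age(s) in years.
#' @examples
#' coarsen_ages(c(0.71, 3.3, 7.49))
#' @export
coarsen_ages <- function(age_exact) {
  if (any(age_exact < 0)) stop("age must be non-negative", call. = FALSE)
  ifelse(age_exact <= 1, round(age_exact * 12) / 12,
         ifelse(age_exact <= 4, round(age_exact * 2) / 2,
                round(age_exact)))
}

# ---- CHU9D latent-trait ordinal model -------------------------------------
# A participant has latent severity t; on every dimension the response level
# follows a shared-cutpoint logistic ordinal model, P(L > l | t) =
# plogis(t - cut_l). Group trait mean/SD are solved so the scored utility
# matches the configured mean/SD targets.

chu9d_cutpoints <- c(-2.2, -0.8, 0.8, 2.2)

chu9d_level_probs <- function(t) {
  q <- vapply(chu9d_cutpoints, function(cc) plogis(t - cc),
              numeric(length(t)))
  if (length(t) == 1L) q <- matrix(q, nrow = 1)
  cbind(1 - q[, 1], q[, 1] - q[, 2], q[, 2] - q[, 3], q[, 3] - q[, 4],
        q[, 4])
}

# Deterministic quadrature moments of scored utility when the trait is
# N(theta, tau).
chu9d_model_moments <- function(theta, tau, value_set) {
  z <- seq(-8, 8, length.out = 321)
  w <- dnorm(z); w <- w / sum(w)
  P <- chu9d_level_probs(theta + tau * z)            # grid x 5
  W <- value_set$weights                             # 9 x 5
  s <- P %*% t(W)                                    # expected per-dim score
  m <- rowSums(s)
  v_within <- rowSums(P %*% t(W^2) - s^2)
  mean_u <- sum(w * m)
  var_u <- sum(w * (m^2 + v_within)) - mean_u^2
  list(mean = mean_u, sd = sqrt(max(var_u, 0)))
}

calibrate_chu9d <- function(target_mean, target_sd, value_set) {
  lo <- sum(apply(value_set$weights, 1, min))
  hi <- sum(apply(value_set$weights, 1, max))
  if (target_mean <= lo || target_mean >= hi) {
    stop(sprintf("target utility mean %.3f outside attainable (%.3f, %.3f)",
                 target_mean, lo, hi), call. = FALSE)
  }
  theta_for <- function(tau) {
    stats::uniroot(function(th) {
      chu9d_model_moments(th, tau, value_set)$mean - target_mean
    }, c(-30, 30), tol = 1e-9)$root
  }
  g <- function(tau) {
    chu9d_model_moments(theta_for(tau), tau, value_set)$sd - target_sd
  }
  g_lo <- g(0.02); g_hi <- g(25)
  if (g_lo > 0 || g_hi < 0) {
    stop(sprintf("target utility SD %.3f not attainable for mean %.3f",
                 target_sd, target_mean), call. = FALSE)
  }
  tau <- stats::uniroot(g, c(0.02, 25), tol = 1e-8)$root
  list(theta = theta_for(tau), tau = tau)
}

sample_chu9d_levels <- function(n, theta, tau) {
  t_i <- rnorm(n, theta, tau)
  P <- chu9d_level_probs(t_i)
  cum <- t(apply(P, 1, cumsum))[, 1:4, drop = FALSE]
  out <- matrix(1L, n, 9, dimnames = list(NULL, chu9d_columns()))
  for (d in 1:9) {
    u <- runif(n)
    out[, d] <- 1L + (u > cum[, 1]) + (u > cum[, 2]) + (u > cum[, 3]) +
      (u > cum[, 4])
  }
  out
}

# ---- truncated-normal parameter solving -----------------------------------
# Closed-form truncated-normal mean/var on [lower, upper_i] with
# per-observation upper bounds; the realized distribution is a mixture over
# observations.

truncnorm_moments_vec <- function(mu, sigma, lower, upper) {
  k <- max(length(mu), length(sigma), length(lower), length(upper))
  mu <- rep_len(mu, k); sigma <- rep_len(sigma, k)
  a <- rep_len((lower - mu) / sigma, k)
  b <- rep_len((upper - mu) / sigma, k)
  # interval mass on whichever tail preserves relative precision
  Z <- ifelse(a > 0,
              pnorm(a, lower.tail = FALSE) - pnorm(b, lower.tail = FALSE),
              pnorm(b) - pnorm(a))
  da <- dnorm(a); db <- dnorm(b)
  m <- mu + sigma * (da - db) / Z
  # when the interval mass underflows entirely the ratio is indeterminate;
  # the truncated mean is then (numerically) the nearer bound
  bad <- !is.finite(m) | Z < 1e-280
  if (any(bad)) m[bad] <- pmin(pmax(mu, lower), upper)[bad]
  v <- sigma^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
  if (any(bad)) v[bad] <- 0
  v <- pmax(v, 0)
  between <- if (length(m) > 1) stats::var(m) * (length(m) - 1) / length(m)
             else 0
  list(mean = mean(m), var = mean(v) + between)
}

# Beta sampler parameterized by mean/SD on (0, 1).
rbeta_moments <- function(n, m, s) {
  if (m <= 0 || m >= 1) stop("beta mean must lie in (0, 1)", call. = FALSE)
  if (s^2 >= m * (1 - m)) {
    stop(sprintf("SD %.3g not attainable for a beta with mean %.3g", s, m),
         call. = FALSE)
  }
  conc <- m * (1 - m) / s^2 - 1
  rbeta(n, m * conc, (1 - m) * conc)
}

# Solve (mu, sigma) so the realized truncated mixture matches target
# mean/SD. Falls back to matching the mean only (sigma at the nearest
# search boundary) if the SD target is unattainable under the bounds.
solve_truncnorm_params <- function(target_mean, target_sd, lower, upper) {
  mu_for <- function(sg) {
    stats::uniroot(function(mu) {
      truncnorm_moments_vec(mu, sg, lower, upper)$mean - target_mean
    }, target_mean + c(-8, 8) * max(target_sd, 1),
    extendInt = "yes", tol = 1e-8)$root
  }
  g <- function(sg) {
    sqrt(truncnorm_moments_vec(mu_for(sg), sg, lower, upper)$var) - target_sd
  }
  if (target_sd <= 1e-9) return(list(mu = target_mean, sigma = 1e-9))
  sg_lo <- 0.2 * target_sd
  sg_hi <- 6 * target_sd
  v_lo <- g(sg_lo)
  if (v_lo > 0) return(list(mu = mu_for(sg_lo), sigma = sg_lo))
  v_hi <- g(sg_hi)
  while (v_hi < 0 && sg_hi < 20 * target_sd) {
    sg_hi <- sg_hi * 1.8
    v_hi <- g(sg_hi)
  }
  if (v_hi < 0) return(list(mu = mu_for(sg_hi), sigma = sg_hi))
  sg <- stats::uniroot(g, c(sg_lo, sg_hi), tol = 1e-8)$root
  list(mu = mu_for(sg), sigma = sg)
}

# ---- utilization calibration ----------------------------------------------
# Component cost profile: published component means, with professional-visit
# rows rescaled so the group total hits the configured target (reconciling
# the published professional-visit subtotal, which is below the sum of its
# printed component rows). Non-medication components get zero-inflated
# Poisson counts moment-matched so expected cost equals the component mean
# and, after a common dispersion inflation, total cost variance matches the
# configured group SD. Medication classes are Bernoulli use of a drug from
# the class mix at its standard dosing.

calibrate_utilization <- function(params, schedule) {
  ref <- reference_cost_components()
  lapply(c(lt6 = "lt6", ge6plus = "ge6plus"), function(g) {
    suffix <- if (g == "lt6") "lt6" else "ge6"
    means <- ref[[paste0("mean_", suffix)]]
    sds <- ref[[paste0("sd_", suffix)]]
    names(means) <- names(sds) <- ref$component
    target_total <- unname(params$group_cost_means[[g]])
    target_sd <- unname(params$cost_sds[[g]])

    prof <- ref$category == "professional_visit"
    med <- ref$category == "medication"
    resid <- target_total - sum(means[!prof & !med]) - sum(means[med])
    fac <- resid / sum(means[prof])
    if (is.finite(fac) && fac > 0.3 && fac < 3) {
      means[prof] <- means[prof] * fac
      sds[prof] <- sds[prof] * fac
    } else {
      sc <- target_total / sum(means)
      means <- means * sc
      sds <- sds * sc
    }

    # medication classes: Bernoulli(prevalence) x drug mix at standard dose
    drugs <- schedule$drugs
    class_map <- c(csDMARDS = "csDMARD", bDMARDS = "bDMARD",
                   tsDMARDS = "tsDMARD",
                   oral_corticosteroid = "oral_corticosteroid")
    med_cal <- lapply(names(class_map), function(row_label) {
      sub <- drugs[drugs$class == class_map[[row_label]], ]
      wmix <- sub$mix_weight / sum(sub$mix_weight)
      cost <- regimen_annual_cost(sub$drug, sub$dose_mg, schedule)
      ec <- sum(wmix * cost); ec2 <- sum(wmix * cost^2)
      prev <- min(1, means[[row_label]] / ec)
      list(row = row_label, drugs = sub$drug, mix = wmix, cost = cost,
           prevalence = prev,
           var = prev * ec2 - (prev * ec)^2)
    })
    var_med <- sum(vapply(med_cal, `[[`, numeric(1), "var"))

    nonmed <- ref$component[!med]
    s2 <- sum(sds[nonmed]^2)
    f <- sqrt(max(target_sd^2 - var_med, 0) / s2)

    unit <- setNames(schedule$items$unit_cost, schedule$items$item)
    item_of <- setNames(ref$item, ref$component)

    zip_for <- function(comp, mean_cost) {
      cu <- unit[[item_of[[comp]]]]
      mu <- mean_cost / cu
      if (mu <= 0) return(list(item = item_of[[comp]], pi = 0, lambda = 0))
      v <- max((f * sds[[comp]] / cu)^2, mu)
      k <- v / mu - 1
      if (k <= 1e-9) return(list(item = item_of[[comp]], pi = 1,
                                 lambda = mu))
      list(item = item_of[[comp]], pi = mu / (mu + k), lambda = mu + k)
    }

    other <- setdiff(nonmed, "primary_care")
    zips <- lapply(other, function(cmp) zip_for(cmp, means[[cmp]]))
    names(zips) <- other

    # expected care-plan cost (tied to allied-health use) is netted out of
    # the primary-care target so the group mean stays on target
    al <- zips[["allied_health"]]
    p_allied <- al$pi * (1 - exp(-al$lambda))
    cp_cost <- unit[["care_plan"]] %||% 0
    pc_target <- max(means[["primary_care"]] - cp_cost * p_allied, 0)
    zips[["primary_care"]] <- zip_for("primary_care", pc_target)

    list(zips = zips, med = med_cal, dispersion = f)
  })
}

sample_counts <- function(n, zip) {
  rbinom(n, 1, zip$pi) * rpois(n, zip$lambda)
}

# ---- generator ------------------------------------------------------------

#' Generate a synthetic survey cohort
#'
#' Draws a seeded synthetic cohort with the published group structure:
#' delay-group sizes binomial in `p_delayed`; within-group ages from
#' truncated normals whose parameters are solved so realized moments match
#' the configured targets; CHU9D level profiles from a latent-trait ordinal
#' model calibrated so scored utility (under `value_set`) matches the group
#' utility mean/SD; utilization counts from moment-matched zero-inflated
#' Poisson draws so costed annual totals (under `schedule`) match the group
#' cost mean/SD; and a configurable fraction with incomplete CHU9D.
#'
#' @param params A [cohort_params()] object.
#' @param value_set CHU9D value set the utility calibration is solved
#'   against.
#' @param schedule Unit-cost schedule the cost calibration is solved
#'   against.
#' @return A `jia_cohort` data frame, one row per participant, with the
#'   generating parameters attached as attribute `params`.
#' @export
generate_cohort <- function(params = cohort_params(),
                            value_set = default_chu9d_value_set(),
                            schedule = default_cost_schedule()) {
  stopifnot(inherits(params, "cohort_params"))
  with_seed(params$seed, {
    n <- params$n_total
    delayed <- rbinom(n, 1, params$p_delayed) == 1
    if (n >= 10 && params$p_delayed > 0 && params$p_delayed < 1) {
      if (!any(delayed)) delayed[sample.int(n, 1)] <- TRUE
      if (all(delayed)) delayed[sample.int(n, 1)] <- FALSE
    }
    group <- ifelse(delayed, "ge6plus", "lt6")

    mids_y <- params$bin_midpoints_months / 12

    # delay bins and the exact onset-to-diagnosis delay, with noise solved
    # so the reported-age delay correlates with the bin midpoints at the
    # configured Pearson target (approximate correction for age coarsening)
    bin <- character(n)
    for (g in c("lt6", "ge6plus")) {
      pb <- params$delay_bin_probs[[g]]
      idx <- which(group == g)
      if (length(idx)) {
        bin[idx] <- sample(names(pb), length(idx), TRUE, prob = pb)
      }
    }
    mid <- mids_y[bin]

    pmix <- c(1 - params$p_delayed, params$p_delayed)
    probs_all <- c(params$delay_bin_probs$lt6 * pmix[1],
                   params$delay_bin_probs$ge6plus * pmix[2])
    mids_all <- mids_y[names(probs_all)]
    e_mid <- sum(probs_all * mids_all)
    var_mid <- sum(probs_all * mids_all^2) - e_mid^2
    r <- params$target_delay_correlation
    if (r <= 0 || r >= 1) {
      sigma_noise <- if (r >= 1) 1e-4 else 1e6
    } else {
      coarse_var <- function(mu, sd, shift) {
        p1 <- pnorm(1, mu + shift, sd)
        p4 <- pnorm(4, mu + shift, sd)
        p1 * (1 / 12)^2 / 12 + (p4 - p1) * 0.5^2 / 12 + (1 - p4) / 12
      }
      vc <- sum(vapply(c(1, 2), function(i) {
        g <- c("lt6", "ge6plus")[i]
        e_delay <- sum(params$delay_bin_probs[[g]] *
                         mids_y[names(params$delay_bin_probs[[g]])]) +
          params$delay_lag_mean
        pmix[i] * (coarse_var(params$onset_age_means[[g]],
                              params$onset_age_sds[[g]], 0) +
                     coarse_var(params$onset_age_means[[g]],
                                params$onset_age_sds[[g]], e_delay))
      }, numeric(1)))
      sigma_noise <- sqrt(max(var_mid * (1 / r^2 - 1) - vc, 1e-4))
    }
    # gamma-distributed onset-to-seeking lag: positive support, so the
    # solved noise variance is realized without truncation distortion
    lag <- max(params$delay_lag_mean, 1e-3)
    if (sigma_noise < 1e-5) {
      eps <- rep(lag, n)
    } else {
      eps <- rgamma(n, shape = lag^2 / sigma_noise^2,
                    scale = sigma_noise^2 / lag)
    }
    delay_exact <- pmin(mid + eps, 15)

    # ages: onset from a scaled beta on [0, 16) matched exactly to the
    # target mean/SD (the truncated-normal family cannot reach the printed
    # onset SD on this support); diagnosis-to-survey gap from a truncated
    # normal whose parameters are solved against the realized
    # per-participant bounds so the printed moments are recovered
    onset <- numeric(n); gap <- numeric(n)
    for (g in c("lt6", "ge6plus")) {
      idx <- which(group == g)
      if (!length(idx)) next
      # cap just below 15.5 so the coarsened (nearest-year) reported onset
      # stays strictly below 16
      onset[idx] <- pmin(16 * rbeta_moments(length(idx),
                                            params$onset_age_means[[g]] / 16,
                                            params$onset_age_sds[[g]] / 16),
                         15.49)
      up_gap <- pmax(25 - (onset[idx] + delay_exact[idx]), 0.1)
      solg <- solve_truncnorm_params(params$survey_gap_means[[g]],
                                     params$survey_gap_sds[[g]],
                                     0, up_gap)
      gap[idx] <- rtrunc_norm(length(idx), solg$mu, solg$sigma, 0, up_gap)
    }
    dx_exact <- onset + delay_exact
    survey_exact <- dx_exact + gap

    age_onset <- coarsen_ages(onset)
    age_dx <- pmax(coarsen_ages(dx_exact), age_onset)
    age_survey <- pmax(coarsen_ages(survey_exact), age_dx)

    sex <- ifelse(runif(n) < params$p_female, "female", "male")
    uveitis <- runif(n) < unname(params$uveitis_probs[
      ifelse(delayed, "ge6plus", "lt6")])
    complete <- runif(n) >= params$p_incomplete
    safety_net <- runif(n) < params$p_safety_net

    # CHU9D levels
    chu <- matrix(NA_integer_, n, 9, dimnames = list(NULL, chu9d_columns()))
    for (g in c("lt6", "ge6plus")) {
      idx <- which(group == g)
      if (!length(idx)) next
      cal <- calibrate_chu9d(params$group_utility_means[[g]],
                             params$utility_sd, value_set)
      chu[idx, ] <- sample_chu9d_levels(length(idx), cal$theta, cal$tau)
    }
    chu[!complete, ] <- NA_integer_

    # utilization
    ucal <- calibrate_utilization(params, schedule)
    count_items <- unique(stats::na.omit(reference_cost_components()$item))
    counts <- matrix(0L, n, length(count_items),
                     dimnames = list(NULL, paste0("n_", count_items)))
    meds <- data.frame(med_csdmard = rep(NA_character_, n),
                       med_bdmard = NA_character_,
                       med_tsdmard = NA_character_,
                       med_steroid = NA_character_)
    med_col <- c(csDMARDS = "med_csdmard", bDMARDS = "med_bdmard",
                 tsDMARDS = "med_tsdmard",
                 oral_corticosteroid = "med_steroid")
    for (g in c("lt6", "ge6plus")) {
      idx <- which(group == g)
      if (!length(idx)) next
      cal <- ucal[[g]]
      for (zp in cal$zips) {
        counts[idx, paste0("n_", zp$item)] <- sample_counts(length(idx), zp)
      }
      for (mc in cal$med) {
        on <- runif(length(idx)) < mc$prevalence
        if (any(on)) {
          meds[idx[on], med_col[[mc$row]]] <-
            sample(mc$drugs, sum(on), TRUE, prob = mc$mix)
        }
      }
    }
    care_plan <- counts[, "n_allied_health"] > 0

    out <- data.frame(
      id = sprintf("P%05d", seq_len(n)),
      delay_group = factor(group, levels = c("lt6", "ge6plus")),
      delay_category = factor(bin, levels = delay_bin_levels),
      delay_seek_years = unname(mid),
      delay_onset_dx_years = age_dx - age_onset,
      delay_onset_dx_exact = delay_exact,
      sex = factor(sex, levels = c("female", "male")),
      age_onset = age_onset, age_diagnosis = age_dx,
      age_survey = age_survey,
      age_onset_exact = onset, age_diagnosis_exact = dx_exact,
      age_survey_exact = survey_exact,
      uveitis = uveitis, chu9d_complete = complete,
      safety_net_reached = safety_net, care_plan = unname(care_plan)
    )
    out <- cbind(out, as.data.frame(chu), meds)
    out <- cbind(out, as.data.frame(counts))
    attr(out, "params") <- params
    attr(out, "delay_noise_sd") <- sigma_noise
    attr(out, "delay_midpoint_var") <- var_mid
    class(out) <- c("jia_cohort", "data.frame")
    out
  })
}

#' @export
print.jia_cohort <- function(x, ...) {
  cat("Synthetic JIA survey cohort:", nrow(x), "participants (",
      sum(x$delay_group == "lt6"), "diagnosed <6 months,",
      sum(x$delay_group == "ge6plus"), "6+ months;",
      sum(x$chu9d_complete), "with complete CHU9D )\n")
  invisible(x)
}

#' Compare realized cohort moments against calibration targets
#'
#' Reports realized group means/SDs for scored utility, annual cost, onset
#' age and diagnosis-to-survey gap against the generator's targets, flagging
#' any moment further than 3 standard errors from its target. Standard
#' errors of SDs use the fourth-moment formula, which matters for the
#' heavy-tailed cost distribution.
#'
#' @param cohort A cohort data frame.
#' @param params The [cohort_params()] targets (defaults to those attached
#'   to the cohort).
#' @param value_set,schedule Scoring and costing inputs.
#' @return Data frame with columns `group`, `quantity`, `target`,
#'   `realized`, `se`, `flag`.
#' @export
calibration_report <- function(cohort, params = attr(cohort, "params"),
                               value_set = default_chu9d_value_set(),
                               schedule = default_cost_schedule()) {
  if (is.null(cohort) || nrow(cohort) == 0) {
    stop("cohort must be nonempty", call. = FALSE)
  }
  if (is.null(params)) stop("no cohort_params supplied", call. = FALSE)
  utility <- score_cohort_utilities(cohort, value_set)
  total_cost <- cohort_costs(cohort, schedule)$total
  gap <- cohort$age_survey_exact - cohort$age_diagnosis_exact

  se_mean <- function(x) stats::sd(x) / sqrt(length(x))
  se_sd <- function(x) {
    m4 <- mean((x - mean(x))^4)
    s <- stats::sd(x)
    sqrt(max(m4 - s^4, 0) / (4 * s^2 * length(x)))
  }
  rows <- list()
  for (g in c("lt6", "ge6plus")) {
    sel <- cohort$delay_group == g
    u <- utility[sel & !is.na(utility)]
    co <- total_cost[sel]
    on <- cohort$age_onset_exact[sel]
    gp <- gap[sel]
    add <- function(qty, target, x, kind = "mean") {
      val <- if (kind == "mean") mean(x) else stats::sd(x)
      se <- if (kind == "mean") se_mean(x) else se_sd(x)
      rows[[length(rows) + 1]] <<- data.frame(
        group = g, quantity = qty, target = target, realized = val,
        se = se, flag = abs(val - target) > 3 * se)
    }
    add("utility_mean", params$group_utility_means[[g]], u)
    add("utility_sd", params$utility_sd, u, "sd")
    add("cost_mean", params$group_cost_means[[g]], co)
    add("cost_sd", params$cost_sds[[g]], co, "sd")
    add("onset_age_mean", params$onset_age_means[[g]], on)
    add("onset_age_sd", params$onset_age_sds[[g]], on, "sd")
    add("survey_gap_mean", params$survey_gap_means[[g]], gp)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a cohort as CSV
#'
#' The cohort is written as plain CSV (one row per participant, CHU9D levels
#' as nine integer columns) with the seed and generation parameters recorded
#' in an adjacent `<path>.meta` text file.
#'
#' @param cohort A cohort data frame.
#' @param path CSV file path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   quote = FALSE)
  params <- attr(cohort, "params")
  meta <- c(sprintf("n_total: %d", nrow(cohort)),
            if (!is.null(params)) sprintf("seed: %d", params$seed),
            if (!is.null(params)) sprintf("p_delayed: %.8g",
                                          params$p_delayed))
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$delay_group <- factor(out$delay_group, levels = c("lt6", "ge6plus"))
  out$delay_category <- factor(out$delay_category,
                               levels = delay_bin_levels)
  out$sex <- factor(out$sex, levels = c("female", "male"))
  for (col in names(out)[startsWith(names(out), "med_")]) {
    out[[col]][out[[col]] == ""] <- NA_character_
  }
  class(out) <- c("jia_cohort", "data.frame")
  out
}
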