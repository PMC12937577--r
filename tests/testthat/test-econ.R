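test_that("incremental means match a from-scratch Welch oracle", {
  x <- c(1.2, 3.4, 2.2)
  y <- c(4.1, 0.3, 5.5)
  got <- incremental_mean(x, y)
  want <- welch_oracle(x, y)
  expect_equal(got$difference, want$diff, tolerance = 1e-9)
  expect_equal(got$p_value, want$p, tolerance = 1e-9)
  expect_equal(c(got$ci_low, got$ci_high), want$ci, tolerance = 1e-9)
  # published group means give the published annual cost difference
  set.seed(71)
  a <- rnorm(102); a <- (a - mean(a)) / sd(a) * 16416 + 18765
  b <- rnorm(61); b <- (b - mean(b)) / sd(b) * 37034 + 29494
  res <- incremental_mean(a, b, sign = "ge6_minus_lt6")
  expect_equal(res$difference, 10729, tolerance = 1e-9)
  expect_true(res$ci_low <= res$difference &
                res$difference <= res$ci_high)
  # identical groups: zero difference, p = 1
  same <- incremental_mean(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$difference, 0)
  expect_equal(same$p_value, 1)
  expect_error(incremental_mean(1, c(1, 2)), "at least 2")
})

test_that("welch_from_summary agrees with t.test on raw data", {
  set.seed(72)
  x <- rnorm(40, 3, 2); y <- rnorm(25, 4, 1)
  tt <- t.test(x, y)
  ws <- welch_from_summary(mean(x), sd(x), length(x),
                           mean(y), sd(y), length(y))
  expect_equal(ws$p_value, tt$p.value, tolerance = 1e-12)
  expect_equal(ws$df, unname(tt$parameter), tolerance = 1e-9)
  expect_equal(c(ws$ci_low, ws$ci_high), as.numeric(tt$conf.int),
               tolerance = 1e-9)
})

test_that("adjusted differences behave under known truth", {
  co <- big_cohort()
  u <- score_cohort_utilities(co)
  adj <- adjusted_difference(co, u)
  unadj <- incremental_mean(u[co$delay_group == "lt6"],
                            u[co$delay_group == "ge6plus"])
  # covariates carry no true effect, so adjusted ~ unadjusted, and both
  # recover the configured 0.15 utility difference
  se <- (adj$ci_high - adj$ci_low) / (2 * 1.96)
  expect_lt(abs(adj$difference - unadj$difference), 3 * se)
  expect_lt(abs(adj$difference - 0.15), 3 * se)
  expect_true(is.finite(adj$interaction_lrt_p))
  # pure-noise outcome: group effect compatible with zero
  set.seed(73)
  noise <- rnorm(nrow(co))
  adj0 <- adjusted_difference(co, noise)
  se0 <- (adj0$ci_high - adj0$ci_low) / (2 * 1.96)
  expect_lt(abs(adj0$difference), 4 * se0)
  # rank deficiency is reported with the collinear column
  co1 <- co[1:300, ]
  co1$sex <- factor(ifelse(co1$delay_group == "lt6", "female", "male"),
                    levels = c("female", "male"))
  expect_error(adjusted_difference(co1, u[1:300]), "collinear")
})

test_that("net monetary benefit satisfies its algebraic identity", {
  set.seed(74)
  for (i in 1:20) {
    n <- 60
    pv <- data.frame(
      delay_group = rep(c("lt6", "ge6plus"), each = n / 2),
      pv_qalys = runif(n, 2, 16),
      pv_costs = runif(n, 1e4, 8e5),
      included = TRUE)
    wtp <- runif(1, 0, 1e5)
    p <- econ_params(wtp_per_qaly = wtp)
    res <- incremental_nmb(pv, p)
    expect_lt(abs(res$aud$difference -
                    (wtp * res$qalys$difference +
                       res$cost_savings$difference)), 1e-9)
    expect_equal(res$usd$difference, res$aud$difference / 1.51,
                 tolerance = 1e-12)
  }
  # wtp = 0 reduces NMB to pure cost savings
  pv <- data.frame(delay_group = rep(c("lt6", "ge6plus"), each = 10),
                   pv_qalys = runif(20), pv_costs = runif(20, 1, 9),
                   included = TRUE)
  r0 <- incremental_nmb(pv, econ_params(wtp_per_qaly = 0))
  expect_equal(r0$aud$difference, r0$cost_savings$difference)
})

test_that("published USD conversion is reproduced", {
  expect_equal(round(aud_to_usd(349520, 1.51)), 231470)
  expect_error(aud_to_usd(100, 0), "positive")
})

test_that("CEA plane bootstrap is seeded and centred on the estimate", {
  co <- big_cohort()
  pv <- cohort_present_values(co)
  cp <- cea_plane(pv, n_boot = 400, seed = 5)
  # analytic point estimate equals the incremental means
  nmb <- incremental_nmb(pv)
  expect_equal(unname(cp$point_estimate["delta_qalys"]),
               nmb$qalys$difference)
  expect_equal(unname(cp$point_estimate["delta_costs"]),
               -nmb$cost_savings$difference)
  # both published CIs exclude zero, so the cloud concentrates in the
  # QALY-gaining, cost-saving quadrant
  expect_gte(cp$quadrants[["gain_saving"]], 0.95)
  expect_identical(cea_plane(pv, n_boot = 50, seed = 9)$points,
                   cea_plane(pv, n_boot = 50, seed = 9)$points)
  # identical groups centre the cloud at the origin
  pv2 <- data.frame(delay_group = rep(c("lt6", "ge6plus"), 50),
                    pv_qalys = rep(runif(50, 5, 10), each = 2),
                    pv_costs = rep(runif(50, 1e4, 1e5), each = 2),
                    included = TRUE)
  cp2 <- cea_plane(pv2, n_boot = 300, seed = 1)
  expect_lt(abs(mean(cp2$points$delta_qalys)),
            3 * sd(pv2$pv_qalys) / sqrt(50))
  pv1 <- pv2[1:3, ]
  expect_error(cea_plane(pv1, 10, 1), "at least 2")
})

test_that("one-way sensitivity recomputes the pipeline per scenario", {
  co <- small_cohort(n = 800, seed = 12)
  sens <- one_way_sensitivity(co)
  base <- sens[sens$label == "base case", ]
  pv <- cohort_present_values(co)
  nmb <- incremental_nmb(pv)
  expect_equal(base$nmb, nmb$aud$difference)
  # exact linearity in willingness to pay
  w30 <- sens[sens$label == "WTP 30,000/QALY", ]
  w70 <- sens[sens$label == "WTP 70,000/QALY", ]
  expect_equal(w70$nmb - w30$nmb, 40000 * base$delta_qalys,
               tolerance = 1e-9)
  # monotone decreasing in the discount rate
  d3 <- sens$nmb[sens$label == "discount rate 3%"]
  d7 <- sens$nmb[sens$label == "discount rate 7%"]
  expect_true(d3 > base$nmb && base$nmb > d7)
  # the exclusion scenario drops exactly the matching records
  excl <- sens[grepl("exclude", sens$label), ]
  gap <- co$age_survey - co$age_diagnosis
  expect_equal(excl$n_lt6 + excl$n_ge6,
               base$n_lt6 + base$n_ge6 -
                 sum(gap < 1 & !is.na(score_cohort_utilities(co))))
  expect_error(one_way_sensitivity(co, list(list(label = "x",
                                                 nonsense = 1))),
               "undefined parameter")
})

test_that("budget impact reproduces the published worked example", {
  bi <- budget_impact(prop_delayed = 61 / 163, nmb_per_child = 349520,
                      incident_children = 358)
  expect_equal(bi$affected_children, 134)
  expect_equal(round(bi$total_benefit_forgone / 1e6), 47)
  # the formula itself gives 357 incident children from 5.1M at 7/100k
  bi2 <- budget_impact(5.1e6, 7, 0.37, 349520)
  expect_equal(bi2$incident_children, 357)
  bi0 <- budget_impact(5.1e6, 7, 0, 349520)
  expect_equal(bi0$affected_children, 0)
  expect_equal(bi0$total_benefit_forgone, 0)
})
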