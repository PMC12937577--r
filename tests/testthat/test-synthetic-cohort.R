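test_that("age coarsening follows the capture rule and is idempotent", {
  # 0.71 y = 8.52 months -> nearest month (9) = 0.75 y
  expect_equal(coarsen_ages(0.71), 9 / 12)
  expect_equal(coarsen_ages(3.3), 3.5)
  expect_equal(coarsen_ages(7.49), 7)
  expect_equal(coarsen_ages(4.6), 5)
  set.seed(41)
  x <- runif(500, 0, 30)
  expect_equal(coarsen_ages(coarsen_ages(x)), coarsen_ages(x))
  expect_error(coarsen_ages(-0.1), "non-negative")
})

test_that("generation is deterministic and file round trips are faithful", {
  p <- cohort_params(n_total = 163, seed = 1)
  a <- generate_cohort(p)
  b <- generate_cohort(p)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(nrow(a), 163)
  # group split near the published 102/61
  expect_lt(abs(sum(a$delay_group == "ge6plus") - 61), 20)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(a, f1); write_cohort(b, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_true(file.exists(paste0(f1, ".meta")))
  rt <- read_cohort(f1)
  expect_equal(rt$age_survey, a$age_survey)
  expect_equal(as.character(rt$delay_category),
               as.character(a$delay_category))
  expect_equal(rt$med_bdmard, a$med_bdmard)
})

test_that("degenerate and invalid parameters behave as specified", {
  all_fast <- generate_cohort(cohort_params(n_total = 50, p_delayed = 0,
                                            seed = 2))
  expect_true(all(all_fast$delay_group == "lt6"))
  expect_error(cohort_params(p_delayed = 1.2), "probability")
  expect_error(cohort_params(utility_sd = -1), "non-negative")
  expect_error(cohort_params(n_total = 1), "at least 2")
  # both groups occupied whenever feasible and n is not tiny
  co <- generate_cohort(cohort_params(n_total = 12, p_delayed = 0.02,
                                      seed = 3))
  expect_true(all(c("lt6", "ge6plus") %in% co$delay_group))
})

test_that("generated records satisfy the participant invariants", {
  set.seed(51)
  grids <- list(
    cohort_params(n_total = 300, seed = 101),
    cohort_params(n_total = 300, seed = 102, p_delayed = 0.7,
                  group_utility_means = c(lt6 = 0.7, ge6plus = 0.3),
                  utility_sd = 0.2),
    cohort_params(n_total = 300, seed = 103,
                  group_cost_means = c(lt6 = 9000, ge6plus = 40000),
                  onset_age_means = c(lt6 = 3, ge6plus = 8)),
    cohort_params(n_total = 300, seed = 104, p_incomplete = 0.5,
                  p_safety_net = 0.3)
  )
  lt6_bins <- c("<1mo", "1-2mo", "3-5mo")
  for (p in grids) {
    co <- generate_cohort(p)
    expect_true(all(co$age_onset <= co$age_diagnosis))
    expect_true(all(co$age_diagnosis <= co$age_survey))
    expect_true(all(co$age_onset < 16))
    expect_true(all(co$age_survey <= 25))
    expect_true(all((co$delay_category %in% lt6_bins) ==
                      (co$delay_group == "lt6")))
    lv <- as.matrix(co[, paste0("chu9d_", chu9d_dimensions)])
    comp <- co$chu9d_complete
    expect_true(all(lv[comp, ] %in% 1:5))
    expect_true(all(is.na(lv[!comp, ])))
    cnt <- as.matrix(co[, grep("^n_", names(co))])
    expect_true(all(cnt >= 0 & cnt == round(cnt)))
  }
})

test_that("calibration report matches targets at large n and flags misses", {
  co <- big_cohort()
  rep_ <- calibration_report(co)
  expect_false(any(rep_$flag))
  # deliberately mis-set target raises a flag
  bad <- attr(co, "params")
  bad$group_utility_means[["lt6"]] <- 0.9
  rep_bad <- calibration_report(co, bad)
  expect_true(rep_bad$flag[rep_bad$group == "lt6" &
                             rep_bad$quantity == "utility_mean"])
  expect_error(calibration_report(co[0, ], attr(co, "params")), "nonempty")
})

test_that("incomplete-CHU9D fraction follows its parameter", {
  co <- big_cohort()
  p <- 21 / 184
  phat <- mean(!co$chu9d_complete)
  expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / nrow(co)))
  # independence of group: proportions similar across groups
  tab <- table(co$delay_group, co$chu9d_complete)
  expect_gt(chisq.test(tab)$p.value, 0.001)
})

test_that("delay measures correlate at the configured level", {
  co <- big_cohort()
  cc <- time_measure_concordance(co)
  expect_lt(abs(cc$r - 0.80), 0.025)
  # exact (pre-coarsening) delays match the analytic attenuation
  vm <- attr(co, "delay_midpoint_var")
  sn <- attr(co, "delay_noise_sd")
  ce <- time_measure_concordance(co, measure = "exact")
  expect_lt(abs(ce$r - sqrt(vm / (vm + sn^2))), 0.02)
  # null behaviour of the estimator: permuted midpoints decorrelate
  set.seed(61)
  shuffled <- co
  shuffled$delay_seek_years <- sample(co$delay_seek_years)
  c0 <- time_measure_concordance(shuffled)
  expect_lt(abs(c0$r), 3 / sqrt(nrow(co)))
  const <- co
  const$delay_seek_years <- 1
  expect_error(time_measure_concordance(const), "zero variance")
})
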