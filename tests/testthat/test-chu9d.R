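test_that("default value set reproduces the published dimension ranges", {
  vs <- default_chu9d_value_set()
  best <- apply(vs$weights, 1, max)
  worst <- apply(vs$weights, 1, min)
  expect_equal(unname(best),
               c(0.22, 0.15, 0.11, 0.11, 0.08, 0.09, 0.06, 0.07, 0.13))
  expect_equal(unname(worst),
               c(0.11, 0.02, -0.02, 0.03, -0.04, -0.02, -0.05, -0.05, 0.02))
  # additivity makes per-dimension extremes global extremes
  expect_equal(sum(worst), 0.00)
  expect_equal(sum(best), 1.02)
  # weakly decreasing in level for every dimension
  expect_true(all(apply(vs$weights, 1, function(r) all(diff(r) <= 0))))
})

test_that("utility scoring is additive, deterministic and handles missing", {
  vs <- default_chu9d_value_set()
  worst <- setNames(rep(5L, 9), chu9d_dimensions)
  best <- setNames(rep(1L, 9), chu9d_dimensions)
  expect_equal(score_utility(worst, vs), 0.00)
  expect_equal(score_utility(best, vs), 1.02)
  # changing exactly one dimension moves utility by that weight delta
  set.seed(11)
  r1 <- setNames(sample(1:5, 9, TRUE), chu9d_dimensions)
  for (d in chu9d_dimensions) {
    r2 <- r1
    r2[d] <- if (r1[d] == 5) 1L else r1[d] + 1L
    expect_equal(score_utility(r2, vs) - score_utility(r1, vs),
                 vs$weights[d, r2[d]] - vs$weights[d, r1[d]])
  }
  # order of named dimensions does not matter
  shuffled <- r1[sample(names(r1))]
  expect_identical(score_utility(shuffled, vs), score_utility(r1, vs))
  # worsening any single dimension never increases utility
  for (d in chu9d_dimensions) {
    r2 <- r1
    if (r1[d] < 5) {
      r2[d] <- r1[d] + 1L
      expect_lte(score_utility(r2, vs), score_utility(r1, vs))
    }
  }
  # incomplete responses yield NA, never zero
  r3 <- r1
  r3["pain"] <- NA
  expect_true(is.na(score_utility(r3, vs)))
  expect_equal(score_utility(r1, zero_value_set()), 0)
  # matrix interface agrees with the vector interface
  m <- rbind(as.data.frame(t(r1)), as.data.frame(t(worst)))
  expect_equal(score_utility(m, vs),
               c(score_utility(r1, vs), 0.00))
})

test_that("dimension_score returns the published endpoint weights", {
  vs <- default_chu9d_value_set()
  r <- setNames(c(1L, rep(3L, 8)), chu9d_dimensions)
  expect_equal(dimension_score(r, "worry", vs), 0.22)
  r2 <- setNames(rep(1L, 9), chu9d_dimensions)
  expect_equal(dimension_score(r2, "pain", vs), 0.11)
  r3 <- setNames(rep(5L, 9), chu9d_dimensions)
  expect_equal(dimension_score(r3, "sleep", vs), -0.05)
  expect_equal(dimension_score(r3, "sleep", zero_value_set()), 0)
  expect_error(dimension_score(r3, "mood", vs), "unknown")
})

test_that("value-set loading validates shape and monotonicity", {
  tab <- value_set_table(default_chu9d_value_set())
  vs <- load_value_set(tab)
  expect_equal(vs$weights, default_chu9d_value_set()$weights)
  expect_error(load_value_set(tab[!(tab$dimension == "pain" &
                                      tab$level == 3), ]),
               "pain, level 3")
  bad <- tab
  bad$weight[bad$dimension == "worry" & bad$level == 2] <- 0.5
  expect_error(load_value_set(bad), "non-monotone")
  expect_s3_class(load_value_set(bad, allow_non_monotone = TRUE),
                  "chu9d_value_set")
  expect_error(load_value_set(tab[-1, ]), "missing cell")
})

test_that("responses are validated", {
  expect_error(chu9d_response(setNames(rep(1, 8), chu9d_dimensions[-1])),
               "nine")
  expect_error(chu9d_response(setNames(c(rep(1, 8), 6), chu9d_dimensions)),
               "1..5")
})

test_that("dimension_summary handles identical and degenerate groups", {
  co <- manual_cohort(8, rep(c("lt6", "ge6plus"), each = 4))
  # identical groups with within-group variation
  for (d in paste0("chu9d_", chu9d_dimensions)) {
    co[[d]] <- rep(c(1L, 2L, 3L, 4L), 2)
  }
  s <- dimension_summary(co)
  expect_equal(s$difference, rep(0, 10))
  expect_equal(s$p_value, rep(1, 10))
  # single-participant groups: means reported, p missing
  co1 <- manual_cohort(2, c("lt6", "ge6plus"), chu_level = 2)
  s1 <- dimension_summary(co1)
  expect_true(all(is.na(s1$p_value)))
  expect_false(anyNA(s1$mean_lt6))
})

test_that("cohort utilities recover the calibrated group means", {
  co <- big_cohort()
  u <- score_cohort_utilities(co)
  s <- dimension_summary(co)
  ov <- s[s$dimension == "overall", ]
  for (g in c("lt6", "ge6plus")) {
    target <- c(lt6 = 0.59, ge6plus = 0.44)[[g]]
    x <- u[co$delay_group == g & !is.na(u)]
    expect_lt(abs(mean(x) - target), 3 * sd(x) / sqrt(length(x)))
  }
  expect_equal(ov$mean_lt6, mean(u[co$delay_group == "lt6" & !is.na(u)]))
  # overall row equals the sum of dimension rows (additivity)
  expect_equal(sum(s$mean_lt6[s$dimension != "overall"]), ov$mean_lt6)
})
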