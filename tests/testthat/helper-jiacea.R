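# shared fixtures; the large calibrated cohort is generated once per run
.fixture_env <- new.env(parent = emptyenv())

big_cohort <- function() {
  if (is.null(.fixture_env$big)) {
    .fixture_env$big <- generate_cohort(cohort_params(n_total = 10000,
                                                      seed = 42))
  }
  .fixture_env$big
}

small_cohort <- function(n = 400, seed = 7, ...) {
  generate_cohort(cohort_params(n_total = n, seed = seed, ...))
}

# a degenerate value set scoring every state 0
zero_value_set <- function() {
  load_value_set(data.frame(dimension = rep(chu9d_dimensions, 5),
                            level = rep(1:5, each = 9),
                            weight = 0),
                 name = "zero")
}

# minimal cohort data frame built by hand (no generator) for unit tests
manual_cohort <- function(n, delay_group, chu_level = 1, seed = 1) {
  chu <- matrix(as.integer(chu_level), n, 9,
                dimnames = list(NULL, paste0("chu9d_", chu9d_dimensions)))
  out <- data.frame(id = sprintf("M%03d", seq_len(n)),
                    delay_group = factor(delay_group,
                                         levels = c("lt6", "ge6plus")),
                    sex = factor(rep_len(c("female", "male"), n),
                                 levels = c("female", "male")),
                    age_survey = rep_len(c(8, 10, 12, 14), n),
                    chu9d_complete = TRUE)
  cbind(out, as.data.frame(chu))
}

# independent Welch oracle written directly from the textbook formulas
welch_oracle <- function(x, y, conf = 0.95) {
  v1 <- var(x) / length(x); v2 <- var(y) / length(y)
  se <- sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  t <- (mean(x) - mean(y)) / se
  q <- qt(1 - (1 - conf) / 2, df)
  list(diff = mean(x) - mean(y), p = 2 * pt(-abs(t), df),
       ci = mean(x) - mean(y) + c(-q, q) * se)
}
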