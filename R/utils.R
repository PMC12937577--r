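`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
assert_prob <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must be a probability in [0, 1]", what), call. = FALSE)
  }
  invisible(x)
}

#' @keywords internal
assert_nonneg <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0)) {
    stop(sprintf("`%s` must be non-negative", what), call. = FALSE)
  }
  invisible(x)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so library code never perturbs the user's random stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Truncated-normal sampler by inverse-CDF; `lower`/`upper` may be vectors.
# Works on whichever tail holds less mass so far-tail truncation (tiny
# interval probabilities) keeps full floating-point precision.
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (any(sd < 0)) stop("`sd` must be non-negative", call. = FALSE)
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  u <- runif(n)
  out <- numeric(n)
  upper_tail <- pnorm(lower, mean, sd) > 0.5
  i <- !upper_tail
  if (any(i)) {
    plo <- pnorm(lower[i], mean[i], sd[i])
    phi <- pnorm(upper[i], mean[i], sd[i])
    if (any(phi <= plo)) stop("empty truncation interval", call. = FALSE)
    out[i] <- qnorm(plo + u[i] * (phi - plo), mean[i], sd[i])
  }
  i <- upper_tail
  if (any(i)) {
    slo <- pnorm(lower[i], mean[i], sd[i], lower.tail = FALSE)
    shi <- pnorm(upper[i], mean[i], sd[i], lower.tail = FALSE)
    if (any(slo <= shi)) stop("empty truncation interval", call. = FALSE)
    out[i] <- qnorm(slo - u[i] * (slo - shi), mean[i], sd[i],
                    lower.tail = FALSE)
  }
  pmin(pmax(out, lower), upper)
}

#' Welch two-sample t-test from summary statistics
#'
#' Computes the Welch (unequal-variance) two-sample t-test directly from
#' group means, standard deviations and sizes, as needed when only published
#' summary statistics are available.
#'
#' @param mean1,sd1,n1 Summary statistics for group 1.
#' @param mean2,sd2,n2 Summary statistics for group 2.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return A list with `difference` (group 1 minus group 2), `se`, `df`,
#'   `statistic`, `p_value`, `ci_low` and `ci_high`.
#' @examples
#' welch_from_summary(4.4, 3.8, 102, 5.7, 3.6, 61)
#' @export
welch_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                               conf_level = 0.95) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  se <- sqrt(v1 + v2)
  diff <- mean1 - mean2
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  tstat <- diff / se
  p <- 2 * pt(-abs(tstat), df)
  q <- qt(1 - (1 - conf_level) / 2, df)
  list(difference = diff, se = se, df = df, statistic = tstat,
       p_value = p, ci_low = diff - q * se, ci_high = diff + q * se)
}

#' Chi-squared test of two proportions from counts
#'
#' @param x1,n1 Events and group size in group 1.
#' @param x2,n2 Events and group size in group 2.
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @param exact_fallback Use Fisher's exact test when any expected cell count
#'   falls below `exact_threshold`; the result is flagged via `test`.
#' @param exact_threshold Expected-count threshold for the fallback.
#' @return A list with `p_value`, `statistic` (NA for exact test), `test`
#'   (`"chi-squared"` or `"fisher"`) and the 2x2 `table`.
#' @export
chisq_from_counts <- function(x1, n1, x2, n2, correct = FALSE,
                              exact_fallback = TRUE, exact_threshold = 5) {
  tab <- matrix(c(x1, n1 - x1, x2, n2 - x2), nrow = 2, byrow = TRUE)
  if (any(tab < 0)) stop("counts must be non-negative and <= group size",
                         call. = FALSE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (exact_fallback && any(expected < exact_threshold)) {
    ft <- fisher.test(tab)
    return(list(p_value = ft$p.value, statistic = NA_real_,
                test = "fisher", table = tab))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  list(p_value = ct$p.value, statistic = unname(ct$statistic),
       test = "chi-squared", table = tab)
}

#' Convert Australian dollars to US dollars
#'
#' @param aud Amount in AUD.
#' @param rate AUD per USD exchange rate (default 1.51, the 2023 rate used
#'   for reporting).
#' @export
aud_to_usd <- function(aud, rate = 1.51) {
  if (any(rate <= 0)) stop("exchange rate must be positive", call. = FALSE)
  aud / rate
}
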