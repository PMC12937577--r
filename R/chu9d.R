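#' The nine CHU9D dimensions
#'
#' Dimension labels of the Child Health Utility 9D instrument, in canonical
#' order: worry, sadness, pain, tiredness, annoyance, school work, sleep,
#' daily routine, activities.
#'
#' @export
chu9d_dimensions <- c("worry", "sadness", "pain", "tiredness", "annoyance",
                      "school", "sleep", "daily_routine", "activities")

# Per-dimension utility contribution at the best (level 1) and worst
# (level 5) response, matching the published per-dimension ranges of the
# Australian adolescent preference weights. Levels 2-4 of the bundled
# default set are linear interpolations between these endpoints.
chu9d_default_endpoints <- data.frame(
  dimension = chu9d_dimensions,
  best  = c(0.22, 0.15, 0.11, 0.11, 0.08, 0.09, 0.06, 0.07, 0.13),
  worst = c(0.11, 0.02, -0.02, 0.03, -0.04, -0.02, -0.05, -0.05, 0.02)
)

new_chu9d_value_set <- function(weights, name, provenance) {
  structure(list(weights = weights, name = name, provenance = provenance),
            class = "chu9d_value_set")
}

#' Default CHU9D value set
#'
#' An additive preference-weight value set for the CHU9D. Level-1 (best) and
#' level-5 (worst) contributions per dimension equal the published Australian
#' adolescent per-dimension ranges; levels 2-4 are linearly interpolated.
#' Utility for a response is the sum of the nine per-dimension contributions,
#' giving 1.02 for the best state and 0.00 for the worst state (the printed
#' per-dimension maxima sum to 1.02, not 1.00, due to rounding of the
#' published ranges; no renormalization is forced). Any full published value
#' set can be substituted via [load_value_set()].
#'
#' @return A `chu9d_value_set`: a 9 x 5 matrix of weights plus metadata.
#' @export
default_chu9d_value_set <- function() {
  w <- t(vapply(seq_len(9), function(i) {
    seq(chu9d_default_endpoints$best[i], chu9d_default_endpoints$worst[i],
        length.out = 5)
  }, numeric(5)))
  dimnames(w) <- list(chu9d_dimensions, paste0("level", 1:5))
  new_chu9d_value_set(w, name = "default-interpolated",
                      provenance = paste("Synthetic additive set anchored at",
                                         "published per-dimension ranges;",
                                         "levels 2-4 linearly interpolated."))
}

#' Load and validate a CHU9D value set
#'
#' @param table A data frame with columns `dimension`, `level`, `weight`
#'   (45 rows, one per dimension-level cell), or the path of a CSV file with
#'   that layout.
#' @param name,provenance Metadata labels attached to the returned set.
#' @param allow_non_monotone Accept dimensions whose contribution is not
#'   weakly decreasing in level (level 1 must be the best response).
#' @return A `chu9d_value_set`.
#' @export
load_value_set <- function(table, name = "user", provenance = "",
                           allow_non_monotone = FALSE) {
  if (is.character(table)) {
    table <- utils::read.csv(table, stringsAsFactors = FALSE)
  }
  req <- c("dimension", "level", "weight")
  if (!all(req %in% names(table))) {
    stop("value-set table needs columns dimension, level, weight",
         call. = FALSE)
  }
  w <- matrix(NA_real_, 9, 5, dimnames = list(chu9d_dimensions,
                                              paste0("level", 1:5)))
  bad_dim <- setdiff(unique(table$dimension), chu9d_dimensions)
  if (length(bad_dim)) {
    stop("unknown CHU9D dimension(s): ", paste(bad_dim, collapse = ", "),
         call. = FALSE)
  }
  w[cbind(match(table$dimension, chu9d_dimensions), table$level)] <-
    table$weight
  if (anyNA(w)) {
    miss <- which(is.na(w), arr.ind = TRUE)
    stop("value set missing cell(s): ",
         paste(sprintf("(%s, level %d)", rownames(w)[miss[, 1]], miss[, 2]),
               collapse = ", "), call. = FALSE)
  }
  mono <- apply(w, 1, function(r) all(diff(r) <= 1e-12))
  if (!all(mono) && !allow_non_monotone) {
    stop("non-monotone weights for dimension(s): ",
         paste(rownames(w)[!mono], collapse = ", "),
         "; pass allow_non_monotone = TRUE to accept", call. = FALSE)
  }
  new_chu9d_value_set(w, name, provenance)
}

#' @export
print.chu9d_value_set <- function(x, ...) {
  cat("CHU9D value set:", x$name, "\n")
  cat("  utility range:",
      format(sum(apply(x$weights, 1, min)), digits = 3), "to",
      format(sum(apply(x$weights, 1, max)), digits = 3), "\n")
  invisible(x)
}

#' Tabulate a value set
#'
#' Long-format `(dimension, level, weight)` table of a value set, the layout
#' read back by [load_value_set()].
#'
#' @param value_set A `chu9d_value_set`.
#' @export
value_set_table <- function(value_set) {
  stopifnot(inherits(value_set, "chu9d_value_set"))
  data.frame(dimension = rep(rownames(value_set$weights), 5),
             level = rep(1:5, each = 9),
             weight = as.vector(value_set$weights))
}

#' Validate a CHU9D response
#'
#' @param levels Named integer vector (or single-row data frame) giving the
#'   response level (1 = best, 5 = worst) for each of the nine dimensions.
#' @return A named integer vector in canonical dimension order.
#' @export
chu9d_response <- function(levels) {
  if (is.data.frame(levels)) levels <- unlist(levels[1, , drop = TRUE])
  if (is.null(names(levels)) || !setequal(names(levels), chu9d_dimensions)) {
    stop("a CHU9D response needs exactly the nine named dimensions",
         call. = FALSE)
  }
  levels <- levels[chu9d_dimensions]
  if (anyNA(levels) || !all(levels %in% 1:5)) {
    stop("every CHU9D level must be an integer in 1..5", call. = FALSE)
  }
  storage.mode(levels) <- "integer"
  levels
}

#' Per-dimension utility contribution
#'
#' @param response A validated CHU9D response (see [chu9d_response()]).
#' @param dimension One of [chu9d_dimensions].
#' @param value_set A `chu9d_value_set`.
#' @return The weight of the responded level on that dimension.
#' @export
dimension_score <- function(response, dimension, value_set) {
  stopifnot(inherits(value_set, "chu9d_value_set"))
  if (!dimension %in% chu9d_dimensions) {
    stop("unknown CHU9D dimension: ", dimension, call. = FALSE)
  }
  response <- chu9d_response(response)
  unname(value_set$weights[dimension, response[[dimension]]])
}

#' Score CHU9D responses into utility values
#'
#' Utility is the sum of the nine per-dimension weight contributions
#' (additive scoring). Incomplete responses score `NA` and are excluded from
#' downstream analyses; they are never silently scored as zero.
#'
#' @param response Either a single named response vector, or a matrix/data
#'   frame with one row per participant and the nine dimensions as columns.
#' @param value_set A `chu9d_value_set` (default [default_chu9d_value_set()]).
#' @return A numeric utility (or vector of utilities), `NA` where any
#'   dimension is unanswered.
#' @export
score_utility <- function(response, value_set = default_chu9d_value_set()) {
  stopifnot(inherits(value_set, "chu9d_value_set"))
  if (is.null(dim(response))) {
    if (anyNA(response)) return(NA_real_)
    response <- chu9d_response(response)
    return(sum(value_set$weights[cbind(seq_len(9), response)]))
  }
  m <- as.matrix(as.data.frame(response)[, chu9d_dimensions, drop = FALSE])
  ok <- !apply(m, 1, anyNA)
  bad <- m[ok, , drop = FALSE]
  if (length(bad) && !all(bad %in% 1:5)) {
    stop("every CHU9D level must be an integer in 1..5", call. = FALSE)
  }
  out <- rep(NA_real_, nrow(m))
  if (any(ok)) {
    wt <- value_set$weights
    out[ok] <- rowSums(vapply(seq_len(9), function(d) {
      wt[d, m[ok, d]]
    }, numeric(sum(ok))))
  }
  out
}

# Columns of a cohort data frame holding the nine CHU9D level responses.
chu9d_columns <- function() paste0("chu9d_", chu9d_dimensions)

#' Score an entire cohort
#'
#' @param cohort A cohort data frame with `chu9d_*` level columns (as
#'   produced by [generate_cohort()] or read with [read_cohort()]).
#' @inheritParams score_utility
#' @return Numeric vector of utilities, `NA` for incomplete responses.
#' @export
score_cohort_utilities <- function(cohort,
                                   value_set = default_chu9d_value_set()) {
  cols <- chu9d_columns()
  if (!all(cols %in% names(cohort))) {
    stop("cohort is missing CHU9D level columns", call. = FALSE)
  }
  m <- cohort[, cols]
  names(m) <- chu9d_dimensions
  score_utility(m, value_set)
}

#' Per-dimension group summary of CHU9D scores
#'
#' One row per dimension plus an overall-utility row, giving mean (SD) per
#' diagnosis-delay group and a Welch two-sample t-test p-value, mirroring the
#' dimension-score table of the source analysis. Participants with incomplete
#' CHU9D are excluded. Groups with fewer than two complete responses yield
#' `NA` statistics.
#'
#' @param cohort A cohort data frame.
#' @inheritParams score_utility
#' @return A data frame with columns `dimension`, `mean_lt6`, `sd_lt6`,
#'   `mean_ge6`, `sd_ge6`, `difference`, `p_value`, `n_lt6`, `n_ge6`.
#' @export
dimension_summary <- function(cohort, value_set = default_chu9d_value_set()) {
  stopifnot(inherits(value_set, "chu9d_value_set"))
  cols <- chu9d_columns()
  complete <- cohort[!is.na(cohort[[cols[1]]]) &
                       stats::complete.cases(cohort[, cols]), ]
  scores <- vapply(seq_len(9), function(d) {
    value_set$weights[d, complete[[cols[d]]]]
  }, numeric(nrow(complete)))
  if (nrow(complete) == 1L) scores <- matrix(scores, nrow = 1)
  overall <- rowSums(scores)
  grp <- complete$delay_group
  one_row <- function(label, x) {
    a <- x[grp == "lt6"]
    b <- x[grp == "ge6plus"]
    p <- if (length(a) >= 2 && length(b) >= 2 &&
             (stats::var(a) + stats::var(b)) > 0) {
      stats::t.test(a, b)$p.value
    } else NA_real_
    data.frame(dimension = label,
               mean_lt6 = if (length(a)) mean(a) else NA_real_,
               sd_lt6 = if (length(a) >= 2) stats::sd(a) else NA_real_,
               mean_ge6 = if (length(b)) mean(b) else NA_real_,
               sd_ge6 = if (length(b) >= 2) stats::sd(b) else NA_real_,
               difference = (if (length(a)) mean(a) else NA_real_) -
                 (if (length(b)) mean(b) else NA_real_),
               p_value = p,
               n_lt6 = length(a), n_ge6 = length(b))
  }
  out <- do.call(rbind, c(list(one_row("overall", overall)),
                          lapply(seq_len(9), function(d) {
                            one_row(chu9d_dimensions[d], scores[, d])
                          })))
  rownames(out) <- NULL
  out
}
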