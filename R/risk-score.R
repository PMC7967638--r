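#' OR-to-weight discretization rule
#'
#' The rule that converts adjusted odds ratios into integer score weights.
#' The default bands are: weight 3 for OR >= 10, weight 2 for 5 <= OR < 10,
#' and weight 1 for OR < 5 (reference categories always weigh 0). Bounds are
#' inclusive lower limits and must be strictly decreasing.
#'
#' @param thresholds A data frame with columns `lower` (inclusive OR lower
#'   bound) and `weight` (nonnegative integer).
#' @return An object of class `weight_rule`.
#' @export
weight_rule <- function(thresholds = tibble::tibble(lower = c(10, 5, 0),
                                                    weight = c(3L, 2L, 1L))) {
  thresholds <- tibble::as_tibble(thresholds)
  if (!all(c("lower", "weight") %in% names(thresholds))) {
    abort("thresholds needs columns lower and weight")
  }
  if (is.unsorted(rev(thresholds$lower), strictly = TRUE)) {
    abort("lower bounds must be strictly decreasing")
  }
  w <- thresholds$weight
  if (any(w < 0) || any(w != as.integer(w))) {
    abort("weights must be nonnegative integers")
  }
  thresholds$weight <- as.integer(w)
  structure(thresholds, class = c("weight_rule", class(thresholds)))
}

apply_weight_rule <- function(rule, or) {
  purrr::map_int(or, function(v) rule$weight[match(TRUE, v >= rule$lower)])
}

#' Select risk factors from crude fits
#'
#' A variable is retained when at least one of its non-reference categories
#' has a 95% (or `level`) confidence interval excluding an odds ratio of 1 —
#' the reproducible operationalization of "statistically significant" used
#' to admit variables to the multiple regression.
#'
#' @param fits A named list of `exact_logit_fit`s, one per variable (see
#'   [crude_fits()]).
#' @return Character vector of selected variable names.
#' @export
select_factors <- function(fits) {
  keep <- purrr::map_lgl(fits, function(f) {
    inf <- f$inference
    any(!is.na(inf$odds_ratio) &
          (inf$ci_lower > 1 | inf$ci_upper < 1), na.rm = TRUE)
  })
  names(fits)[keep]
}

#' Derive an integer score formula from an adjusted fit
#'
#' Maps each non-reference category's adjusted odds ratio through the weight
#' rule and assembles the score formula. The maximum attainable score is the
#' sum over variables of the largest weight among that variable's
#' categories. Odds ratios below 1 still receive the lowest band's weight
#' but trigger a warning, since a protective category inflating a risk score
#' deserves a second look.
#'
#' @param adjusted_fit An `exact_logit_fit` from the multiple regression of
#'   the selected factors (parameters must carry variable/category labels,
#'   as produced by [design_from_records()] or [design_from_counts()]), or a
#'   data frame with columns `variable`, `category`, `odds_ratio`.
#' @param rule A [weight_rule()].
#' @return An object of class `score_formula`: a tibble of
#'   (variable, category, weight) terms with attribute `max_score`.
#' @export
derive_weights <- function(adjusted_fit, rule = weight_rule()) {
  inf <- if (inherits(adjusted_fit, "exact_logit_fit")) {
    adjusted_fit$inference
  } else {
    tibble::as_tibble(adjusted_fit)
  }
  if (!all(c("variable", "category", "odds_ratio") %in% names(inf))) {
    abort("adjusted_fit needs variable, category and odds_ratio")
  }
  if (anyNA(inf$odds_ratio)) {
    abort("adjusted fit has missing odds ratios; cannot derive weights")
  }
  if (anyNA(inf$variable) || anyNA(inf$category)) {
    abort("adjusted fit parameters lack variable/category labels")
  }
  if (any(inf$odds_ratio < 1)) {
    warn("odds ratio(s) below 1 mapped to the minimum weight band")
  }
  terms <- tibble::tibble(
    variable = inf$variable,
    category = inf$category,
    weight = apply_weight_rule(rule, inf$odds_ratio)
  )
  new_score_formula(terms)
}

new_score_formula <- function(terms) {
  if (anyDuplicated(terms[c("variable", "category")])) {
    abort("duplicate (variable, category) term in score formula")
  }
  max_score <- sum(purrr::map_int(split(terms$weight, terms$variable), max))
  structure(terms, class = c("score_formula", class(tibble::tibble())),
            max_score = max_score)
}

#' @export
print.score_formula <- function(x, ...) {
  cat("Risk score formula (max score ", attr(x, "max_score"), "):\n", sep = "")
  print(tibble::as_tibble(x))
  invisible(x)
}

#' Maximum attainable score of a formula
#' @param formula A `score_formula`.
#' @return Integer maximum score.
#' @export
max_score <- function(formula) attr(formula, "max_score")

# a formula category "no/not_answered" matches record categories "no",
# "not_answered" and the merged label itself
category_matches <- function(record_value, formula_category) {
  record_value %in% unique(c(formula_category,
                             strsplit(formula_category, "/", fixed = TRUE)[[1]]))
}

#' Score a cohort with a risk-score formula
#'
#' Adds up the weights of the formula terms matched by each record's
#' categories. A merged formula category such as `"no/not_answered"` matches
#' either constituent label, so formulas derived from merged tables apply
#' directly to unmerged records.
#'
#' @param records A recoded cohort ([recode_cohort()]).
#' @param formula A `score_formula`.
#' @return The cohort tibble with an integer `score` column appended.
#' @export
score_cohort <- function(records, formula) {
  missing_vars <- setdiff(unique(formula$variable), names(records))
  if (length(missing_vars) > 0) {
    abort(paste0("records lack formula variable(s): ",
                 paste(missing_vars, collapse = ", ")))
  }
  score <- integer(nrow(records))
  for (i in seq_len(nrow(formula))) {
    v <- formula$variable[i]
    hit <- purrr::map_lgl(as.character(records[[v]]),
                          category_matches, formula$category[i])
    score <- score + formula$weight[i] * hit
  }
  dplyr::mutate(records, score = as.integer(score))
}

#' Score a single recoded record
#'
#' @param record A named list mapping variable to category (see
#'   [recode_record()]), or a one-row recoded cohort.
#' @param formula A `score_formula`.
#' @return Integer score in `[0, max_score(formula)]`.
#' @export
compute_score <- function(record, formula) {
  record <- purrr::map(as.list(record), as.character)
  missing_vars <- setdiff(unique(formula$variable), names(record))
  if (length(missing_vars) > 0) {
    abort(paste0("record lacks formula variable(s): ",
                 paste(missing_vars, collapse = ", ")))
  }
  s <- 0L
  for (i in seq_len(nrow(formula))) {
    if (category_matches(record[[formula$variable[i]]], formula$category[i])) {
      s <- s + formula$weight[i]
    }
  }
  s
}

#' Tabulate a score distribution
#'
#' @param scores Integer scores.
#' @return A tibble of class `score_distribution` with `score`, `n` and
#'   `percent` (one decimal, rounded half up) per observed score value.
#' @export
score_distribution <- function(scores) {
  counts <- table(scores)
  tibble::new_tibble(
    tibble::tibble(
      score = as.integer(names(counts)),
      n = as.integer(counts),
      percent = round_half_up(100 * as.integer(counts) / length(scores), 1)
    ),
    class = "score_distribution"
  )
}

#' @export
autoplot.score_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$score, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Risk score", y = "Mothers",
                  title = "Prenatal risk score distribution") +
    ggplot2::theme_minimal()
}
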