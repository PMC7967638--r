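#' Per-cutoff classification table for an integer risk score
#'
#' For each observed score value `c` (plus one value beyond the maximum), a
#' record is classified positive when `score >= c`, and the table reports
#' sensitivity, specificity, the overall rate of correct classification, and
#' the positive and negative predictive values as percentages rounded half
#' up to one decimal. Zero-denominator predictive values are reported as
#' `NA`. Full-precision fractions are kept in the `"raw"` attribute.
#'
#' @param scores Numeric scores.
#' @param labels Binary outcomes (logical or 0/1); needs both classes.
#' @return A tibble of class `classification_table`, one row per cutoff.
#'   Sensitivity is non-increasing and specificity non-decreasing down the
#'   table.
#' @export
classification_table <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) abort("scores and labels differ in length")
  if (all(labels) || !any(labels)) {
    abort("labels must contain at least one positive and one negative")
  }
  pos <- scores[labels]; neg <- scores[!labels]
  cutoffs <- c(sort(unique(scores)), max(scores) + 1)
  raw <- purrr::map_dfr(cutoffs, function(cc) {
    tp <- sum(pos >= cc); fn <- length(pos) - tp
    fp <- sum(neg >= cc); tn <- length(neg) - fp
    tibble::tibble(
      cutoff = cc,
      sensitivity = tp / length(pos),
      specificity = tn / length(neg),
      correct_classification = (tp + tn) / length(scores),
      ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_
    )
  })
  shown <- dplyr::mutate(raw, dplyr::across(-"cutoff",
                                            ~ round_half_up(100 * .x, 1)))
  tibble::new_tibble(shown, raw = raw, class = "classification_table")
}

#' @export
autoplot.classification_table <- function(object, ...) {
  raw <- attr(object, "raw") %||% object
  ggplot2::ggplot(raw, ggplot2::aes(x = 1 - .data$specificity,
                                    y = .data$sensitivity)) +
    ggplot2::geom_step(direction = "vh", colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = "ROC curve of the risk score") +
    ggplot2::theme_minimal()
}

#' AUC with a DeLong confidence interval
#'
#' The area under the ROC curve is estimated by the Mann-Whitney statistic:
#' the proportion of (positive, negative) pairs in which the positive scores
#' higher, ties counting one half. The confidence interval uses the DeLong
#' structural-components variance with a normal approximation, truncated to
#' `[0, 1]` only if it spills over.
#'
#' @param scores Numeric scores.
#' @param labels Binary outcomes; needs both classes.
#' @param level Confidence level (default 0.95).
#' @return An object of class `roc_result` with `auc`, `auc_ci`, `se`,
#'   `n_pos`, `n_neg`. [tidy()]/[glance()] return it as a one-row tibble.
#' @export
roc_auc <- function(scores, labels, level = 0.95) {
  labels <- as.logical(labels)
  if (all(labels) || !any(labels)) {
    abort("labels must contain at least one positive and one negative")
  }
  pos <- scores[labels]; neg <- scores[!labels]
  np <- length(pos); nn <- length(neg)
  # placement of each positive among the negatives and vice versa
  v10 <- purrr::map_dbl(pos, ~ (sum(neg < .x) + 0.5 * sum(neg == .x)) / nn)
  v01 <- purrr::map_dbl(neg, ~ (sum(pos > .x) + 0.5 * sum(pos == .x)) / np)
  auc <- mean(v10)
  se <- sqrt(var(v10) / np + var(v01) / nn)
  z <- qnorm(1 - (1 - level) / 2)
  ci <- c(max(0, auc - z * se), min(1, auc + z * se))
  structure(
    list(auc = auc, auc_ci = ci, se = se, n_pos = np, n_neg = nn,
         level = level),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (%d%% CI %.3f-%.3f; %d positives, %d negatives)\n",
              x$auc, round(100 * x$level), x$auc_ci[1], x$auc_ci[2],
              x$n_pos, x$n_neg))
  invisible(x)
}

#' @rdname roc_auc
#' @param x A `roc_result`.
#' @param ... Unused.
#' @export
tidy.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, ci_lower = x$auc_ci[1], ci_upper = x$auc_ci[2],
                 se = x$se, n_pos = x$n_pos, n_neg = x$n_neg, level = x$level)
}

#' @rdname roc_auc
#' @export
glance.roc_result <- tidy.roc_result

#' Select a classification cutoff
#'
#' Picks the cutoff maximizing Youden's J (sensitivity + specificity - 100)
#' or, alternatively, the overall rate of correct classification. Ties break
#' toward the smaller cutoff.
#'
#' @param table A `classification_table`.
#' @param criterion `"youden"` (default) or `"correct"`.
#' @return The selected cutoff.
#' @export
select_cutoff <- function(table, criterion = c("youden", "correct")) {
  criterion <- match.arg(criterion)
  if (nrow(table) == 0) abort("empty classification table")
  objective <- switch(criterion,
    youden = table$sensitivity + table$specificity - 100,
    correct = table$correct_classification
  )
  table$cutoff[which.max(objective)]
}
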