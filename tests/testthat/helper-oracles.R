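# Independent oracles and small-design generators used across test files.

# Maximize the conditional log-likelihood over a beta grid (independent of
# the score-equation solver used by cmle()).
grid_cmle <- function(dist, t_observed, betas = seq(-10, 10, by = 1e-4)) {
  ll <- vapply(betas, function(b) {
    lw <- dist$log_coef + b * dist$support
    lw[dist$support == t_observed] - prenatalrisk:::logsumexp(lw)
  }, numeric(1))
  betas[which.max(ll)]
}

# Invert one exact tail equation by grid search.
grid_tail_root <- function(dist, t_observed, alpha, side = c("ge", "le"),
                           betas = seq(-12, 12, by = 1e-3)) {
  side <- match.arg(side)
  f <- vapply(betas, function(b) {
    p <- cond_pmf(dist, b)
    if (side == "ge") sum(p[dist$support >= t_observed]) else
      sum(p[dist$support <= t_observed])
  }, numeric(1))
  betas[which.min(abs(f - alpha))]
}

# Random per-subject design with n <= 20 subjects and 1-2 binary covariates,
# guaranteed to give a non-degenerate event total.
random_subject_design <- function(n_max = 20) {
  n <- sample(6:n_max, 1)
  p <- sample(1:2, 1)
  x <- matrix(rbinom(n * p, 1, 0.5), nrow = n)
  y <- integer(n)
  y[sample(n, sample(1:4, 1))] <- 1L
  list(x = x, y = y, p = p, n = n)
}

group_design_from_subjects <- function(x, y) {
  key <- apply(x, 1, paste, collapse = ",")
  groups <- split(seq_len(nrow(x)), key)
  patt <- do.call(rbind, lapply(groups, function(i) x[i[1], , drop = TRUE]))
  grouped_design(patt,
                 m = vapply(groups, length, integer(1)),
                 y = vapply(groups, function(i) sum(y[i]), integer(1)))
}

# A raw cohort row with innocuous defaults, overridable per field.
raw_record <- function(...) {
  rec <- list(
    household_id = "h1", municipality_id = "m5",
    maternal_age_years = 30L, gestational_weeks_at_registration = 8L,
    marital_status = "married", pregnancy_progress = "good",
    birth_order = "subsequent", abortion_history = "no",
    infertility_treatment = "no", feeling_at_pregnancy = "happy",
    return_to_parents_home = "yes", has_helper = "yes",
    worries_anxiety = "no", smoking = "no", passive_smoking = "no",
    alcohol = "no", disease_history = "no", mental_illness_history = "no",
    depressive_symptoms = "no", outcome_rccrc = FALSE
  )
  utils::modifyList(rec, list(...))
}

raw_cohort <- function(records) {
  dplyr::bind_rows(lapply(records, tibble::as_tibble))
}

# The published prenatal risk-score formula.
paper_formula <- function() {
  prenatalrisk:::new_score_formula(tibble::tibble(
    variable = c("marital_status", "marital_status", "marital_status",
                 "abortion_history", "smoking", "smoking"),
    category = c("unmarried", "not_answered", "not_investigated",
                 "yes", "stopped_after_confirmation", "yes"),
    weight = c(3L, 2L, 1L, 2L, 1L, 2L)
  ))
}
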