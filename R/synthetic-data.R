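#' Default per-variable category probabilities
#'
#' Category sampling probabilities for the synthetic generator, taken from
#' the packaged published-cohort marginals: for each analysis variable, the
#' published category proportions among investigated records (the
#' `not_investigated` rows are excluded and the rest renormalized, because
#' structural missingness is produced by municipality masking, not drawn).
#'
#' @return Named list of named probability vectors.
#' @export
default_category_probs <- function() {
  purrr::map(load_table1_fixture(), function(tb) {
    tb <- tb[tb$category != "not_investigated", ]
    setNames(tb$n_total / sum(tb$n_total), tb$category)
  })
}

#' Default municipality masking patterns
#'
#' Five municipalities whose weights and sets of non-digitized items
#' reproduce the published "not investigated" fractions (e.g. 417/893
#' records with marital status not investigated, 326/893 for pregnancy
#' progress). The assignment of masking sets to municipalities is a modelling
#' choice constrained only by those totals.
#'
#' @return A tibble with `municipality`, `weight`, and list-column `masked`.
#' @export
default_municipality_patterns <- function() {
  tibble::tibble(
    municipality = paste0("m", 1:5),
    weight = c(124, 78, 202, 13, 476) / 893,
    masked = list(
      c("marital_status", "pregnancy_progress", "passive_smoking",
        "disease_history", "worries_anxiety", "infertility_treatment",
        "return_to_parents_home", "mental_illness_history"),
      c("marital_status", "worries_anxiety"),
      c("marital_status", "pregnancy_progress", "passive_smoking",
        "disease_history"),
      "marital_status",
      character(0)
    )
  )
}

#' Default true effects for the synthetic generator
#'
#' Log odds ratios reproducing the structure of the published adjusted
#' model: elevated risk for unmarried status (and its missingness
#' categories), a history of artificial abortion, and smoking during
#' pregnancy.
#'
#' @return Named list of named log-odds-ratio vectors.
#' @export
default_true_log_odds <- function() {
  list(
    marital_status = c(unmarried = log(12.14), not_answered = log(8.76),
                       not_investigated = log(3.10)),
    abortion_history = c(yes = log(5.82)),
    smoking = c(stopped_after_confirmation = log(3.35), yes = log(5.30))
  )
}

#' Configuration of the synthetic-cohort generator
#'
#' The generator emulates the questionnaire cohort the analysis assumes:
#' records are drawn from a municipality (with municipality-dependent item
#' availability), covariates independently from per-variable category
#' probabilities, and a binary outcome from a logistic model whose intercept
#' is calibrated to the target event prevalence.
#'
#' @param n Cohort size (default 893, the published cohort size).
#' @param category_probs Per-variable category probabilities; defaults to
#'   [default_category_probs()].
#' @param municipality_patterns Masking design; defaults to
#'   [default_municipality_patterns()].
#' @param true_log_odds Named list of named log-odds-ratio vectors;
#'   defaults to [default_true_log_odds()]. Use `list()` for a null model.
#' @param target_prevalence Expected event prevalence (default 11/893).
#' @param seed Integer RNG seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n = 893, category_probs = NULL,
                             municipality_patterns = NULL,
                             true_log_odds = NULL,
                             target_prevalence = 11 / 893, seed = 1L) {
  if (n < 1) abort("n must be at least 1")
  if (target_prevalence <= 0 || target_prevalence >= 1) {
    abort("target_prevalence must be in (0, 1)")
  }
  category_probs <- category_probs %||% default_category_probs()
  purrr::iwalk(category_probs, ~ assert_prob_vector(.x, paste0("category_probs$", .y)))
  municipality_patterns <- municipality_patterns %||% default_municipality_patterns()
  assert_prob_vector(municipality_patterns$weight, "municipality weights")
  true_log_odds <- true_log_odds %||% default_true_log_odds()
  structure(
    list(n = as.integer(n), category_probs = category_probs,
         municipality_patterns = municipality_patterns,
         true_log_odds = true_log_odds,
         target_prevalence = target_prevalence, seed = as.integer(seed)),
    class = "generator_config"
  )
}

# exact distribution of the linear predictor over (municipality, effect
# covariates): a tibble of (lp, prob)
linear_predictor_distribution <- function(config) {
  eff_vars <- names(config$true_log_odds)[
    purrr::map_lgl(config$true_log_odds, ~ any(.x != 0))
  ]
  out <- purrr::pmap_dfr(config$municipality_patterns,
    function(municipality, weight, masked) {
      acc <- tibble::tibble(lp = 0, prob = weight)
      for (v in eff_vars) {
        coefs <- config$true_log_odds[[v]]
        if (v %in% masked) {
          lp_v <- unname(coefs["not_investigated"])
          lp_v <- if (is.na(lp_v)) 0 else lp_v
          part <- tibble::tibble(lp = lp_v, prob = 1)
        } else {
          p <- config$category_probs[[v]]
          part <- tibble::tibble(
            lp = unname(ifelse(is.na(coefs[names(p)]), 0, coefs[names(p)])),
            prob = unname(p)
          )
        }
        acc <- tidyr::expand_grid(acc, part2 = seq_len(nrow(part))) |>
          dplyr::mutate(lp = .data$lp + part$lp[.data$part2],
                        prob = .data$prob * part$prob[.data$part2]) |>
          dplyr::select("lp", "prob")
      }
      acc
    })
  dplyr::summarise(dplyr::group_by(out, .data$lp),
                   prob = sum(.data$prob), .groups = "drop")
}

#' Calibrate the generator's intercept to the target prevalence
#'
#' Solves for the logistic intercept that makes the expected event
#' prevalence equal the configured target, given the covariate distribution
#' and the true effects. The expectation is computed exactly by enumerating
#' the joint distribution of the linear predictor over municipalities and
#' the covariates with nonzero effects; with no effects the intercept is the
#' closed-form logit of the target.
#'
#' @param config A `generator_config`.
#' @return The intercept on the log-odds scale.
#' @export
calibrate_intercept <- function(config) {
  lpd <- linear_predictor_distribution(config)
  if (nrow(lpd) == 1 && lpd$lp[1] == 0) return(qlogis(config$target_prevalence))
  f <- function(b0) sum(lpd$prob * plogis(b0 + lpd$lp)) - config$target_prevalence
  if (f(-40) > 0 || f(40) < 0) abort("target prevalence unattainable")
  uniroot(f, c(-40, 40), tol = 1e-12)$root
}

age_band_range <- list("<20" = 16:19, "20-24" = 20:24, "25-39" = 25:39,
                       ">=40" = 40:45)

# map an analysis category back to a raw questionnaire cell
raw_cell <- function(category) {
  dplyr::case_when(
    category %in% c("not_answered", "not_investigated") ~ NA_character_,
    TRUE ~ sub("/not_answered$", "", category)
  )
}

#' Generate a synthetic cohort of raw pregnancy notification records
#'
#' Draws, for each record: a municipality, analysis categories for every
#' questionnaire variable, municipality masking (items the municipality does
#' not digitize become structurally missing), and a Bernoulli outcome from
#' the logistic model with the calibrated intercept. Analysis categories are
#' then mapped back to raw questionnaire cells (an age drawn within its
#' band, gestational weeks consistent with the late-registration indicator,
#' a specific pooled feeling label), so the cohort exercises the full
#' recoding pipeline. Byte-identical for a fixed seed.
#'
#' @param config A `generator_config`.
#' @param intercept Optional pre-computed intercept (skips calibration).
#' @return A raw cohort tibble with attributes `availability` (the
#'   municipality masking map for [recode_cohort()]), `intercept`, and
#'   `config`.
#' @export
generate_cohort <- function(config, intercept = NULL) {
  intercept <- intercept %||% calibrate_intercept(config)
  specs <- coded_variables()
  mp <- config$municipality_patterns
  with_seed(config$seed, {
    n <- config$n
    muni_idx <- sample(nrow(mp), n, replace = TRUE, prob = mp$weight)
    cats <- purrr::imap(config$category_probs, function(p, v) {
      drawn <- sample(names(p), n, replace = TRUE, prob = p)
      masked <- purrr::map_lgl(muni_idx, ~ v %in% mp$masked[[.x]])
      dplyr::if_else(masked, "not_investigated", drawn)
    })
    lp <- rep(intercept, n)
    for (v in names(config$true_log_odds)) {
      coefs <- config$true_log_odds[[v]]
      hit <- coefs[cats[[v]]]
      lp <- lp + ifelse(is.na(hit), 0, hit)
    }
    outcome <- runif(n) < plogis(lp)

    age_band <- cats$maternal_age
    age <- purrr::map_int(age_band, ~ sample(age_band_range[[.x]], 1))
    weeks <- dplyr::case_when(
      cats$late_registration == "no" ~ sample(5:11, n, replace = TRUE),
      cats$late_registration == "yes" ~ sample(12:20, n, replace = TRUE),
      TRUE ~ NA_integer_
    )
    feeling <- cats$feeling_at_pregnancy
    feeling[feeling == "unexpected_other"] <-
      sample(feeling_pool, sum(feeling == "unexpected_other"), replace = TRUE)

    cohort <- tibble::tibble(
      household_id = sprintf("h%05d", seq_len(n)),
      municipality_id = mp$municipality[muni_idx],
      maternal_age_years = age,
      gestational_weeks_at_registration = weeks
    )
    for (item in names(raw_enum_levels())) {
      varname <- names(specs)[purrr::map_chr(specs, "source") == item]
      cohort[[item]] <- if (item == "feeling_at_pregnancy") {
        raw_cell(feeling)
      } else {
        raw_cell(cats[[varname]])
      }
    }
    cohort$outcome_rccrc <- outcome
    availability <- setNames(mp$masked, mp$municipality)
    structure(cohort, availability = availability, intercept = intercept,
              config = config)
  })
}

#' Parameter-recovery experiment
#'
#' Validation harness for the whole inferential chain: repeatedly generates
#' a cohort from `config`, runs the crude exact logistic fits of the
#' requested variables, and summarises, per non-reference category, the
#' median bias of the log odds-ratio estimate and the empirical coverage of
#' the exact confidence interval against the configured true values.
#' Replicates in which a parameter's conditional support degenerates to a
#' point (e.g. a zero-event cohort) are flagged and excluded from the
#' summaries rather than crashing the run.
#'
#' @param config A `generator_config` with `true_log_odds` set.
#' @param n_replicates Number of replicate cohorts.
#' @param seed Seed governing the replicate seeds.
#' @param variables Variables to fit (default: those with nonzero effects).
#' @param level Confidence level for the coverage check.
#' @return A tibble of class `recovery_report`: one row per (variable,
#'   category) with `true_log_or`, `median_bias`, `coverage`, `n_ok`,
#'   `n_flagged`.
#' @export
recovery_experiment <- function(config, n_replicates = 100, seed = 1,
                                variables = NULL, level = 0.95) {
  if (length(config$true_log_odds) == 0) abort("config has no true effects set")
  variables <- variables %||% names(config$true_log_odds)
  intercept <- calibrate_intercept(config)
  draws <- purrr::map(seq_len(n_replicates), function(r) {
    cfg <- config
    cfg$seed <- as.integer(seed + r)
    cohort <- generate_cohort(cfg, intercept = intercept)
    recoded <- recode_cohort(cohort, attr(cohort, "availability"))
    if (sum(recoded$outcome) == 0) return(NULL)  # flagged: nothing estimable
    purrr::map_dfr(variables, function(v) {
      fit <- fit_exact_logit(design_from_counts(build_count_table(recoded, v)),
                             level = level)
      dplyr::mutate(fit$inference, variable = v)
    })
  })
  est <- dplyr::bind_rows(purrr::compact(draws))
  n_zero_event <- sum(purrr::map_lgl(draws, is.null))
  if (nrow(est) == 0) {
    return(tibble::new_tibble(
      tibble::tibble(variable = character(), category = character(),
                     true_log_or = numeric(), n_ok = integer(),
                     n_flagged = integer(), median_bias = numeric(),
                     coverage = numeric()),
      class = "recovery_report", n_replicates = n_replicates
    ))
  }
  truth <- purrr::imap_dfr(config$true_log_odds, function(coefs, v) {
    tibble::tibble(variable = v, category = names(coefs),
                   true_log_or = unname(coefs))
  })
  est <- dplyr::inner_join(est, truth, by = c("variable", "category"))
  report <- est |>
    dplyr::group_by(.data$variable, .data$category, .data$true_log_or) |>
    dplyr::summarise(
      n_ok = sum(.data$estimate_kind != "non_informative"),
      n_flagged = sum(.data$estimate_kind == "non_informative") + n_zero_event,
      median_bias = stats::median(log(.data$odds_ratio) - .data$true_log_or,
                                  na.rm = TRUE),
      coverage = mean((.data$ci_lower <= exp(.data$true_log_or) &
                         exp(.data$true_log_or) <= .data$ci_upper)[
                           .data$estimate_kind != "non_informative"]),
      .groups = "drop"
    )
  tibble::new_tibble(report, class = "recovery_report",
                     n_replicates = n_replicates)
}
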