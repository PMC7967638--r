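#' Grouped design for exact conditional logistic regression
#'
#' A grouped design collects subjects sharing the same 0/1 covariate pattern:
#' pattern j has indicator vector `x[j, ]`, group size `m[j]` and observed
#' event count `y[j]`. The sufficient statistic for parameter i is
#' `T_i = sum_j y_j x_{ji}`; the intercept's statistic is the total event
#' count. Exact inference for one parameter works on the distribution of its
#' statistic conditional on all the others.
#'
#' @param x Matrix (patterns by parameters) of 0/1 indicators; a vector is
#'   taken as a single-parameter design.
#' @param m Integer vector of group sizes.
#' @param y Integer vector of observed events per group.
#' @param parameter_names Optional parameter names (defaults to the column
#'   names of `x`).
#' @return An object of class `grouped_design`.
#' @export
grouped_design <- function(x, m, y, parameter_names = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  if (!all(x %in% c(0L, 1L))) abort("design indicators must be 0/1")
  m <- as.integer(m); y <- as.integer(y)
  if (length(m) != nrow(x) || length(y) != nrow(x)) {
    abort("m and y must have one entry per pattern")
  }
  if (any(y < 0) || any(y > m)) abort("need 0 <= y_j <= m_j for every pattern")
  parameter_names <- parameter_names %||% colnames(x) %||%
    paste0("beta", seq_len(ncol(x)))
  colnames(x) <- parameter_names
  structure(
    list(x = x, m = m, y = y, parameter_names = parameter_names),
    class = "grouped_design"
  )
}

#' @export
print.grouped_design <- function(x, ...) {
  cat("<grouped_design> ", sum(x$m), " subjects, ", sum(x$y), " events, ",
      length(x$parameter_names), " parameter(s)\n", sep = "")
  invisible(x)
}

#' Build a one-variable design from a category count table
#'
#' Expands a per-category (total, events) table into the grouped design of
#' the crude exact logistic regression of that variable: one dummy per
#' non-reference category. Parameter names are the category labels.
#'
#' @param table A `count_table` (see [build_count_table()]).
#' @return A `grouped_design` whose parameters carry `variable` and
#'   `category` attributes used downstream by the score machinery.
#' @export
design_from_counts <- function(table) {
  non_ref <- which(!table$reference)
  if (length(non_ref) == 0) abort("count table has only the reference category")
  p <- length(non_ref)
  x <- matrix(0L, nrow = nrow(table), ncol = p)
  for (k in seq_len(p)) x[non_ref[k], k] <- 1L
  d <- grouped_design(x, table$n_total, table$n_events,
                      parameter_names = table$category[non_ref])
  d$variable <- rep(table$variable[1], p)
  d$category <- table$category[non_ref]
  d
}

#' Build a multi-variable design from recoded records
#'
#' Expands the selected variables' non-reference categories into dummies,
#' groups records by identical dummy pattern, and returns the grouped design
#' of the joint (multiple) exact logistic regression.
#'
#' @param records A recoded (and usually collapsed) cohort.
#' @param variables Character vector of analysis variable names to enter.
#' @return A `grouped_design`; parameter names are `"variable=category"`.
#' @export
design_from_records <- function(records, variables) {
  cols <- list(); vars <- character(); cats <- character()
  for (v in variables) {
    x <- records[[v]]
    if (is.null(x)) abort(sprintf("no variable '%s' in records", v))
    for (lev in levels(x)[-1]) {
      if (!any(x == lev)) next
      cols[[paste0(v, "=", lev)]] <- as.integer(x == lev)
      vars <- c(vars, v); cats <- c(cats, lev)
    }
  }
  if (length(cols) == 0) abort("no non-reference categories to model")
  xm <- do.call(cbind, cols)
  key <- apply(xm, 1, paste, collapse = ",")
  groups <- split(seq_len(nrow(xm)), key)
  patt <- do.call(rbind, purrr::map(groups, ~ xm[.x[1], , drop = TRUE]))
  m <- purrr::map_int(groups, length)
  y <- purrr::map_int(groups, ~ sum(records$outcome[.x]))
  d <- grouped_design(patt, m, y, parameter_names = colnames(xm))
  d$variable <- vars
  d$category <- cats
  d
}

observed_statistics <- function(design) {
  c(total = sum(design$y), as.vector(t(design$x) %*% design$y))
}

#' Exact conditional distribution of one parameter's sufficient statistic
#'
#' Enumerates the distribution of the target parameter's sufficient
#' statistic T conditional on the observed values of all other sufficient
#' statistics (including the intercept's, the total event count). The joint
#' coefficients come from multiplying the per-group generating polynomials
#' `prod_j sum_k C(m_j, k) z^(k x_j) u^k`; the package carries their
#' logarithms and combines terms with log-sum-exp, so coefficients on the
#' scale of C(834, 11) are handled without overflow. Under a log odds ratio
#' `beta`, `P(T = t | beta)` is proportional to `c_t exp(beta t)`.
#'
#' @param design A `grouped_design`.
#' @param target Parameter index or name.
#' @return An object of class `cond_dist` with fields `parameter_name`,
#'   `support` (sorted integer values), `log_coef` (log c_t),
#'   `conditioning` (the fixed statistics), and `t_observed`.
#'   A single-point support is flagged `non_informative`.
#' @export
conditional_distribution <- function(design, target) {
  if (is.character(target)) target <- match(target, design$parameter_names)
  p <- ncol(design$x)
  if (is.na(target) || target < 1 || target > p) abort("unknown target parameter")
  t_obs <- observed_statistics(design)
  total <- t_obs[["total"]]
  # caps used to prune: non-target statistics can never exceed their
  # observed value in a retained term; the target never exceeds the total
  cap <- c(total, t_obs[-1])
  cap[1 + target] <- total

  states <- new.env(parent = emptyenv())
  assign(paste(rep(0L, p + 1), collapse = ","), 0, envir = states)
  for (j in seq_along(design$m)) {
    xj <- design$x[j, ]
    step <- c(1L, xj)
    nxt <- new.env(parent = emptyenv())
    keys <- ls(states)
    kmax_j <- min(design$m[j], total)
    for (key in keys) {
      s <- as.integer(strsplit(key, ",", fixed = TRUE)[[1]])
      lc <- get(key, envir = states)
      for (k in 0:kmax_j) {
        s2 <- s + k * step
        if (any(s2 > cap)) break
        key2 <- paste(s2, collapse = ",")
        add <- lc + lchoose(design$m[j], k)
        old <- if (exists(key2, envir = nxt, inherits = FALSE)) {
          get(key2, envir = nxt)
        } else {
          -Inf
        }
        mx <- max(old, add)
        assign(key2, mx + log1p(exp(min(old, add) - mx)), envir = nxt)
      }
    }
    states <- nxt
  }

  support <- integer(); log_coef <- numeric()
  want <- c(total, t_obs[-1])
  for (key in ls(states)) {
    s <- as.integer(strsplit(key, ",", fixed = TRUE)[[1]])
    if (all(s[-(1 + target)] == want[-(1 + target)])) {
      support <- c(support, s[1 + target])
      log_coef <- c(log_coef, get(key, envir = states))
    }
  }
  if (length(support) == 0) abort("degenerate conditioning: empty support")
  ord <- order(support)
  structure(
    list(
      parameter_name = design$parameter_names[target],
      support = support[ord],
      log_coef = log_coef[ord],
      conditioning = want[-(1 + target)],
      t_observed = unname(t_obs[1 + target]),
      non_informative = length(support) == 1
    ),
    class = "cond_dist"
  )
}

#' @export
print.cond_dist <- function(x, ...) {
  cat("<cond_dist> ", x$parameter_name, ": support {",
      min(x$support), "..", max(x$support), "}, t_observed = ",
      x$t_observed, "\n", sep = "")
  invisible(x)
}

#' Conditional probabilities P(T = t | beta)
#'
#' @param dist A `cond_dist`.
#' @param beta Log odds ratio (tilt parameter).
#' @return Probability vector over `dist$support`.
#' @export
cond_pmf <- function(dist, beta = 0) {
  lw <- dist$log_coef + beta * dist$support
  exp(lw - logsumexp(lw))
}

#' Conditional mean E(T | beta)
#' @param dist A `cond_dist`.
#' @param beta Log odds ratio.
#' @return The conditional expectation, strictly increasing in `beta`.
#' @export
cond_mean <- function(dist, beta = 0) {
  sum(dist$support * cond_pmf(dist, beta))
}

BETA_BRACKET <- 35

solve_beta <- function(f, what) {
  lo <- f(-BETA_BRACKET); hi <- f(BETA_BRACKET)
  if (sign(lo) == sign(hi)) {
    warn(sprintf("%s lies outside the search bracket; reporting boundary", what))
    return(if (abs(lo) < abs(hi)) -BETA_BRACKET else BETA_BRACKET)
  }
  uniroot(f, c(-BETA_BRACKET, BETA_BRACKET), tol = 1e-10)$root
}

#' Conditional maximum likelihood estimate
#'
#' Solves the conditional score equation `E(T | beta) = t_observed` for the
#' log odds ratio. Defined only when `t_observed` is interior to the support;
#' at a boundary the conditional likelihood is maximized at an infinite
#' `beta` and [mue()] applies instead.
#'
#' @param dist A `cond_dist`.
#' @param t_observed Observed sufficient statistic.
#' @return The log odds ratio estimate (exponentiate for the OR).
#' @export
cmle <- function(dist, t_observed) {
  check_t(dist, t_observed)
  if (t_observed %in% range(dist$support)) {
    abort("t_observed is at the support boundary; use mue()")
  }
  solve_beta(function(b) cond_mean(dist, b) - t_observed, "CMLE")
}

#' Median unbiased estimate
#'
#' The estimate used when the observed statistic sits at an end of its
#' support, where the conditional MLE is infinite: at the minimum it solves
#' `P(T <= t | beta) = 1/2`, at the maximum `P(T >= t | beta) = 1/2`. For an
#' interior `t` (on request) it returns the midpoint of the two tail
#' solutions.
#'
#' @param dist A `cond_dist`.
#' @param t_observed Observed sufficient statistic.
#' @return The log odds ratio estimate.
#' @export
mue <- function(dist, t_observed) {
  check_t(dist, t_observed)
  if (dist$non_informative) abort("single-point support: estimate undefined")
  lower_half <- function(b) sum(cond_pmf(dist, b)[dist$support <= t_observed]) - 0.5
  upper_half <- function(b) sum(cond_pmf(dist, b)[dist$support >= t_observed]) - 0.5
  if (t_observed == min(dist$support)) return(solve_beta(lower_half, "MUE"))
  if (t_observed == max(dist$support)) return(solve_beta(upper_half, "MUE"))
  (solve_beta(lower_half, "MUE") + solve_beta(upper_half, "MUE")) / 2
}

#' Exact equal-tail confidence interval on the odds-ratio scale
#'
#' Inverts the two exact tail tests: the lower limit solves
#' `P(T >= t | beta) = (1 - level)/2` and the upper limit solves
#' `P(T <= t | beta) = (1 - level)/2`. When `t` is at the support minimum the
#' lower limit is exactly 0; at the maximum the upper limit is infinite —
#' reproducing the `0 - U` style intervals reported for zero-event
#' categories.
#'
#' @param dist A `cond_dist`.
#' @param t_observed Observed sufficient statistic.
#' @param level Confidence level in (0, 1).
#' @return `c(ci_lower, ci_upper)` on the odds-ratio scale.
#' @export
exact_ci <- function(dist, t_observed, level = 0.95) {
  check_t(dist, t_observed)
  if (level <= 0 || level >= 1) abort("level must be in (0, 1)")
  a <- (1 - level) / 2
  lo <- if (t_observed == min(dist$support)) {
    0
  } else {
    exp(solve_beta(function(b) {
      sum(cond_pmf(dist, b)[dist$support >= t_observed]) - a
    }, "CI lower"))
  }
  hi <- if (t_observed == max(dist$support)) {
    Inf
  } else {
    exp(solve_beta(function(b) {
      sum(cond_pmf(dist, b)[dist$support <= t_observed]) - a
    }, "CI upper"))
  }
  c(ci_lower = lo, ci_upper = hi)
}

#' Exact two-sided p-value at the null odds ratio of 1
#'
#' The default "probability" method sums, under `beta = 0`, the null
#' probabilities of all support points no more probable than the observed
#' one. The "twice smaller tail" alternative doubles the smaller of the two
#' tail probabilities. Both are clipped to `[0, 1]`.
#'
#' @param dist A `cond_dist`.
#' @param t_observed Observed sufficient statistic.
#' @param method `"probability"` (default) or `"twice_smaller_tail"`.
#' @return The p-value.
#' @export
exact_p <- function(dist, t_observed,
                    method = c("probability", "twice_smaller_tail")) {
  check_t(dist, t_observed)
  method <- match.arg(method)
  p0 <- cond_pmf(dist, 0)
  p_obs <- p0[dist$support == t_observed]
  p <- if (method == "probability") {
    sum(p0[p0 <= p_obs * (1 + 1e-7)])
  } else {
    2 * min(sum(p0[dist$support <= t_observed]),
            sum(p0[dist$support >= t_observed]))
  }
  min(max(p, 0), 1)
}

check_t <- function(dist, t_observed) {
  if (!t_observed %in% dist$support) {
    abort("t_observed is not in the support of the conditional distribution")
  }
  invisible(TRUE)
}

#' Fit an exact conditional logistic regression
#'
#' For each parameter, builds the conditional distribution of its sufficient
#' statistic given all other parameters' observed statistics (and the total
#' event count), then reports the conditional MLE — or the median unbiased
#' estimate when the observed statistic sits at the support boundary — with
#' the exact equal-tail confidence interval and exact p-value. Used both for
#' crude fits (the dummies of a single variable) and multiple fits (several
#' variables jointly).
#'
#' @param design A `grouped_design`.
#' @param level Confidence level (default 0.95).
#' @param p_method Two-sided p-value convention, see [exact_p()].
#' @return An object of class `exact_logit_fit`. [tidy()] returns the
#'   per-parameter inference tibble; [glance()] the fit-level summary.
#'   Parameters whose conditional support is a single point are flagged
#'   `non_informative` with `NA` estimates rather than dropped.
#' @export
fit_exact_logit <- function(design, level = 0.95,
                            p_method = c("probability", "twice_smaller_tail")) {
  p_method <- match.arg(p_method)
  p <- ncol(design$x)
  rows <- purrr::map(seq_len(p), function(i) {
    d <- conditional_distribution(design, i)
    t <- d$t_observed
    base <- tibble::tibble(
      parameter = d$parameter_name,
      variable = (design$variable %||% rep(NA_character_, p))[i],
      category = (design$category %||% rep(NA_character_, p))[i],
      t_observed = t, t_min = min(d$support), t_max = max(d$support)
    )
    if (d$non_informative) {
      return(dplyr::mutate(base, estimate_kind = "non_informative",
                           odds_ratio = NA_real_, ci_lower = NA_real_,
                           ci_upper = NA_real_, p_value = NA_real_))
    }
    boundary <- t %in% range(d$support)
    beta <- if (boundary) mue(d, t) else cmle(d, t)
    ci <- exact_ci(d, t, level)
    dplyr::mutate(base,
      estimate_kind = if (boundary) "median_unbiased" else "cmle",
      odds_ratio = exp(beta),
      ci_lower = unname(ci[1]), ci_upper = unname(ci[2]),
      p_value = exact_p(d, t, p_method)
    )
  })
  inference <- dplyr::bind_rows(rows)[, c(
    "parameter", "variable", "category", "estimate_kind", "odds_ratio",
    "ci_lower", "ci_upper", "p_value", "t_observed", "t_min", "t_max"
  )]
  structure(
    list(inference = inference, design = design, level = level,
         p_method = p_method),
    class = "exact_logit_fit"
  )
}

#' @export
print.exact_logit_fit <- function(x, ...) {
  cat("Exact conditional logistic regression (", sum(x$design$m),
      " subjects, ", sum(x$design$y), " events)\n", sep = "")
  print(x$inference)
  invisible(x)
}

#' @rdname fit_exact_logit
#' @param x An `exact_logit_fit`.
#' @param ... Unused.
#' @export
tidy.exact_logit_fit <- function(x, ...) x$inference

#' @rdname fit_exact_logit
#' @export
glance.exact_logit_fit <- function(x, ...) {
  n <- sum(x$design$m); e <- sum(x$design$y)
  tibble::tibble(
    n = n, n_events = e,
    prevalence_percent = round_half_up(100 * e / n, 1),
    n_parameters = ncol(x$design$x),
    level = x$level, p_method = x$p_method
  )
}

#' Crude exact logistic fits for a set of count tables
#'
#' Fits one exact conditional logistic regression per variable from its
#' count table (all of a variable's dummies in one joint model, each dummy's
#' inference conditioning on the others).
#'
#' @param tables A named list of `count_table`s, e.g. from
#'   [load_table1_fixture()] or built with [build_count_table()].
#' @param ... Passed to [fit_exact_logit()].
#' @return A named list of `exact_logit_fit` objects.
#' @export
crude_fits <- function(tables, ...) {
  purrr::map(tables, function(tb) fit_exact_logit(design_from_counts(tb), ...))
}

#' Brute-force conditional distribution (small-sample oracle)
#'
#' Independent check of [conditional_distribution()]: enumerates every
#' assignment of the observed number of events to individual subjects,
#' keeps those matching the conditioning statistics, and tallies the target
#' statistic directly. Exponential in the cohort size, so it refuses more
#' than 25 subjects.
#'
#' @param x Per-subject 0/1 covariate matrix (subjects by parameters).
#' @param y Per-subject 0/1 outcomes.
#' @param target Parameter index.
#' @return A `cond_dist` with exactly enumerated (log) coefficients.
#' @export
brute_force_distribution <- function(x, y, target) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n > 25) abort("brute force refuses n > 25 subjects")
  if (length(y) != n || !all(y %in% c(0, 1))) abort("y must be 0/1 per subject")
  total <- sum(y)
  t_obs <- as.vector(t(x) %*% y)
  counts <- list()
  sets <- if (total == 0) list(integer(0)) else
    combn(n, total, simplify = FALSE)
  for (s in sets) {
    stats <- colSums(x[s, , drop = FALSE])
    if (all(stats[-target] == t_obs[-target])) {
      key <- as.character(stats[target])
      counts[[key]] <- (counts[[key]] %||% 0) + 1
    }
  }
  support <- as.integer(names(counts))
  ord <- order(support)
  structure(
    list(
      parameter_name = paste0("beta", target),
      support = support[ord],
      log_coef = log(as.numeric(unlist(counts)))[ord],
      conditioning = t_obs[-target],
      t_observed = t_obs[target],
      non_informative = length(support) == 1
    ),
    class = "cond_dist"
  )
}
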