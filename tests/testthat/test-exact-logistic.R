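test_that("a 2x2 layout gives the closed-form hypergeometric coefficients", {
  fx <- load_table1_fixture()
  d <- conditional_distribution(design_from_counts(fx$abortion_history), 1)
  expect_equal(d$support, 0:11)
  expect_equal(d$log_coef, lchoose(59, 0:11) + lchoose(834, 11 - 0:11),
               tolerance = 1e-10)
  expect_equal(d$t_observed, 4)
})

test_that("multi-category conditioning reduces to the two remaining groups", {
  fx <- load_table1_fixture()
  d <- conditional_distribution(design_from_counts(fx$marital_status), "unmarried")
  # 1 event fixed in not_answered and 6 in not_investigated leave 4 events
  # shared between married (423) and unmarried (27)
  expect_equal(d$support, 0:4)
  ratio <- d$log_coef - (lchoose(27, 0:4) + lchoose(423, 4 - 0:4))
  expect_equal(ratio, rep(ratio[1], 5), tolerance = 1e-10)
})

test_that("at beta = 0 the distribution is central hypergeometric", {
  d <- conditional_distribution(grouped_design(c(0, 1), m = c(30, 20), y = c(4, 3)), 1)
  # closed-form mean and variance of the central hypergeometric(50, 20, 7)
  N <- 50; K <- 20; n <- 7
  expect_equal(cond_mean(d, 0), n * K / N, tolerance = 1e-12)
  p <- cond_pmf(d, 0)
  v <- sum(d$support^2 * p) - cond_mean(d, 0)^2
  expect_equal(v, n * (K / N) * (1 - K / N) * (N - n) / (N - 1), tolerance = 1e-12)
  expect_equal(p, stats::dhyper(d$support, K, N - K, n), tolerance = 1e-12)
})

test_that("the conditional mean is strictly increasing in beta", {
  set.seed(42)
  for (rep in 1:20) {
    sd <- random_subject_design()
    des <- group_design_from_subjects(sd$x, sd$y)
    d <- conditional_distribution(des, sample(sd$p, 1))
    if (d$non_informative) next
    betas <- seq(-6, 6, length.out = 25)
    means <- vapply(betas, function(b) cond_mean(d, b), numeric(1))
    expect_true(all(diff(means) > 0))
  }
})

test_that("generating-function enumeration matches brute force on small designs", {
  set.seed(202)
  for (rep in 1:40) {
    sd <- random_subject_design()
    target <- sample(sd$p, 1)
    bf <- brute_force_distribution(sd$x, sd$y, target)
    gf <- conditional_distribution(group_design_from_subjects(sd$x, sd$y), target)
    expect_equal(gf$support, bf$support)
    expect_equal(exp(gf$log_coef), exp(bf$log_coef), tolerance = 1e-8)
    expect_equal(gf$t_observed, bf$t_observed)
  }
})

test_that("brute force handles forced single-subject supports and refuses large n", {
  one <- brute_force_distribution(matrix(1), y = 1, target = 1)
  expect_equal(one$support, 1L)
  expect_true(one$non_informative)
  expect_error(brute_force_distribution(matrix(rbinom(30, 1, 0.5)), rbinom(30, 1, 0.3), 1),
               "refuses")
})

test_that("the CMLE solves the conditional score equation", {
  d <- conditional_distribution(grouped_design(c(0, 1), m = c(10, 10), y = c(2, 2)), 1)
  expect_equal(exp(cmle(d, 2)), 1, tolerance = 1e-8)  # symmetric design

  tiny <- conditional_distribution(grouped_design(c(0, 1), m = c(4, 3), y = c(1, 2)), 1)
  expect_equal(cmle(tiny, 2), grid_cmle(tiny, 2), tolerance = 2e-4)

  expect_error(cmle(tiny, 3), "boundary")
  expect_error(cmle(tiny, 5), "not in the support")
})

test_that("median unbiased estimates are reciprocal under group swap", {
  a <- conditional_distribution(grouped_design(c(0, 1), m = c(12, 12), y = c(3, 0)), 1)
  b <- conditional_distribution(grouped_design(c(0, 1), m = c(12, 12), y = c(0, 3)), 1)
  expect_equal(mue(a, 0), -mue(b, 3), tolerance = 1e-8)
  single <- conditional_distribution(grouped_design(c(0, 1), m = c(5, 3), y = c(0, 0)), 1)
  expect_error(mue(single, 0), "single-point")
})

test_that("exact confidence intervals invert the tail tests", {
  tiny <- conditional_distribution(grouped_design(c(0, 1), m = c(6, 5), y = c(2, 3)), 1)
  ci <- exact_ci(tiny, 3)
  expect_equal(log(ci[["ci_lower"]]), grid_tail_root(tiny, 3, 0.025, "ge"),
               tolerance = 2e-3)
  expect_equal(log(ci[["ci_upper"]]), grid_tail_root(tiny, 3, 0.025, "le"),
               tolerance = 2e-3)
  # the interval brackets the CMLE and narrows as the level drops
  b <- cmle(tiny, 3)
  expect_true(ci[["ci_lower"]] < exp(b) && exp(b) < ci[["ci_upper"]])
  ci90 <- exact_ci(tiny, 3, level = 0.9)
  expect_true(ci90[["ci_lower"]] > ci[["ci_lower"]])
  expect_true(ci90[["ci_upper"]] < ci[["ci_upper"]])
  expect_error(exact_ci(tiny, 3, level = 1.2), "level")

  zero <- conditional_distribution(grouped_design(c(0, 1), m = c(20, 8), y = c(4, 0)), 1)
  expect_identical(exact_ci(zero, 0)[["ci_lower"]], 0)
  allev <- conditional_distribution(grouped_design(c(0, 1), m = c(20, 3), y = c(2, 3)), 1)
  expect_identical(exact_ci(allev, 3)[["ci_upper"]], Inf)
})

test_that("exact p-values match direct summation and respect conventions", {
  tiny <- conditional_distribution(grouped_design(c(0, 1), m = c(6, 5), y = c(2, 3)), 1)
  p0 <- cond_pmf(tiny, 0)
  p_obs <- p0[tiny$support == 3]
  expect_equal(exact_p(tiny, 3), sum(p0[p0 <= p_obs + 1e-12]), tolerance = 1e-9)
  expect_equal(exact_p(tiny, 3, "twice_smaller_tail"),
               min(1, 2 * min(sum(p0[tiny$support <= 3]), sum(p0[tiny$support >= 3]))),
               tolerance = 1e-9)

  # symmetric distribution observed at its mode: everything is "as extreme"
  sym <- conditional_distribution(grouped_design(c(0, 1), m = c(8, 8), y = c(2, 2)), 1)
  expect_equal(exact_p(sym, 2), 1)
})

test_that("fit_exact_logit reproduces the published crude smoking fit", {
  fx <- load_table1_fixture()
  inf <- tidy(fit_exact_logit(design_from_counts(fx$smoking)))
  expect_equal(inf$odds_ratio[inf$category == "yes"], 12.10, tolerance = 0.01)
  expect_equal(inf$odds_ratio[inf$category == "stopped_after_confirmation"],
               4.22, tolerance = 0.01)
  expect_equal(inf$estimate_kind, rep("cmle", 2))
})

test_that("degenerate designs are flagged, not fitted silently", {
  fit <- fit_exact_logit(grouped_design(c(0, 1), m = c(10, 5), y = c(0, 0)))
  expect_equal(fit$inference$estimate_kind, "non_informative")
  expect_true(is.na(fit$inference$odds_ratio))
})

test_that("exact interval coverage on 2x2 cohorts is at least nominal - slack", {
  set.seed(314)
  true_or <- 5
  n <- 400; p_exposed <- 0.3; p0 <- 0.05
  p1 <- plogis(qlogis(p0) + log(true_or))
  hits <- 0L; reps <- 120L
  for (r in seq_len(reps)) {
    m1 <- rbinom(1, n, p_exposed); m0 <- n - m1
    y1 <- rbinom(1, m1, p1); y0 <- rbinom(1, m0, p0)
    if (y0 + y1 == 0 || y0 + y1 == n) { hits <- hits + 1L; next }
    d <- conditional_distribution(grouped_design(c(0, 1), c(m0, m1), c(y0, y1)), 1)
    ci <- exact_ci(d, d$t_observed)
    if (ci[1] <= true_or && true_or <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.93)
})
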