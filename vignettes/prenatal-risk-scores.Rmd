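---
title: "Exact logistic regression and prenatal risk scores for sparse-event cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact logistic regression and prenatal risk scores for sparse-event cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prenatalrisk)
```

## The problem

Administrative registries of child maltreatment record very few events
relative to the cohorts they cover. The motivating setting is a Japanese
municipal cohort of 893 mother-child pairs followed from pregnancy
registration to the child's third birthday, in which 11 children (1.2%)
were registered with a Regional Council for Children Requiring Care
(RCCRC), the registry that serves as an objective proxy for a maltreatment
case. The predictors are categorical questionnaire items from the pregnancy
notification form (marital status, age band, smoking, abortion history, and
so on). With 11 events spread over many categories, ordinary
maximum-likelihood logistic regression is unreliable — several cells have
zero events and the Wald machinery degenerates — so the whole analysis
rests on *exact conditional* logistic regression, and on converting its
adjusted odds ratios into a small integer risk score that a public-health
nurse can compute by hand.

This vignette explains the model, the estimation conventions, the score
construction, the ROC evaluation, and the synthetic-cohort generator that
makes the pipeline testable without access to individual-level data, which
were never released.

## Exact conditional logistic regression

Group the subjects by their 0/1 dummy pattern: pattern $j$ has indicator
vector $x_j \in \{0,1\}^p$, size $m_j$ and event count $y_j$. Under the
logistic model the sufficient statistic for parameter $i$ is
$T_i = \sum_j y_j x_{ji}$, and for the intercept it is the total event
count $T_0 = \sum_j y_j$. Exact inference for one parameter uses the
distribution of its statistic *conditional on all the others*, which frees
the inference from the intercept and the nuisance parameters. The
conditional distribution is

$$P(T = t \mid \beta) = \frac{c_t e^{\beta t}}{\sum_s c_s e^{\beta s}},$$

where $\beta$ is the log odds ratio and $c_t$ counts the outcome
assignments consistent with the conditioning. The $c_t$ are read off the
product of per-group generating polynomials
$\prod_j \sum_{k=0}^{m_j} \binom{m_j}{k} z^{k x_j} u^k$, restricted to the
terms whose non-target statistics equal their observed values. For a
two-group (2×2) layout this reduces to the familiar noncentral
hypergeometric weights $c_t = \binom{m_1}{t}\binom{m_0}{T_0 - t}$.

`conditional_distribution()` performs this enumeration by dynamic
programming over groups. Coefficients on the scale of $\binom{834}{11}
\approx 10^{24}$ exceed exact double-precision integers, so the package
stores their logarithms (`lchoose`) and combines terms with log-sum-exp;
the relative error of this representation (about $10^{-14}$) is far below
the two-decimal reporting precision of any odds ratio. Terms whose partial
statistics already exceed an observed conditioning value are pruned, which
keeps the state space tiny even for cohort-sized groups. An independent
oracle, `brute_force_distribution()`, enumerates outcome assignments
subject-by-subject for up to 25 subjects; a property-style test holds the
two equal on randomized designs.

### Estimates, intervals, p-values

* **Conditional MLE** (`cmle()`): the $\beta$ solving
  $E(T \mid \beta) = t_{obs}$. The map $\beta \mapsto E(T\mid\beta)$ is
  strictly increasing, so the root is bracketed on $\beta \in [-35, 35]$
  (odds ratios from $e^{-35}$ to $e^{35}$) and refined to
  $|\Delta\beta| < 10^{-10}$ with `uniroot()`. A root outside the bracket
  is reported at the boundary with a warning.
* **Median unbiased estimate** (`mue()`): when $t_{obs}$ sits at an end of
  the support (a zero-event category, say) the conditional likelihood is
  maximized at $\beta = \pm\infty$; the MUE instead solves
  $P(T \le t_{obs} \mid \beta) = 1/2$ at the minimum (or the mirrored
  equation at the maximum), giving a finite, median-unbiased odds ratio.
* **Exact confidence interval** (`exact_ci()`): equal-tail inversion — the
  lower limit solves $P(T \ge t_{obs} \mid \beta) = \alpha/2$ and the upper
  limit the mirrored equation, with the lower limit defined as exactly 0
  when $t_{obs}$ is at the support minimum and the upper limit as
  $+\infty$ at the maximum. This convention reproduces, to the printed two
  decimals, every crude odds ratio and confidence limit of the published
  cohort (including the $0$–$U$ intervals of its zero-event categories), so
  it matches the convention of the original analysis software.
* **Exact p-value** (`exact_p()`): the default "probability method" sums
  the null probabilities of all support points no more probable than the
  observed one; a twice-smaller-tail variant is exposed as an option. The
  original report prints only significance markers, so the convention
  cannot be adjudicated from it; the probability method is the common
  default in exact-inference software.

Crude fits of a multi-category variable put all of its dummies in one joint
model and condition each dummy's inference on the others' observed
statistics; `fit_exact_logit()` does this uniformly for crude and multiple
fits and falls back from CMLE to MUE per parameter as the support dictates.
Parameters whose conditional support collapses to a single point are
reported as `non_informative` with `NA` estimates rather than dropped or
invented.

## From odds ratios to a score

The score machinery follows the published derivation pipeline:

1. **Selection** (`select_factors()`): a variable enters the multiple model
   when at least one of its categories has a 95% exact CI excluding 1.
   This is the reproducible operationalization of "statistically
   significant"; on the packaged count tables it selects exactly unmarried
   status, abortion history and smoking.
2. **Weighting** (`derive_weights()`): adjusted odds ratios are discretized
   by inclusive lower bounds — weight 3 for OR ≥ 10, weight 2 for
   5 ≤ OR < 10, weight 1 for OR < 5. The weight-1 band (rather than weight
   0) for small odds ratios follows the published score formula, which
   assigns 1 to adjusted ORs of 3.10 and 3.35; the formula is taken as
   authoritative over the looser prose describing the rule. An OR below 1
   still earns weight 1 but triggers a warning, since a protective category
   inflating a risk score deserves scrutiny.
3. **Scoring** (`score_cohort()`): a record's score is the sum of the
   weights of its matched (variable, category) terms. A merged category
   label such as `no/not_answered` matches either constituent, so formulas
   derived from merged tables score unmerged records directly. The
   published formula has maximum score 7.

Small "not answered" groups (fewer than 5 respondents) are pooled into the
reference category before fitting (`merge_small_not_answered()` on tables,
`collapse_small_not_answered()` on records; the two commute with
tabulation). "Not investigated" — an item a municipality never digitized —
is structural missingness, is never pooled, and is modelled as its own
category throughout.

## ROC evaluation

`classification_table()` classifies a record positive when its score
reaches the cutoff (`score >= c`), for every observed score value plus one
beyond the maximum, and reports sensitivity, specificity, correct
classification, PPV and NPV as percentages rounded half-up to one decimal
(full-precision fractions ride along in the `"raw"` attribute;
zero-denominator predictive values are `NA`). `roc_auc()` uses the
Mann-Whitney estimator with ties counted one half and a DeLong
structural-components variance for the normal-approximation CI, truncated
to $[0,1]$ only if it spills over — the original report does not state its
CI method, and DeLong is the standard choice. `select_cutoff()` maximizes
Youden's $J$ by default (ties toward the smaller cutoff); maximum correct
classification is exposed as an alternative because, on the published
classification rows, both criteria are defensible (Youden reproduces the
published choice of 2).

## The synthetic-cohort generator

Individual-level data were never released, so `generate_cohort()` draws
cohorts with the statistical structure the analysis assumes:

* **Marginals**: category probabilities default to the published cohort's
  category proportions among investigated records.
* **Structural missingness**: five municipalities with weights
  124/78/202/13/476 out of 893 and nested masking sets reproduce the
  published "not investigated" totals (417/893 for marital status, 326/893
  for pregnancy progress, passive smoking and disease history, 202/893 for
  worries/anxiety, 124/893 for the remainder). The assignment of masking
  sets to municipalities is a free choice constrained only by those totals,
  since municipality-level cross-tabulations were not published.
* **Outcome model**: a logistic model on the analysis categories, with
  default true effects mirroring the published adjusted structure
  (unmarried 12.14, abortion 5.82, smoking 5.30, and so on) and an
  intercept calibrated by `calibrate_intercept()` so the expected
  prevalence equals 11/893. The calibration enumerates the joint
  distribution of the linear predictor over municipalities and the
  effect-bearing covariates exactly, so no Monte-Carlo error enters; with
  no effects it is the closed-form logit of the target.
* **Raw records**: analysis categories are mapped back to raw
  questionnaire cells — an age drawn uniformly within its band (16–19,
  20–24, 25–39, 40–45), gestational weeks consistent with the
  late-registration indicator (5–11 versus 12–20), and a specific label
  from the pooled "unexpected" feelings — so generated cohorts exercise
  the full recoding path. Generation is byte-identical for a fixed seed.

What the generator deliberately does **not** emulate: the real joint
dependence between questionnaire items (covariates are drawn independently
given the municipality; real items such as marital status and smoking
correlate), cluster-level confounding beyond the masking structure, and
follow-up censoring. Tests passing on synthetic cohorts therefore validate
the *inferential machinery* — enumeration, estimation, coverage, scoring,
evaluation — not any epidemiological claim about real questionnaire data.
For the same reason the published multiple-regression odds ratios, AUC of
0.805 and per-cutoff classification rows are not reproducible from the
published marginals alone; the package reproduces them structurally on
synthetic data and numerically only where counts suffice (every crude
regression).

`recovery_experiment()` closes the loop: repeated generate-fit cycles
summarise median bias of the log odds ratio and empirical CI coverage per
parameter, flagging (rather than crashing on) degenerate replicates such as
zero-event cohorts.

## Numerical and design choices

* Log-domain generating-polynomial arithmetic (see above); no
  arbitrary-precision integers are needed at two-decimal reporting
  precision.
* Root bracket $[-35, 35]$ on the log-odds scale, `uniroot` tolerance
  $10^{-10}$; tail-inversion equations share the same bracket.
* Near-ties in the probability-method p-value are absorbed with a
  $1 + 10^{-7}$ relative slack so floating-point noise cannot drop an
  exactly-tied support point.
* Percentages are rounded half away from zero to one decimal for display
  (matching how such tables are conventionally printed); raw fractions are
  kept for computation.
* Simulation sizes used by the test suite — 200 randomized small designs
  for the enumeration/brute-force equivalence, 500 replicate 2×2 cohorts
  (n = 500, 30% exposure, 5% baseline prevalence, true OR 5) for the
  coverage check, and 200 replicates of n = 2000 at 5% prevalence for
  parameter recovery — were chosen as the smallest sizes at which the
  binomial noise of the checked proportions is comfortably below the
  asserted margins.
* Exact conditional CIs are conservative by construction, so nominal 95%
  intervals are checked against a 93% floor, leaving room for the
  simulation's own binomial noise without ever excusing undercoverage.

## Limitations

Exact enumeration is exponential in the number of *distinct covariate
patterns* carrying events; with 11 events and a handful of categorical
predictors it is instantaneous, but dense designs with many events call for
Markov-chain or saddlepoint approximations that are out of scope here. The
apparent AUC is reported without optimism correction, as in the original
analysis. And a risk score derived from 11 events, however carefully the
intervals are computed, carries the uncertainty its wide exact intervals
display — the package makes that uncertainty visible rather than making it
go away.
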