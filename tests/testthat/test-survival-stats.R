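make_22_cohort <- function(a, b, c_, d) {
  # a exposed/relapse, b exposed/no, c unexposed/relapse, d unexposed/no
  data.frame(flag = c(rep(1, a + b), rep(0, c_ + d)),
             relapse = c(rep(1, a), rep(0, b), rep(1, c_), rep(0, d)))
}

test_that("logistic odds ratio equals the 2x2 cross-product ratio", {
  co <- make_22_cohort(7, 2, 8, 38)
  est <- univariate_logistic(co, "flag")
  expect_equal(est$estimate, 7 * 38 / (2 * 8), tolerance = 1e-6)
  expect_false(est$degenerate)
  expect_true(est$ci95[1] <= est$estimate && est$estimate <= est$ci95[2])
  # sweep of further tables
  for (cells in list(c(5, 5, 5, 5), c(3, 9, 12, 20), c(10, 1, 2, 30))) {
    co2 <- make_22_cohort(cells[1], cells[2], cells[3], cells[4])
    expect_equal(univariate_logistic(co2, "flag")$estimate,
                 cells[1] * cells[4] / (cells[2] * cells[3]),
                 tolerance = 1e-5)
  }
})

test_that("separation and empty cells yield flagged degenerate estimates", {
  # no exposed patient relapsed -> OR 0
  co0 <- make_22_cohort(0, 6, 10, 30)
  e0 <- univariate_logistic(co0, "flag")
  expect_true(e0$degenerate)
  expect_equal(e0$estimate, 0)
  # every exposed patient relapsed -> OR Inf
  co1 <- make_22_cohort(6, 0, 10, 30)
  e1 <- univariate_logistic(co1, "flag")
  expect_true(e1$degenerate)
  expect_equal(e1$estimate, Inf)
  # constant predictor -> error
  co2 <- data.frame(flag = rep(1, 10), relapse = rep(0:1, 5))
  expect_error(univariate_logistic(co2, "flag"), "no variation")
})

test_that("AUC equals brute-force pair counting, including ties", {
  co <- data.frame(x = c(1, 2, 3, 4), relapse = c(0, 0, 1, 1))
  r <- roc_analysis(co, "x")
  expect_equal(r$auc, 1)
  expect_equal(r$youden_J, 1)
  expect_gt(r$threshold, 1.999)
  expect_lte(r$threshold, 3)
  expect_equal(r$sensitivity_at_threshold, 1)
  expect_equal(r$specificity_at_threshold, 1)

  tied <- data.frame(x = rep(5, 20), relapse = rep(0:1, 10))
  expect_equal(roc_analysis(tied, "x")$auc, 0.5)

  set.seed(13)
  for (rep in 1:5) {
    x <- round(rnorm(200), 1)   # induces ties
    y <- rbinom(200, 1, plogis(x))
    if (length(unique(y)) < 2) next
    co2 <- data.frame(x = x, relapse = y)
    expect_equal(roc_analysis(co2, "x")$auc, bf_auc(x, y), tolerance = 1e-12)
  }
  expect_error(roc_analysis(data.frame(x = 1:4, relapse = rep(1, 4)), "x"),
               "both outcome classes")
})

test_that("Youden threshold is consistent, deterministic, and monotone-invariant", {
  set.seed(17)
  x <- c(rnorm(30, 0), rnorm(20, 1.2))
  y <- c(rep(0, 30), rep(1, 20))
  co <- data.frame(x = x, relapse = y)
  r <- roc_analysis(co, "x")
  flag <- dichotomize(co, "x", r$threshold)
  expect_equal(mean(flag[y == 1]), r$sensitivity_at_threshold)
  expect_equal(1 - mean(flag[y == 0]), r$specificity_at_threshold)
  expect_equal(attr(flag, "n_above") + attr(flag, "n_below"), 50)

  # strictly monotone transform: J and AUC unchanged, threshold maps
  co2 <- data.frame(x = exp(x), relapse = y)
  r2 <- roc_analysis(co2, "x")
  expect_equal(r2$auc, r$auc, tolerance = 1e-12)
  expect_equal(r2$youden_J, r$youden_J, tolerance = 1e-12)
  expect_equal(r2$threshold, exp(r$threshold), tolerance = 1e-12)
})

test_that("dichotomize handles boundary thresholds", {
  co <- data.frame(x = 1:10)
  all_false <- dichotomize(co, "x", 11)
  expect_equal(sum(all_false), 0)
  med <- dichotomize(co, "x", median(co$x))
  expect_equal(sum(med), 5)
  expect_error(dichotomize(co, "x", Inf), "finite")
})

test_that("Cox estimates maximize the written-out partial likelihood", {
  # hand-computable 4-subject dataset with events in both exposure groups
  co <- data.frame(followup_months = 1:4, relapse = c(1, 1, 1, 0),
                   x = c(1, 0, 1, 0))
  fit <- cox_fit(co, "x")
  bf <- bf_cox_mle(co$followup_months, co$relapse, co$x)
  expect_equal(log(fit$x$estimate), bf, tolerance = 1e-5)

  # random no-tie datasets up to 6 subjects
  set.seed(19)
  for (rep in 1:20) {
    n <- sample(4:6, 1)
    co2 <- data.frame(followup_months = sample(seq(1, 40), n),
                      relapse = rbinom(n, 1, 0.7),
                      x = rbinom(n, 1, 0.5))
    # skip draws without events in both exposure groups (monotone
    # partial likelihood: no interior maximum to compare)
    if (length(unique(co2$x)) < 2 ||
        length(unique(co2$x[co2$relapse == 1])) < 2) next
    f2 <- tryCatch(suppressWarnings(cox_fit(co2, "x")),
                   error = function(e) NULL)
    if (is.null(f2)) next
    b <- log(f2$x$estimate)
    if (abs(b) > 7) next
    expect_equal(b, bf_cox_mle(co2$followup_months, co2$relapse, co2$x),
                 tolerance = 1e-4)
  }
  expect_error(cox_fit(data.frame(followup_months = 1:4, relapse = rep(0, 4),
                                  x = c(1, 1, 0, 0)), "x"), "no events")
})

test_that("Kaplan-Meier reproduces the empirical survival function without censoring", {
  co <- data.frame(followup_months = c(1, 2, 3), relapse = c(1, 1, 1),
                   g = c(0, 0, 0))
  km <- kaplan_meier(co, "g")
  expect_equal(km$curves[["0"]]$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(unname(km$rmst["0"]), 2)   # (1 + 2 + 3) / 3

  # no events: curve stays at 1, RMST equals the largest time
  co2 <- data.frame(followup_months = c(5, 8, 11), relapse = c(0, 0, 0),
                    g = c(1, 1, 1))
  km2 <- kaplan_meier(co2, "g")
  expect_true(all(km2$curves[["1"]]$surv == 1))
  expect_equal(unname(km2$rmst["1"]), 11)

  # property: curves non-increasing, in [0, 1]
  co3 <- simulate_cohort(cohort_sim_spec(n_patients = 80, seed = 23))
  km3 <- kaplan_meier(co3, "cystic_component")
  for (cv in km3$curves) {
    expect_true(all(diff(cv$surv) <= 1e-12))
    expect_true(all(cv$surv >= 0 & cv$surv <= 1))
  }
})

test_that("log-rank matches brute-force observed/expected summation", {
  # identical groups, relabeled: chi-square exactly 0
  base <- data.frame(followup_months = c(2, 4, 6, 8), relapse = c(1, 0, 1, 1))
  dup <- rbind(cbind(base, g = 0), cbind(base, g = 1))
  lr <- log_rank(dup, "g")
  expect_equal(lr$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1, tolerance = 1e-12)

  # hand-computable 6-subject example
  co <- data.frame(followup_months = c(1, 3, 5, 2, 4, 6),
                   relapse = c(1, 1, 0, 1, 1, 1),
                   g = c(1, 1, 1, 0, 0, 0))
  expect_equal(log_rank(co, "g")$chi_square,
               bf_logrank_chisq(co$followup_months, co$relapse, co$g),
               tolerance = 1e-10)

  # random cohorts
  set.seed(29)
  for (rep in 1:10) {
    co2 <- simulate_cohort(cohort_sim_spec(n_patients = 60,
                                           baseline_hazard_per_month = 0.01,
                                           seed = 600 + rep))
    if (length(unique(co2$cystic_component)) < 2 || sum(co2$relapse) == 0)
      next
    expect_equal(log_rank(co2, "cystic_component")$chi_square,
                 bf_logrank_chisq(co2$followup_months, co2$relapse,
                                  co2$cystic_component),
                 tolerance = 1e-8)
  }
  expect_error(log_rank(cbind(base, g = 1), "g"), "two")
})

test_that("cohort summary reports printed-style percentages", {
  co <- simulate_cohort(cohort_sim_spec(n_patients = 76, seed = 31))
  s <- cohort_summary(co)
  expect_equal(s$n, 76)
  expect_equal(s$relapse_pct, round(100 * sum(co$relapse) / 76, 1))
  expect_equal(s$pct_complete_resection,
               round(100 * sum(co$simpson_grade <= 2) / 76, 1))
  expect_equal(sum(s$localization_pct), 100, tolerance = 0.2)
  # empty strata report as 0
  co$localization <- "convexity_falx"
  s2 <- cohort_summary(co)
  expect_equal(unname(s2$localization_pct["ventricular"]), 0)
  expect_error(cohort_summary(co[0, ]), "empty")
})
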