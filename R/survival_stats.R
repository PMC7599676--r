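# The statistical chain: univariate logistic screening with odds ratios,
# ROC/Youden dichotomization, Cox proportional-hazards models (Efron ties,
# via the survival package), Kaplan-Meier curves with log-rank tests, and
# cohort summary tables.

effect_estimate <- function(kind, term, estimate, ci_lo, ci_hi, p_value,
                            n_used, degenerate = FALSE) {
  structure(list(kind = kind, term = term, estimate = estimate,
                 ci95 = c(ci_lo, ci_hi), p_value = p_value, n_used = n_used,
                 degenerate = degenerate),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  lab <- if (x$kind == "odds_ratio") "OR" else "HR"
  cat(sprintf("%s: %s %.3g (95%% CI %.3g-%.3g), p = %.3g, n = %d%s\n",
              x$term, lab, x$estimate, x$ci95[1], x$ci95[2], x$p_value,
              x$n_used, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Univariate logistic regression for a binary outcome
#'
#' Maximum-likelihood logistic fit with intercept; the odds ratio is
#' `exp(beta)` with a Wald 95% CI. For a binary predictor this equals the
#' 2x2 cross-product ratio. Complete separation or an empty cell is detected
#' from the 2x2 table and reported as a degenerate estimate (0 or Inf) with
#' the `degenerate` flag set, rather than as a spuriously finite fit.
#'
#' @param cohort cohort data.frame.
#' @param predictor name of the predictor column (binary flag or
#'   dichotomized feature).
#' @param outcome name of the binary outcome column (default `"relapse"`).
#' @return an `effect_estimate` of kind `odds_ratio`.
#' @export
univariate_logistic <- function(cohort, predictor, outcome = "relapse") {
  x <- cohort[[predictor]]
  y <- cohort[[outcome]]
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 2L)
    stop("no variation in predictor '", predictor, "'")
  is_binary <- all(x %in% c(0, 1))
  if (is_binary) {
    a <- sum(x == 1 & y == 1); b <- sum(x == 1 & y == 0)
    c_ <- sum(x == 0 & y == 1); d <- sum(x == 0 & y == 0)
    if (min(a, b, c_, d) == 0) {
      est <- if (a == 0 || d == 0) 0 else Inf
      if (a > 0 && d > 0 && (b == 0 || c_ == 0)) est <- Inf
      return(effect_estimate("odds_ratio", predictor, est, NA_real_, NA_real_,
                             NA_real_, length(x), degenerate = TRUE))
    }
  }
  fit <- stats::glm(y ~ x, family = stats::binomial())
  beta <- stats::coef(fit)[["x"]]
  se <- sqrt(stats::vcov(fit)["x", "x"])
  z <- beta / se
  effect_estimate("odds_ratio", predictor, exp(beta),
                  exp(beta - 1.96 * se), exp(beta + 1.96 * se),
                  2 * stats::pnorm(-abs(z)), length(x))
}

#' ROC analysis with Youden-index threshold selection
#'
#' AUC is the Mann-Whitney probability (mean-rank form, tie-corrected) that
#' a random positive scores above a random negative. The threshold is the
#' observed feature value maximizing Youden's J = sensitivity +
#' specificity - 1 under the rule `positive if feature > threshold`; ties in
#' J are broken toward the lower threshold so reports are deterministic.
#' The p-value is the two-sided Wilcoxon rank-sum test of the two outcome
#' groups.
#'
#' @param cohort cohort data.frame.
#' @param feature name of the continuous feature column.
#' @param outcome name of the binary outcome column.
#' @return a `roc_analysis` list: `auc`, `p_value`, `threshold`,
#'   `sensitivity_at_threshold`, `specificity_at_threshold`, `youden_J`,
#'   `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(cohort, feature, outcome = "relapse") {
  x <- cohort[[feature]]
  y <- cohort[[outcome]]
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L)
    stop("both outcome classes must be present for ROC analysis")
  r <- rank(x)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  pv <- suppressWarnings(stats::wilcox.test(x[y == 1], x[y == 0])$p.value)
  thr_cand <- sort(unique(x))
  sens <- vapply(thr_cand, function(t) mean(x[y == 1] > t), numeric(1))
  spec <- vapply(thr_cand, function(t) mean(x[y == 0] <= t), numeric(1))
  J <- sens + spec - 1
  best <- which(J >= max(J) - 1e-12)[1]   # lowest maximizing threshold
  structure(list(auc = auc, p_value = pv, threshold = thr_cand[best],
                 sensitivity_at_threshold = sens[best],
                 specificity_at_threshold = spec[best],
                 youden_J = J[best], n_pos = n1, n_neg = n0),
            class = "roc_analysis")
}

#' Dichotomize a continuous feature at a threshold
#'
#' @param cohort cohort data.frame.
#' @param feature name of the continuous feature column.
#' @param threshold finite cutoff; the flag is `feature > threshold`.
#' @return integer 0/1 vector with attributes `threshold`, `n_above`,
#'   `n_below`.
#' @export
dichotomize <- function(cohort, feature, threshold) {
  if (!is.finite(threshold)) stop("'threshold' must be finite")
  x <- cohort[[feature]]
  flag <- as.integer(x > threshold)
  structure(flag, threshold = threshold,
            n_above = sum(flag == 1L, na.rm = TRUE),
            n_below = sum(flag == 0L, na.rm = TRUE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit with Efron tie handling (via
#' [survival::coxph()]), returning one hazard-ratio estimate with Wald 95%
#' CI per coefficient.
#'
#' @param cohort cohort data.frame.
#' @param covariates character vector of covariate column names.
#' @param time name of the follow-up time column (months).
#' @param event name of the event indicator column.
#' @return list of `effect_estimate`s of kind `hazard_ratio`, one per model
#'   coefficient, with the fitted `coxph` object attached as attribute
#'   `"fit"`.
#' @export
cox_fit <- function(cohort, covariates, time = "followup_months",
                    event = "relapse") {
  if (length(covariates) < 1L) stop("at least one covariate is required")
  dat <- cohort[, c(time, event, covariates), drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (sum(dat[[event]]) < 1) stop("no events: cannot fit a Cox model")
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time, ", ", event, ") ~ ",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "efron",
                         control = survival::coxph.control(iter.max = 100,
                                                           eps = 1e-9))
  if (fit$iter >= 100)
    stop("Cox fit did not converge in 100 iterations (final gradient not ",
         "at tolerance); check covariates for separation or collinearity")
  beta <- stats::coef(fit)
  if (any(is.na(beta)))
    stop("collinear covariates: ", paste(names(beta)[is.na(beta)],
                                         collapse = ", "))
  se <- sqrt(diag(stats::vcov(fit)))
  out <- lapply(seq_along(beta), function(i) {
    b <- unname(beta[i]); s <- unname(se[i])
    effect_estimate("hazard_ratio", names(beta)[i], exp(b),
                    exp(b - 1.96 * s), exp(b + 1.96 * s),
                    2 * stats::pnorm(-abs(b / s)), nrow(dat))
  })
  names(out) <- names(beta)
  attr(out, "fit") <- fit
  out
}

#' Kaplan-Meier curves by group, with restricted mean survival time
#'
#' Product-limit estimates per group. The "mean" survival per group is the
#' restricted mean survival time (RMST): the area under the KM curve up to
#' the largest observed follow-up time across the whole cohort, the
#' convention of common clinical software when the curve does not reach
#' zero.
#'
#' @param cohort cohort data.frame.
#' @param group name of a binary (or factor) grouping column.
#' @param time,event follow-up and event column names.
#' @return a `km_analysis` list: per-group `curves` (data.frame time,
#'   n_risk, n_event, surv), `rmst` (named vector), `tau` (RMST horizon).
#' @export
kaplan_meier <- function(cohort, group, time = "followup_months",
                         event = "relapse") {
  dat <- cohort[, c(time, event, group), drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  g <- factor(dat[[group]])
  if (any(table(g) == 0L) || nlevels(g) < 1L || nrow(dat) == 0L)
    stop("every group must contain at least one subject")
  tau <- max(dat[[time]])
  fit <- survival::survfit(
    stats::as.formula(paste0("survival::Surv(", time, ", ", event, ") ~ g")),
    data = cbind(dat, g = g))
  strata_names <- if (is.null(fit$strata)) levels(g) else
    sub("^g=", "", names(fit$strata))
  idx <- if (is.null(fit$strata)) rep(1L, length(fit$time)) else
    rep(seq_along(fit$strata), fit$strata)
  curves <- list(); rmst <- numeric(0)
  for (k in seq_along(strata_names)) {
    sel <- idx == k
    curves[[strata_names[k]]] <- data.frame(time = fit$time[sel],
                                            n_risk = fit$n.risk[sel],
                                            n_event = fit$n.event[sel],
                                            surv = fit$surv[sel])
    rmst[strata_names[k]] <- rmst_step(fit$time[sel], fit$surv[sel], tau)
  }
  structure(list(curves = curves, rmst = rmst, tau = tau, group = group),
            class = "km_analysis")
}

# Area under a right-continuous KM step function from 0 to tau.
rmst_step <- function(times, surv, tau) {
  t_all <- c(0, times[times <= tau], tau)
  s_all <- c(1, surv[times <= tau])
  sum(diff(t_all) * s_all)
}

#' Two-group log-rank test
#'
#' Standard one-degree-of-freedom log-rank statistic
#' (via [survival::survdiff()]).
#'
#' @inheritParams kaplan_meier
#' @return list with `chi_square` and `p_value`.
#' @export
log_rank <- function(cohort, group, time = "followup_months",
                     event = "relapse") {
  dat <- cohort[, c(time, event, group), drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  g <- factor(dat[[group]])
  if (nlevels(droplevels(g)) != 2L)
    stop("log-rank test requires exactly two non-empty groups")
  if (sum(dat[[event]]) < 1) stop("no events: log-rank test undefined")
  sd_ <- survival::survdiff(
    stats::as.formula(paste0("survival::Surv(", time, ", ", event, ") ~ g")),
    data = cbind(dat, g = droplevels(g)))
  chi <- sd_$chisq
  list(chi_square = chi, p_value = stats::pchisq(chi, df = 1,
                                                 lower.tail = FALSE))
}

#' Cohort summary table
#'
#' N, mean age (SD), percentage of women, tumor localization, Simpson grade
#' and postoperative radiation percentages (1 decimal), and relapse N (%).
#' Empty strata are reported as 0%.
#'
#' @param cohort cohort data.frame.
#' @return a `cohort_summary` list.
#' @export
cohort_summary <- function(cohort) {
  if (nrow(cohort) == 0L) stop("empty cohort")
  n <- nrow(cohort)
  pct <- function(k) round(100 * k / n, 1)
  loc_levels <- c("convexity_falx", "skull_base", "ventricular")
  loc <- vapply(loc_levels, function(l)
    pct(sum(cohort$localization == l, na.rm = TRUE)), numeric(1))
  simpson <- vapply(1:4, function(gr)
    pct(sum(cohort$simpson_grade == gr, na.rm = TRUE)), numeric(1))
  names(simpson) <- paste0("grade_", 1:4)
  relapse_n <- sum(cohort$relapse, na.rm = TRUE)
  structure(list(
    n = n,
    mean_age = round(mean(cohort$age, na.rm = TRUE), 1),
    sd_age = round(stats::sd(cohort$age, na.rm = TRUE), 1),
    pct_women = pct(sum(cohort$sex == "f", na.rm = TRUE)),
    localization_pct = loc,
    simpson_pct = simpson,
    pct_complete_resection = pct(sum(cohort$simpson_grade <= 2, na.rm = TRUE)),
    pct_radiation = pct(sum(cohort$postop_radiation, na.rm = TRUE)),
    relapse_n = relapse_n,
    relapse_pct = pct(relapse_n)), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort of", x$n, "patients\n")
  cat(sprintf("  Age %0.1f (SD %0.1f); women %0.1f%%\n",
              x$mean_age, x$sd_age, x$pct_women))
  cat("  Localization (%):",
      paste(names(x$localization_pct), x$localization_pct, collapse = ", "),
      "\n")
  cat("  Simpson grade (%):", paste(x$simpson_pct, collapse = "/"),
      sprintf(" (complete resection %0.1f%%)\n", x$pct_complete_resection))
  cat(sprintf("  Postoperative radiation %0.1f%%; relapse %d (%0.1f%%)\n",
              x$pct_radiation, x$relapse_n, x$relapse_pct))
  invisible(x)
}
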