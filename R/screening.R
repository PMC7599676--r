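# The full screening procedure: univariate screening of semantic flags and
# radiomic features, Youden dichotomization of promising continuous
# features, multivariate models for recurrence and progression-free
# survival, and KM/log-rank for the leading semantic feature.

#' The 11 semantic imaging flags
#' @return character vector of column names.
#' @export
semantic_feature_names <- function() {
  c("intra_tumoral_heterogeneity", "multifocality", "midline_shift",
    "sinus_invasion", "necrosis_hemorrhage", "mass_effect",
    "cystic_component", "bone_invasion", "hyperostosis", "spiculation",
    "edema")
}

#' Screening configuration
#'
#' @param univariate_p significance cutoff for a semantic flag to advance to
#'   the multivariate model (default 0.05).
#' @param auc_p rank-test cutoff for a continuous radiomic feature to be
#'   dichotomized and advanced (default 0.10, admitting predictive trends).
#' @param recurrence_model `"cox"` (default; time-to-recurrence hazard
#'   ratios) or `"logistic"` for the multivariate recurrence model.
#' @param adjust_p `"none"` (default, single-cohort screening convention) or
#'   `"BH"` for Benjamini-Hochberg adjustment of the univariate p-values
#'   before selection.
#' @return named list of options.
#' @export
screening_config <- function(univariate_p = 0.05, auc_p = 0.10,
                             recurrence_model = c("cox", "logistic"),
                             adjust_p = c("none", "BH")) {
  list(univariate_p = univariate_p, auc_p = auc_p,
       recurrence_model = match.arg(recurrence_model),
       adjust_p = match.arg(adjust_p))
}

#' Run the univariate -> Youden -> multivariate screening procedure
#'
#' Stages: (1) univariate logistic odds ratio of relapse for every semantic
#' flag; (2) ROC analysis of every continuous radiomic feature; (3) features
#' passing the selection rule (semantic p < `univariate_p`; radiomic
#' rank-test p <= `auc_p`) are dichotomized at the Youden threshold and
#' advanced; (4) multivariate recurrence model (Cox by default) on the
#' advanced features; (5) PFS analysis: univariate Cox per clinical/advanced
#' covariate, then a multivariate Cox on the significant ones plus resection
#' completeness; (6) KM curves and log-rank test for the leading semantic
#' feature. Dichotomization thresholds are always derived from the cohort at
#' hand: absolute cutoffs are tied to the feature scale and quantization and
#' do not transfer across pipelines.
#'
#' @param cohort cohort data.frame (see [simulate_cohort()] for the schema);
#'   may contain merged radiomic feature columns.
#' @param semantic character vector of semantic flag columns present in
#'   `cohort` (default: the 11 standard flags, filtered to those present).
#' @param radiomic character vector of continuous radiomic feature columns
#'   (default `"cluster_prominence"`, filtered to those present).
#' @param config a [screening_config()].
#' @return a `screening_report` list with elements `cohort_summary`,
#'   `univariate_semantic`, `roc_radiomic`, `advanced`, `thresholds`,
#'   `multivariate_recurrence`, `pfs_univariate`, `pfs_multivariate`,
#'   `km`, `log_rank`, and per-analysis n.
#' @export
run_screening_procedure <- function(cohort,
                                    semantic = semantic_feature_names(),
                                    radiomic = "cluster_prominence",
                                    config = screening_config()) {
  if (nrow(cohort) == 0L) stop("empty cohort")
  semantic <- intersect(semantic, names(cohort))
  radiomic <- intersect(radiomic, names(cohort))

  # (1) univariate logistic per semantic flag
  uni <- list()
  for (s in semantic) {
    uni[[s]] <- tryCatch(univariate_logistic(cohort, s),
                         error = function(e) NULL)
  }
  uni <- Filter(Negate(is.null), uni)

  # (2) ROC per radiomic feature
  roc <- list()
  for (f in radiomic) {
    roc[[f]] <- tryCatch(roc_analysis(cohort, f), error = function(e) NULL)
  }
  roc <- Filter(Negate(is.null), roc)

  # (3) selection + Youden dichotomization
  p_sem <- vapply(uni, function(e)
    if (e$degenerate) NA_real_ else e$p_value, numeric(1))
  p_rad <- vapply(roc, function(r) r$p_value, numeric(1))
  if (identical(config$adjust_p, "BH")) {
    adj <- stats::p.adjust(c(p_sem, p_rad), method = "BH")
    p_sem <- adj[seq_along(p_sem)]
    p_rad <- adj[seq_along(p_rad) + length(p_sem)]
  }
  adv_sem <- names(uni)[!is.na(p_sem) & p_sem < config$univariate_p]
  adv_rad <- names(roc)[!is.na(p_rad) & p_rad <= config$auc_p]

  work <- cohort
  thresholds <- list()
  adv_rad_cols <- character(0)
  for (f in adv_rad) {
    thr <- roc[[f]]$threshold
    col <- paste0("high_", f)
    work[[col]] <- as.integer(dichotomize(work, f, thr))
    thresholds[[f]] <- thr
    adv_rad_cols <- c(adv_rad_cols, col)
  }
  advanced <- c(adv_sem, adv_rad_cols)

  # (4) multivariate recurrence model on advanced features
  multi_rec <- NULL
  if (length(advanced) >= 1L) {
    multi_rec <- tryCatch({
      if (identical(config$recurrence_model, "logistic")) {
        lapply(stats::setNames(advanced, advanced), function(v) {
          fit <- stats::glm(stats::reformulate(sprintf("`%s`", advanced),
                                               response = "relapse"),
                            data = work, family = stats::binomial())
          b <- stats::coef(fit)[make.names(v)]
          se <- sqrt(diag(stats::vcov(fit)))[make.names(v)]
          effect_estimate("odds_ratio", v, exp(b), exp(b - 1.96 * se),
                          exp(b + 1.96 * se), 2 * stats::pnorm(-abs(b / se)),
                          nrow(work))
        })
      } else {
        cox_fit(work, advanced)
      }
    }, error = function(e) structure(list(error = conditionMessage(e)),
                                     class = "failed_fit"))
  }

  # (5) PFS: univariate Cox per covariate, multivariate on significant +
  # resection completeness
  work$convexity_falx <- as.integer(work$localization == "convexity_falx")
  work$age_over_65 <- as.integer(work$age > 65)
  work$female <- as.integer(work$sex == "f")
  pfs_covs <- intersect(c("complete_resection", "convexity_falx", "female",
                          "age_over_65", "postop_radiation",
                          adv_sem, adv_rad_cols),
                        names(work))
  pfs_uni <- list()
  for (v in pfs_covs) {
    pfs_uni[[v]] <- tryCatch(cox_fit(work, v)[[1]], error = function(e) NULL)
  }
  pfs_uni <- Filter(Negate(is.null), pfs_uni)
  sig_pfs <- names(pfs_uni)[vapply(pfs_uni, function(e)
    is.finite(e$p_value) && e$p_value < config$univariate_p, logical(1))]
  pfs_multi_covs <- unique(c("complete_resection", sig_pfs))
  pfs_multi <- tryCatch(cox_fit(work, pfs_multi_covs),
                        error = function(e)
                          structure(list(error = conditionMessage(e)),
                                    class = "failed_fit"))

  # (6) KM + log-rank for the leading semantic feature
  top_sem <- if (length(p_sem) && any(!is.na(p_sem)))
    names(uni)[which.min(p_sem)] else NULL
  km <- lr <- NULL
  if (!is.null(top_sem) && length(unique(work[[top_sem]])) == 2L) {
    km <- tryCatch(kaplan_meier(work, top_sem), error = function(e) NULL)
    lr <- tryCatch(log_rank(work, top_sem), error = function(e) NULL)
  }

  structure(list(
    cohort_summary = cohort_summary(cohort),
    univariate_semantic = uni,
    roc_radiomic = roc,
    advanced = advanced,
    thresholds = thresholds,
    multivariate_recurrence = multi_rec,
    pfs_univariate = pfs_uni,
    pfs_multivariate = pfs_multi,
    top_semantic = top_sem,
    km = km, log_rank = lr,
    n_total = nrow(cohort),
    config = config), class = "screening_report")
}

effects_to_df <- function(effs) {
  if (is.null(effs) || inherits(effs, "failed_fit")) return(NULL)
  do.call(rbind, lapply(effs, function(e)
    data.frame(term = e$term, kind = e$kind, estimate = e$estimate,
               ci_lo = e$ci95[1], ci_hi = e$ci95[2], p_value = e$p_value,
               n = e$n_used, degenerate = e$degenerate,
               stringsAsFactors = FALSE)))
}

#' Serialize a screening report
#'
#' @param report a `screening_report`.
#' @param json_path,text_path output file paths (either may be `NULL`).
#' @return invisibly, the report.
#' @export
write_screening_report <- function(report, json_path = NULL,
                                   text_path = NULL) {
  stopifnot(inherits(report, "screening_report"))
  if (!is.null(json_path)) {
    ser <- list(
      n_total = report$n_total,
      cohort_summary = unclass(report$cohort_summary),
      univariate_semantic = effects_to_df(report$univariate_semantic),
      roc_radiomic = lapply(report$roc_radiomic, unclass),
      advanced = report$advanced,
      thresholds = report$thresholds,
      multivariate_recurrence = effects_to_df(report$multivariate_recurrence),
      pfs_univariate = effects_to_df(report$pfs_univariate),
      pfs_multivariate = effects_to_df(report$pfs_multivariate),
      top_semantic = report$top_semantic,
      log_rank = report$log_rank,
      rmst = if (!is.null(report$km)) as.list(report$km$rmst))
    jsonlite::write_json(ser, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  if (!is.null(text_path)) {
    con <- file(text_path, "w")
    on.exit(close(con))
    sink(con)
    print(report)
    sink()
  }
  invisible(report)
}

#' @export
print.screening_report <- function(x, ...) {
  print(x$cohort_summary)
  cat("\nUnivariate semantic screening (odds ratios for relapse):\n")
  for (e in x$univariate_semantic) print(e)
  cat("\nROC analysis of radiomic features:\n")
  for (f in names(x$roc_radiomic)) {
    r <- x$roc_radiomic[[f]]
    cat(sprintf("  %s: AUC %.3f (p = %.3g), Youden threshold %.4g (sens %.2f, spec %.2f)\n",
                f, r$auc, r$p_value, r$threshold,
                r$sensitivity_at_threshold, r$specificity_at_threshold))
  }
  cat("\nAdvanced to multivariate:",
      if (length(x$advanced)) paste(x$advanced, collapse = ", ") else "none",
      "\n")
  if (!is.null(x$multivariate_recurrence) &&
      !inherits(x$multivariate_recurrence, "failed_fit")) {
    cat("\nMultivariate recurrence model:\n")
    for (e in x$multivariate_recurrence) print(e)
  }
  cat("\nPFS univariate (Cox):\n")
  for (e in x$pfs_univariate) print(e)
  if (!inherits(x$pfs_multivariate, "failed_fit")) {
    cat("\nPFS multivariate (Cox):\n")
    for (e in x$pfs_multivariate) print(e)
  }
  if (!is.null(x$log_rank))
    cat(sprintf("\nLog-rank by %s: chi2 = %.3f, p = %.3g; RMST %s months\n",
                x$top_semantic, x$log_rank$chi_square, x$log_rank$p_value,
                paste(sprintf("%s: %.1f", names(x$km$rmst), x$km$rmst),
                      collapse = ", ")))
  invisible(x)
}
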