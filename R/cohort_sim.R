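# Simulated patient cohorts. Time to recurrence follows proportional hazards
# with an exponential baseline; administrative censoring is uniform over the
# follow-up window. Effect sizes default to the multivariate hazard ratios
# the analysis is designed to detect (20.21 for cystic component, 5.89 for
# the high-cluster-prominence phenotype); the follow-up window (3, 168)
# months matches a cohort with mean follow-up around 41.6 months.

#' Specify a simulated cohort
#'
#' @param n_patients number of patients (>= 2).
#' @param prevalence_cystic probability of the cystic-component phenotype.
#' @param prevalence_high_cp probability of the high-cluster-prominence
#'   phenotype (independent of cystic).
#' @param hr_cystic hazard ratio of recurrence for cystic tumors.
#' @param hr_high_cp hazard ratio for the high-cluster-prominence phenotype.
#' @param baseline_hazard_per_month exponential baseline hazard (events per
#'   month) for unexposed patients.
#' @param censor_window_months length-2 (min, max) of the uniform
#'   administrative censoring window in months.
#' @param seed integer RNG seed.
#' @return a `cohort_sim_spec` list.
#' @export
cohort_sim_spec <- function(n_patients = 76L,
                            prevalence_cystic = 0.16,
                            prevalence_high_cp = 0.25,
                            hr_cystic = 20.21,
                            hr_high_cp = 5.89,
                            baseline_hazard_per_month = 0.0008,
                            censor_window_months = c(3, 168),
                            seed = 1L) {
  if (n_patients < 2) stop("'n_patients' must be at least 2")
  for (p in c(prevalence_cystic, prevalence_high_cp))
    if (p < 0 || p > 1) stop("prevalences must lie in [0, 1]")
  if (hr_cystic <= 0 || hr_high_cp <= 0) stop("hazard ratios must be positive")
  if (baseline_hazard_per_month < 0) stop("baseline hazard must be >= 0")
  if (length(censor_window_months) != 2L ||
      censor_window_months[1] <= 0 ||
      censor_window_months[2] < censor_window_months[1])
    stop("'censor_window_months' must be (min, max) with 0 < min <= max")
  structure(list(n_patients = as.integer(n_patients),
                 prevalence_cystic = prevalence_cystic,
                 prevalence_high_cp = prevalence_high_cp,
                 hr_cystic = hr_cystic, hr_high_cp = hr_high_cp,
                 baseline_hazard_per_month = baseline_hazard_per_month,
                 censor_window_months = as.numeric(censor_window_months),
                 seed = as.integer(seed)),
            class = "cohort_sim_spec")
}

#' Simulate a patient cohort under proportional hazards
#'
#' Each patient draws the cystic and high-cluster-prominence phenotypes
#' independently; the recurrence time is exponential with hazard
#' `baseline * hr_cystic^cystic * hr_high_cp^highCP`; censoring is uniform
#' over the window and the observed follow-up is the minimum of the two.
#' Clinical covariates (age, sex, localization, Simpson grade, postoperative
#' radiation) and the remaining semantic flags are drawn at frequencies
#' typical of an atypical-meningioma surgical cohort and carry no effect on
#' outcome. A continuous `cluster_prominence` surrogate (log-normal, shifted
#' upward for the high-CP phenotype) supports threshold-screening analyses
#' that do not run image extraction.
#'
#' @param spec a [cohort_sim_spec()].
#' @return a `data.frame` (the cohort table) with one row per patient: id,
#'   clinical covariates, the 11 semantic flags, the true phenotype flags,
#'   true event/censor times, observed `followup_months` and `relapse`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$seed)
  n <- spec$n_patients

  cystic <- stats::rbinom(n, 1, spec$prevalence_cystic)
  high_cp <- stats::rbinom(n, 1, spec$prevalence_high_cp)
  hazard <- spec$baseline_hazard_per_month *
    spec$hr_cystic^cystic * spec$hr_high_cp^high_cp
  event_time <- ifelse(hazard > 0, stats::rexp(n, rate = pmax(hazard, 1e-300)),
                       Inf)
  event_time[hazard == 0] <- Inf
  censor_time <- stats::runif(n, spec$censor_window_months[1],
                              spec$censor_window_months[2])
  followup <- pmin(event_time, censor_time)
  relapse <- as.integer(event_time <= censor_time)

  age <- round(pmin(pmax(stats::rnorm(n, 58.7, 13.8), 12), 81), 1)
  sex <- ifelse(stats::runif(n) < 0.592, "f", "m")
  localization <- sample(c("convexity_falx", "skull_base", "ventricular"),
                         n, replace = TRUE, prob = c(0.592, 0.395, 0.013))
  simpson_grade <- sample(1:4, n, replace = TRUE,
                          prob = c(0.711, 0.145, 0.079, 0.053) / 0.988)
  semantic_prev <- c(intra_tumoral_heterogeneity = 0.25, multifocality = 0.05,
                     midline_shift = 0.25, sinus_invasion = 0.15,
                     necrosis_hemorrhage = 0.30, mass_effect = 0.45,
                     bone_invasion = 0.20, hyperostosis = 0.20,
                     spiculation = 0.15, edema = 0.50)
  sem <- lapply(semantic_prev, function(p) stats::rbinom(n, 1, p))
  cp_value <- exp(stats::rnorm(n, mean = log(6e4) + 0.9 * high_cp, sd = 0.7))

  out <- data.frame(
    id = sprintf("P%03d", seq_len(n)),
    age = age, sex = sex, localization = localization,
    simpson_grade = simpson_grade,
    complete_resection = as.integer(simpson_grade <= 2),
    postop_radiation = stats::rbinom(n, 1, 0.289),
    stringsAsFactors = FALSE)
  for (nm in names(sem)) out[[nm]] <- sem[[nm]]
  out$cystic_component <- cystic
  out$high_cp_true <- high_cp
  out$cluster_prominence <- cp_value
  out$true_event_time <- event_time
  out$censor_time <- censor_time
  out$followup_months <- followup
  out$relapse <- relapse
  out
}

#' Build a paired image + outcome fixture
#'
#' Couples the simulated cohort flags to phantom generation: cystic patients
#' get cystic phantoms; high-cluster-prominence patients get a long texture
#' correlation length (smooth, strongly clustered intensity, which raises
#' co-occurrence cluster prominence), other patients a short one. Per-patient
#' phantom seeds derive deterministically from the fixture seed.
#'
#' @param n number of patients.
#' @param seed integer RNG seed.
#' @param sim_spec optional [cohort_sim_spec()] template (its `n_patients`
#'   and `seed` are overridden).
#' @param phantom_template optional [phantom_spec()] template supplying grid
#'   geometry and intensity settings.
#' @param corr_low,corr_high texture correlation lengths (mm) assigned to
#'   the low and high cluster-prominence phenotypes.
#' @return list with `cohort` (data.frame) and `phantoms` (list of
#'   [generate_phantom()] outputs, one per patient, in cohort row order).
#' @export
generate_end_to_end_fixture <- function(n, seed = 1L, sim_spec = NULL,
                                        phantom_template = NULL,
                                        corr_low = 0.6, corr_high = 3) {
  if (n < 1) stop("'n' must be at least 1")
  if (is.null(sim_spec)) sim_spec <- cohort_sim_spec()
  sim_spec$n_patients <- as.integer(max(n, 2))
  sim_spec$seed <- as.integer(seed)
  cohort <- simulate_cohort(sim_spec)
  cohort <- cohort[seq_len(n), , drop = FALSE]
  if (is.null(phantom_template)) phantom_template <- phantom_spec()
  phantoms <- vector("list", n)
  for (i in seq_len(n)) {
    ps <- phantom_template
    ps$cystic <- cohort$cystic_component[i] == 1L
    ps$texture_correlation_mm <-
      if (cohort$high_cp_true[i] == 1L) corr_high else corr_low
    ps$seed <- as.integer((as.numeric(seed) * 10007 + i) %% 2147483647)
    phantoms[[i]] <- generate_phantom(ps)
  }
  list(cohort = cohort, phantoms = phantoms)
}
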