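# Pipeline orchestration: simulate a fixture to disk, extract features from
# image/mask pairs, and run the screening analysis. Each step stamps its
# outputs with the configuration hash and seed so reruns are verifiable.
# Analyses use the maximal available subset: patients without usable imaging
# are retained for the clinical/semantic analyses and only dropped from
# feature-based ones, with per-analysis n reported.

#' Pipeline run configuration
#'
#' @param output_dir directory for all outputs.
#' @param image_dir,mask_dir directories holding `<id>_image.nii.gz` /
#'   `<id>_mask.nii.gz` pairs (defaults: under `output_dir`).
#' @param cohort_csv path of the cohort table.
#' @param n_patients fixture size for [run_simulate()].
#' @param seed integer seed recorded in every output.
#' @param features a [feature_config()].
#' @param screening a [screening_config()].
#' @param radiomic_feature continuous feature advanced to ROC screening
#'   (default the original-channel cluster prominence).
#' @return a `run_config` list.
#' @export
run_config <- function(output_dir,
                       image_dir = file.path(output_dir, "images"),
                       mask_dir = image_dir,
                       cohort_csv = file.path(output_dir, "cohort.csv"),
                       n_patients = 20L,
                       seed = 1L,
                       features = feature_config(),
                       screening = screening_config(),
                       radiomic_feature = "original__cluster_prominence") {
  structure(list(output_dir = output_dir, image_dir = image_dir,
                 mask_dir = mask_dir, cohort_csv = cohort_csv,
                 n_patients = as.integer(n_patients), seed = as.integer(seed),
                 features = features, screening = screening,
                 radiomic_feature = radiomic_feature),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized keys mirror the arguments of [run_config()],
#' [feature_config()] and [screening_config()]; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  y <- yaml::read_yaml(path)
  known <- c("output_dir", "image_dir", "mask_dir", "cohort_csv",
             "n_patients", "seed", "features", "screening",
             "radiomic_feature")
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (is.null(y$output_dir)) stop("config must set 'output_dir'")
  args <- y
  if (!is.null(y$features)) args$features <- do.call(feature_config, y$features)
  if (!is.null(y$screening))
    args$screening <- do.call(screening_config, y$screening)
  do.call(run_config, args)
}

config_hash <- function(config) digest::digest(unclass(config), algo = "sha1")

stamp <- function(config) {
  list(seed = config$seed, config_sha1 = config_hash(config),
       package_version = as.character(utils::packageVersion("meningrisk")))
}

#' Simulate a phantom/cohort fixture to disk
#'
#' Writes one NIfTI image/mask pair per patient, the cohort CSV, and a
#' ground-truth JSON (true phenotype flags, seed, config hash). Deterministic
#' per seed.
#'
#' @param config a [run_config()].
#' @param ... passed to [generate_end_to_end_fixture()] (e.g.
#'   `phantom_template`).
#' @return invisibly, the fixture list.
#' @export
run_simulate <- function(config, ...) {
  stopifnot(inherits(config, "run_config"))
  if (config$n_patients < 1L) stop("'n_patients' must be at least 1")
  for (d in unique(c(config$output_dir, config$image_dir, config$mask_dir))) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(d)) stop("cannot create output directory: ", d)
  }
  fix <- generate_end_to_end_fixture(config$n_patients, seed = config$seed,
                                     ...)
  for (i in seq_len(nrow(fix$cohort))) {
    id <- fix$cohort$id[i]
    write_volume_pair(fix$phantoms[[i]]$grid, fix$phantoms[[i]]$mask,
                      file.path(config$image_dir, paste0(id, "_image.nii.gz")),
                      file.path(config$mask_dir, paste0(id, "_mask.nii.gz")))
  }
  utils::write.csv(fix$cohort, config$cohort_csv, row.names = FALSE)
  truth <- lapply(seq_len(nrow(fix$cohort)), function(i)
    c(list(id = fix$cohort$id[i]), fix$phantoms[[i]]$ground_truth))
  jsonlite::write_json(list(stamp = stamp(config), ground_truth = truth),
                       file.path(config$output_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(fix)
}

#' Extract radiomic features for every case with usable imaging
#'
#' Iterates the cohort ids, reading `<id>_image` / `<id>_mask` NIfTI pairs.
#' Failures on individual cases (missing or corrupt files, empty masks) are
#' logged and collected, not fatal — those patients keep their clinical and
#' semantic data and are simply absent from the feature table. Writes wide
#' (one row per patient) and long (patient, channel, feature, value) CSVs.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `wide` and `long` data.frames and
#'   `failures` (named character vector of per-case error messages).
#' @export
run_extract <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!file.exists(config$cohort_csv))
    stop("cohort table not found: ", config$cohort_csv)
  cohort <- utils::read.csv(config$cohort_csv, stringsAsFactors = FALSE)
  wide_rows <- list(); long_rows <- list(); failures <- character(0)
  for (id in cohort$id) {
    img <- file.path(config$image_dir, paste0(id, "_image.nii.gz"))
    msk <- file.path(config$mask_dir, paste0(id, "_mask.nii.gz"))
    res <- tryCatch({
      pair <- read_volume_pair(img, msk)
      extract_features(pair$grid, pair$mask, config = config$features)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[id] <- conditionMessage(res)
      message("skipping ", id, ": ", conditionMessage(res))
      next
    }
    wide_rows[[id]] <- data.frame(id = id, t(res$wide), check.names = FALSE,
                                  stringsAsFactors = FALSE)
    long_rows[[id]] <- cbind(id = id, res$long)
  }
  if (!length(wide_rows))
    stop("no valid cases: every image/mask pair failed extraction")
  wide <- do.call(rbind, wide_rows)
  long <- do.call(rbind, long_rows)
  rownames(wide) <- rownames(long) <- NULL
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(wide, file.path(config$output_dir, "features_wide.csv"),
                   row.names = FALSE)
  utils::write.csv(long, file.path(config$output_dir, "features_long.csv"),
                   row.names = FALSE)
  jsonlite::write_json(c(stamp(config),
                         list(n_extracted = nrow(wide),
                              failures = as.list(failures))),
                       file.path(config$output_dir, "extract_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(wide = wide, long = long, failures = failures))
}

#' Run the screening analysis on extracted features plus the cohort table
#'
#' Joins the feature table onto the cohort by id (left join: patients
#' without imaging stay in for clinical-only analyses) and runs
#' [run_screening_procedure()]. Writes `report.json` and `report.txt`.
#'
#' @param config a [run_config()].
#' @param features optional wide feature data.frame (defaults to the CSV
#'   written by [run_extract()]).
#' @return invisibly, the `screening_report`.
#' @export
run_analyze <- function(config, features = NULL) {
  stopifnot(inherits(config, "run_config"))
  cohort <- utils::read.csv(config$cohort_csv, stringsAsFactors = FALSE)
  if (is.null(features)) {
    fpath <- file.path(config$output_dir, "features_wide.csv")
    if (!file.exists(fpath)) stop("feature table not found: ", fpath)
    features <- utils::read.csv(fpath, stringsAsFactors = FALSE,
                                check.names = FALSE)
  }
  merged <- merge(cohort, features, by = "id", all.x = TRUE, sort = TRUE)
  if (nrow(merged) == 0L) stop("join of cohort and feature tables is empty")
  feat <- config$radiomic_feature
  if (!feat %in% names(merged))
    stop("requested feature column '", feat, "' is missing from the ",
         "feature table")
  report <- run_screening_procedure(merged, radiomic = feat,
                                    config = config$screening)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  write_screening_report(report,
                         json_path = file.path(config$output_dir,
                                               "report.json"),
                         text_path = file.path(config$output_dir,
                                               "report.txt"))
  jsonlite::write_json(stamp(config),
                       file.path(config$output_dir, "analyze_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Simulate, extract and analyze in one call
#'
#' @param config a [run_config()].
#' @param ... passed to [run_simulate()].
#' @return invisibly, the `screening_report`.
#' @export
run_all <- function(config, ...) {
  run_simulate(config, ...)
  run_extract(config)
  run_analyze(config)
}
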