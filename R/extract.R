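#' The 13 radiomic feature names
#'
#' First-order: mean, median, minimum, skewness. Shape: spherical
#' disproportion (original channel only). Co-occurrence: cluster prominence,
#' difference entropy, inverse difference normalized. Run-length: run-length
#' non-uniformity, short-run low gray-level emphasis. Size-zone:
#' high-intensity large area emphasis, low-intensity large area emphasis,
#' low-intensity small area emphasis.
#'
#' @return character vector of the 13 snake_case feature names.
#' @export
radiomic_feature_names <- function() {
  c("mean", "median", "minimum", "skewness", "spherical_disproportion",
    "cluster_prominence", "difference_entropy", "inverse_difference_normalized",
    "run_length_nonuniformity", "short_run_low_gray_emphasis",
    "high_intensity_large_area_emphasis", "low_intensity_large_area_emphasis",
    "low_intensity_small_area_emphasis")
}

#' Default feature-extraction configuration
#'
#' @param ng_levels gray levels for discretization (default 32).
#' @param target_spacing_mm isotropic resampling target (default 1 mm).
#' @param log_sigmas_mm LoG scales in mm (default 3).
#' @param wavelet_enabled include the 8 wavelet subband channels.
#' @param glrlm_aggregate run-length direction policy, `"sum"` or `"mean"`.
#' @return named list of configuration values.
#' @export
feature_config <- function(ng_levels = 32L, target_spacing_mm = 1,
                           log_sigmas_mm = 3, wavelet_enabled = TRUE,
                           glrlm_aggregate = "sum") {
  list(ng_levels = as.integer(ng_levels),
       target_spacing_mm = target_spacing_mm,
       log_sigmas_mm = log_sigmas_mm,
       wavelet_enabled = isTRUE(wavelet_enabled),
       glrlm_aggregate = glrlm_aggregate)
}

#' Extract the radiomic feature set from one image/mask pair
#'
#' Resamples to isotropic spacing, builds the filter channels (original, LoG,
#' wavelet subbands), discretizes each channel over the mask and computes the
#' 13 features per channel. The shape feature (spherical disproportion)
#' depends only on the mask and is reported for the original channel alone.
#'
#' @param grid a [voxel_grid].
#' @param mask the paired [roi_mask].
#' @param channels optional precomputed channel list from
#'   [filter_channels()]; by default built from `config`. Supplying channels
#'   skips resampling, so the grid must already be isotropic.
#' @param config a [feature_config()].
#' @return an object of class `radiomic_feature_set`: list with `wide` (named
#'   numeric vector, names `channel__feature`) and `long` (data.frame with
#'   columns channel, feature, value).
#' @export
extract_features <- function(grid, mask, channels = NULL,
                             config = feature_config()) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(mask, "roi_mask"))
  if (is.null(channels)) {
    rs <- resample_isotropic(grid, mask, config$target_spacing_mm)
    grid <- rs$grid
    mask <- rs$mask
    channels <- filter_channels(grid, log_sigmas_mm = config$log_sigmas_mm,
                                wavelet = config$wavelet_enabled)
  }
  rows <- list()
  for (ch in channels) {
    vals <- tryCatch(
      channel_features(ch$grid, mask, config,
                       with_shape = identical(ch$name, "original")),
      error = function(e)
        stop("feature extraction failed on channel '", ch$name, "': ",
             conditionMessage(e), call. = FALSE))
    rows[[ch$name]] <- data.frame(channel = ch$name, feature = names(vals),
                                  value = unname(vals),
                                  stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, rows)
  rownames(long) <- NULL
  wide <- stats::setNames(long$value, paste0(long$channel, "__", long$feature))
  structure(list(wide = wide, long = long), class = "radiomic_feature_set")
}

channel_features <- function(cgrid, mask, config, with_shape = FALSE) {
  fo <- first_order(cgrid, mask)
  disc <- discretize(cgrid, mask, config$ng_levels)
  g <- compute_glcm(disc, mask)
  r <- compute_glrlm(disc, mask, aggregate = config$glrlm_aggregate)
  s <- compute_glszm(disc, mask)
  out <- c(mean = fo$mean, median = fo$median, minimum = fo$minimum,
           skewness = fo$skewness)
  if (with_shape)
    out <- c(out, spherical_disproportion = spherical_disproportion(mask))
  c(out,
    cluster_prominence = cluster_prominence(g),
    difference_entropy = difference_entropy(g),
    inverse_difference_normalized = inverse_difference_normalized(g),
    run_length_nonuniformity = run_length_nonuniformity(r),
    short_run_low_gray_emphasis = short_run_low_gray_emphasis(r),
    high_intensity_large_area_emphasis = high_intensity_large_area_emphasis(s),
    low_intensity_large_area_emphasis = low_intensity_large_area_emphasis(s),
    low_intensity_small_area_emphasis = low_intensity_small_area_emphasis(s))
}
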