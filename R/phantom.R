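# Phantom tumor volumes: an ellipsoidal "tumor" with a correlated intensity
# texture, optional central cystic subregion, and additive noise. These stand
# in for contrast-enhanced T1 volumes with manual segmentations so the
# extraction pipeline can be validated end to end. They are synthetic: no
# MRI physics (bias fields, partial volume, multi-sequence contrast) is
# modeled.

#' Specify a phantom tumor volume
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param spacing_mm voxel size per axis in mm.
#' @param tumor_radii_mm ellipsoid semi-axes in mm.
#' @param base_intensity mean tumor intensity (arbitrary units).
#' @param noise_sd additive white Gaussian noise SD.
#' @param texture_correlation_mm correlation length of the Gaussian random
#'   field giving the tumor its intensity texture (Gaussian white noise
#'   convolved with a Gaussian kernel of this width, then rescaled to
#'   `texture_sd`); 0 disables the textured component.
#' @param texture_sd amplitude (SD) of the correlated texture field.
#' @param cystic logical; add a central hypointense cystic subregion.
#' @param cyst_radius_frac cyst radius as a fraction of the smallest tumor
#'   semi-axis (in (0, 1)).
#' @param cyst_intensity_frac cyst mean intensity as a fraction of
#'   `base_intensity`.
#' @param seed integer RNG seed.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(48L, 48L, 48L),
                         spacing_mm = c(1, 1, 1),
                         tumor_radii_mm = c(14, 12, 10),
                         base_intensity = 300,
                         noise_sd = 15,
                         texture_correlation_mm = 1.5,
                         texture_sd = 60,
                         cystic = FALSE,
                         cyst_radius_frac = 0.5,
                         cyst_intensity_frac = 0.3,
                         seed = 1L) {
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (texture_correlation_mm < 0) stop("'texture_correlation_mm' must be >= 0")
  if (texture_sd < 0) stop("'texture_sd' must be >= 0")
  if (isTRUE(cystic) && (cyst_radius_frac <= 0 || cyst_radius_frac >= 1))
    stop("'cyst_radius_frac' must lie strictly between 0 and 1")
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing_mm = as.numeric(spacing_mm),
                 tumor_radii_mm = as.numeric(tumor_radii_mm),
                 base_intensity = base_intensity, noise_sd = noise_sd,
                 texture_correlation_mm = texture_correlation_mm,
                 texture_sd = texture_sd, cystic = isTRUE(cystic),
                 cyst_radius_frac = cyst_radius_frac,
                 cyst_intensity_frac = cyst_intensity_frac,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a phantom tumor volume
#'
#' Builds the ellipsoidal tumor mask, fills it (and the background) with
#' `base + correlated texture field + white noise`, and, for cystic
#' phantoms, lowers the mean intensity inside a central sphere to
#' `cyst_intensity_frac * base_intensity`. Identical seeds give bit-identical
#' volumes.
#'
#' @param spec a [phantom_spec()].
#' @return list with `grid` ([voxel_grid]), `mask` ([roi_mask]) and
#'   `ground_truth` (list recording the cystic flag and texture correlation
#'   length).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  sp <- spec$spacing_mm
  rad_vox <- spec$tumor_radii_mm / sp
  ax_names <- c("x", "y", "z")
  for (ax in 1:3) {
    # ellipsoid centered on the grid plus a 2-voxel margin must fit
    if ((d[ax] - 1) / 2 < rad_vox[ax] + 2)
      stop("tumor exceeds grid along ", ax_names[ax], " axis: semi-axis ",
           spec$tumor_radii_mm[ax], " mm (", round(rad_vox[ax], 1),
           " voxels) does not fit in ", d[ax], " voxels with a 2-voxel margin")
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$seed)

  center <- (d + 1) / 2
  cx <- (seq_len(d[1]) - center[1]) * sp[1]
  cy <- (seq_len(d[2]) - center[2]) * sp[2]
  cz <- (seq_len(d[3]) - center[3]) * sp[3]
  r <- spec$tumor_radii_mm
  ell <- outer(outer((cx / r[1])^2, (cy / r[2])^2, "+"), (cz / r[3])^2, "+")
  mask_arr <- ell <= 1

  vals <- array(spec$base_intensity, dim = d)
  if (spec$cystic) {
    cyst_r <- spec$cyst_radius_frac * min(r)
    dist2 <- outer(outer(cx^2, cy^2, "+"), cz^2, "+")
    vals[dist2 <= cyst_r^2] <- spec$cyst_intensity_frac * spec$base_intensity
  }
  if (spec$texture_correlation_mm > 0 && spec$texture_sd > 0) {
    field <- array(stats::rnorm(prod(d)), dim = d)
    field <- smooth_gaussian(field, sp, spec$texture_correlation_mm)
    field <- field / stats::sd(field) * spec$texture_sd
    vals <- vals + field
  }
  if (spec$noise_sd > 0)
    vals <- vals + array(stats::rnorm(prod(d), sd = spec$noise_sd), dim = d)

  grid <- voxel_grid(vals, spacing_mm = sp)
  list(grid = grid, mask = roi_mask(mask_arr, grid),
       ground_truth = list(cystic = spec$cystic,
                           texture_correlation_mm = spec$texture_correlation_mm))
}
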