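#' Voxel grids and region-of-interest masks
#'
#' A `voxel_grid` is a 3D scalar lattice with physical voxel spacing and an
#' origin, the container for a contrast-enhanced T1 volume or any filtered
#' channel derived from it. A `roi_mask` is a binary lattice aligned with its
#' grid, holding a segmented tumor volume.
#'
#' @param values numeric 3D array of voxel intensities (finite).
#' @param spacing_mm numeric length-3, strictly positive voxel size in mm.
#' @param origin_mm numeric length-3 physical position of the first voxel
#'   center, in mm.
#' @return `voxel_grid()` returns an object of class `voxel_grid`;
#'   `roi_mask()` an object of class `roi_mask`.
#' @examples
#' g <- voxel_grid(array(rnorm(8), c(2, 2, 2)), spacing_mm = c(1, 1, 1))
#' m <- roi_mask(array(1, c(2, 2, 2)), g)
#' @export
voxel_grid <- function(values, spacing_mm = c(1, 1, 1), origin_mm = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array")
  if (!all(is.finite(values)))
    stop("voxel values must all be finite")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("'spacing_mm' must be 3 strictly positive values")
  origin_mm <- as.numeric(origin_mm)
  if (length(origin_mm) != 3L) stop("'origin_mm' must have length 3")
  structure(list(values = values, spacing_mm = spacing_mm, origin_mm = origin_mm),
            class = "voxel_grid")
}

#' @param mask array of mask values (any nonzero voxel is foreground), or a
#'   logical array.
#' @param grid the `voxel_grid` the mask is aligned with.
#' @rdname voxel_grid
#' @export
roi_mask <- function(mask, grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("'mask' must be a 3D array")
  if (!identical(dim(mask), dim(grid$values)))
    stop("mask shape ", paste(dim(mask), collapse = "x"),
         " does not match image shape ", paste(dim(grid$values), collapse = "x"))
  vals <- array(as.integer(mask != 0), dim = dim(mask))
  structure(list(values = vals, spacing_mm = grid$spacing_mm,
                 origin_mm = grid$origin_mm),
            class = "roi_mask")
}

#' @rdname voxel_grid
#' @param x object to test or print.
#' @export
is_isotropic <- function(x) {
  s <- x$spacing_mm
  isTRUE(max(abs(s - s[1])) < 1e-9 * max(s))
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("voxel_grid:", paste(dim(x$values), collapse = " x "),
      "voxels, spacing", paste(signif(x$spacing_mm, 4), collapse = " x "), "mm\n")
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("roi_mask:", paste(dim(x$values), collapse = " x "),
      "voxels,", sum(x$values), "foreground\n")
  invisible(x)
}

n_foreground <- function(mask) sum(mask$values != 0L)

assert_nonempty_mask <- function(mask, n_min = 1L) {
  n <- n_foreground(mask)
  if (n < 1L) stop("mask has no foreground voxels")
  if (n < 27L)
    warning("ROI has only ", n, " voxels (< 27); texture statistics are ",
            "defined but unstable", call. = FALSE)
  invisible(n)
}
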