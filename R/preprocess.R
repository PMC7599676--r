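# Preprocessing: isotropic resampling, gray-level discretization, and the
# convolution machinery shared by the filter channels. All boundary handling
# is mirror (symmetric) reflection so filter responses stay usable for masks
# that approach the volume border.

# Map arbitrary integer indices onto 1..n by symmetric reflection
# (edge voxel included once per reflection, scipy "reflect" convention).
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * n)
  ifelse(j < n, j + 1L, 2L * n - j)
}

# 1D convolution along one axis of a 3D array, mirror padding, kernel of odd
# length centered on the voxel.
conv_axis <- function(a, kern, axis) {
  d <- dim(a)
  n <- d[axis]
  K <- (length(kern) - 1L) %/% 2L
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(a, perm), nrow = n)
  idx <- reflect_index(seq.int(1L - K, n + K), n)
  mp <- m[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (t in seq_along(kern))
    out <- out + kern[t] * mp[t:(t + n - 1L), , drop = FALSE]
  aperm(array(out, d[perm]), order(perm))
}

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-0.5 * ((-r:r) / sigma_vox)^2)
  k / sum(k)
}

# Separable Gaussian smoothing; sigma in mm is converted to voxels per axis.
smooth_gaussian <- function(values, spacing_mm, sigma_mm) {
  out <- values
  for (ax in 1:3) {
    k <- gaussian_kernel_1d(sigma_mm / spacing_mm[ax])
    if (length(k) > 1L) out <- conv_axis(out, k, ax)
  }
  out
}

#' Resample an image/mask pair to isotropic voxel spacing
#'
#' Direction-consistent 3D texture offsets assume cubic voxels, so volumes
#' are resampled before feature extraction. The image is linearly
#' interpolated (separable, axis by axis, equivalent to trilinear); the mask
#' is resampled nearest-neighbor so it stays strictly binary. An input
#' already at the target spacing passes through unchanged.
#'
#' @param grid a [voxel_grid].
#' @param mask the paired [roi_mask].
#' @param target_mm target isotropic spacing in mm (default 1).
#' @return a list with resampled `grid` and `mask`.
#' @export
resample_isotropic <- function(grid, mask, target_mm = 1) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(mask, "roi_mask"))
  if (!is.numeric(target_mm) || length(target_mm) != 1L || target_mm <= 0)
    stop("'target_mm' must be a single positive number")
  img <- grid$values
  msk <- mask$values
  sp <- grid$spacing_mm
  for (ax in 1:3) {
    if (abs(sp[ax] - target_mm) < 1e-9) next
    img <- resample_axis(img, ax, sp[ax], target_mm, linear = TRUE)
    msk <- resample_axis(msk, ax, sp[ax], target_mm, linear = FALSE)
  }
  g <- voxel_grid(img, spacing_mm = rep(target_mm, 3), origin_mm = grid$origin_mm)
  list(grid = g, mask = roi_mask(msk, g))
}

resample_axis <- function(a, axis, old_sp, new_sp, linear = TRUE) {
  d <- dim(a)
  n <- d[axis]
  new_n <- max(1L, as.integer(round((n - 1L) * old_sp / new_sp)) + 1L)
  new_x <- pmin((seq_len(new_n) - 1L) * new_sp, (n - 1L) * old_sp)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(a, perm), nrow = n)
  if (linear) {
    pos <- new_x / old_sp          # 0-based fractional voxel index
    lo <- pmin(floor(pos), n - 1L)
    w <- pos - lo
    lo <- as.integer(lo) + 1L
    hi <- pmin(lo + 1L, n)
    out <- (1 - w) * m[lo, , drop = FALSE] + w * m[hi, , drop = FALSE]
  } else {
    idx <- pmin(pmax(as.integer(round(new_x / old_sp)) + 1L, 1L), n)
    out <- m[idx, , drop = FALSE]
  }
  dd <- d[perm]
  dd[1] <- new_n
  aperm(array(out, dd), order(perm))
}

#' Quantize masked intensities to Ng gray levels
#'
#' Fixed-bin-count quantization over the masked voxels only:
#' `level(x) = min(Ng, floor((x - min) / (max - min) * Ng) + 1)`. This makes
#' texture features unit-free and comparable across acquisitions; a constant
#' ROI maps every voxel to level 1. Note that absolute feature magnitudes
#' (and any threshold derived from them, such as a cluster-prominence cutoff)
#' are tied to the quantization and are not transferable across different
#' discretization schemes.
#'
#' @param grid a [voxel_grid] (any channel).
#' @param mask the paired [roi_mask]; must be nonempty.
#' @param Ng number of gray levels, at least 2 (default 32).
#' @return an object of class `discretized_roi`: list with `levels` (integer
#'   array, `NA` outside the mask), `Ng`, and `bin_edges` (Ng + 1 increasing
#'   edges).
#' @export
discretize <- function(grid, mask, Ng = 32L) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(mask, "roi_mask"))
  if (!is.numeric(Ng) || length(Ng) != 1L || Ng < 2)
    stop("'Ng' must be a single count >= 2")
  Ng <- as.integer(Ng)
  assert_nonempty_mask(mask)
  inside <- mask$values != 0L
  x <- grid$values[inside]
  lo <- min(x); hi <- max(x)
  lev <- array(NA_integer_, dim = dim(grid$values))
  if (hi > lo) {
    lev[inside] <- pmin(Ng, floor((x - lo) / (hi - lo) * Ng) + 1L)
    edges <- seq(lo, hi, length.out = Ng + 1L)
  } else {
    lev[inside] <- 1L   # constant ROI: single occupied level
    edges <- lo + seq(0, 1, length.out = Ng + 1L)
  }
  structure(list(levels = lev, Ng = Ng, bin_edges = edges),
            class = "discretized_roi")
}

#' Laplacian-of-Gaussian filter channel
#'
#' Gaussian smoothing at scale `sigma_mm` followed by the discrete Laplacian
#' (second central differences divided by squared spacing, summed over axes).
#' Highlights blob-like intensity structure at the chosen physical scale;
#' requires an isotropic grid so the scale is direction-independent.
#'
#' @param grid an isotropic [voxel_grid].
#' @param sigma_mm Gaussian scale in mm (> 0).
#' @return a `filter_channel`: list with `name` (e.g. `"log_sigma_3mm"`) and
#'   `grid` (the response as a [voxel_grid]).
#' @export
log_filter <- function(grid, sigma_mm = 3) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!is_isotropic(grid))
    stop("LoG filtering requires isotropic spacing; resample_isotropic() first")
  if (sigma_mm <= 0) stop("'sigma_mm' must be positive")
  sm <- smooth_gaussian(grid$values, grid$spacing_mm, sigma_mm)
  h2 <- grid$spacing_mm[1]^2
  lap <- conv_axis(sm, c(1, -2, 1) / h2, 1) +
    conv_axis(sm, c(1, -2, 1) / h2, 2) +
    conv_axis(sm, c(1, -2, 1) / h2, 3)
  name <- paste0("log_sigma_", format(sigma_mm, trim = TRUE), "mm")
  list(name = name, grid = voxel_grid(lap, grid$spacing_mm, grid$origin_mm))
}

# Coiflet-1 analysis filters (orthonormal).
.coif1_lo <- c(-0.015655728135791993, -0.07273261951252645, 0.3848648468648578,
               0.8525720202116004, 0.3378976624574818, -0.07273261951252645)
.coif1_hi <- c(0.07273261951252645, 0.3378976624574818, -0.8525720202116004,
               0.3848648468648578, 0.07273261951252645, -0.015655728135791993)

# Periodized single-axis DWT step: returns low and high subbands of length
# ceiling(n/2) along the axis (odd lengths are wrapped periodically).
dwt_axis <- function(a, axis) {
  d <- dim(a)
  n <- d[axis]
  L <- length(.coif1_lo)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(a, perm), nrow = n)
  nh <- as.integer(ceiling(n / 2))
  starts <- (seq_len(nh) - 1L) * 2L
  lo <- matrix(0, nh, ncol(m))
  hi <- matrix(0, nh, ncol(m))
  for (t in seq_len(L)) {
    idx <- (starts + (t - 1L)) %% n + 1L
    lo <- lo + .coif1_lo[t] * m[idx, , drop = FALSE]
    hi <- hi + .coif1_hi[t] * m[idx, , drop = FALSE]
  }
  dd <- d[perm]
  dd[1] <- nh
  list(lo = aperm(array(lo, dd), order(perm)),
       hi = aperm(array(hi, dd), order(perm)))
}

# Nearest-neighbor upsample of a subband back to the original axis length.
upsample_axis <- function(a, axis, n_out) {
  d <- dim(a)
  idx <- pmin(((seq_len(n_out) - 1L) %/% 2L) + 1L, d[axis])
  switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

#' Single-level 3D wavelet decomposition channels
#'
#' Separable single-level discrete wavelet transform (Coiflet-1, periodic
#' boundary) applied along each axis, yielding the 8 subbands
#' `wavelet_LLL` ... `wavelet_HHH`. Each subband is upsampled back to the
#' input shape (nearest-neighbor) so the original tumor mask applies
#' unchanged. The raw (half-resolution) coefficients are kept alongside: for
#' even axis lengths the transform is orthonormal, so their total energy
#' equals the input energy.
#'
#' @param grid a [voxel_grid]; every axis must be at least as long as the
#'   6-tap filter.
#' @return a list of 8 `filter_channel`s, each with `name`, `grid` (subband
#'   at input shape) and `coefficients` (the decimated subband array).
#' @export
wavelet_channels <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  d <- dim(grid$values)
  if (any(d < length(.coif1_lo)))
    stop("axis length ", min(d), " is shorter than the wavelet filter (",
         length(.coif1_lo), "); volume too small for wavelet channels")
  s1 <- dwt_axis(grid$values, 1L)
  out <- list()
  for (t1 in c("L", "H")) {
    a1 <- if (t1 == "L") s1$lo else s1$hi
    s2 <- dwt_axis(a1, 2L)
    for (t2 in c("L", "H")) {
      a2 <- if (t2 == "L") s2$lo else s2$hi
      s3 <- dwt_axis(a2, 3L)
      for (t3 in c("L", "H")) {
        a3 <- if (t3 == "L") s3$lo else s3$hi
        up <- upsample_axis(a3, 1L, d[1])
        up <- upsample_axis(up, 2L, d[2])
        up <- upsample_axis(up, 3L, d[3])
        nm <- paste0("wavelet_", t1, t2, t3)
        out[[nm]] <- list(name = nm,
                          grid = voxel_grid(up, grid$spacing_mm, grid$origin_mm),
                          coefficients = a3)
      }
    }
  }
  out
}

#' Build the full channel set for feature extraction
#'
#' @param grid an isotropic [voxel_grid].
#' @param log_sigmas_mm numeric vector of LoG scales (mm); empty to disable.
#' @param wavelet logical, include the 8 wavelet subband channels.
#' @return named list of `filter_channel`s, always starting with `original`.
#' @export
filter_channels <- function(grid, log_sigmas_mm = 3, wavelet = TRUE) {
  chans <- list(original = list(name = "original", grid = grid))
  for (s in log_sigmas_mm) {
    ch <- log_filter(grid, s)
    chans[[ch$name]] <- ch
  }
  if (isTRUE(wavelet)) chans <- c(chans, wavelet_channels(grid))
  chans
}
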