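#' Read and write NIfTI-1 image/mask pairs
#'
#' Volumes travel as NIfTI-1 files with voxel spacing carried in the header.
#' On read, the mask is binarized (any nonzero value becomes 1) and checked
#' against the image for shape and spacing agreement (0.001 mm tolerance).
#'
#' @param image_path path to the scalar image volume (.nii or .nii.gz).
#' @param mask_path path to the aligned binary tumor mask.
#' @return a list with elements `grid` (a [voxel_grid]) and `mask`
#'   (a [roi_mask]).
#' @seealso [write_volume_pair()]
#' @export
read_volume_pair <- function(image_path, mask_path) {
  for (p in c(image_path, mask_path))
    if (!file.exists(p)) stop("file does not exist: ", p)
  img <- RNifti::readNifti(image_path)
  msk <- RNifti::readNifti(mask_path)
  di <- dim(img); dm <- dim(msk)
  if (length(di) != 3L || length(dm) != 3L)
    stop("expected 3D volumes, got ", length(di), "D image and ",
         length(dm), "D mask")
  if (!identical(di, dm))
    stop("image shape ", paste(di, collapse = "x"),
         " does not match mask shape ", paste(dm, collapse = "x"))
  si <- RNifti::pixdim(img); sm <- RNifti::pixdim(msk)
  if (any(abs(si - sm) > 1e-3))
    stop("image and mask voxel spacing differ by more than 0.001 mm")
  grid <- voxel_grid(array(as.numeric(img), dim = di), spacing_mm = si)
  mask <- roi_mask(array(as.numeric(msk) != 0, dim = dm), grid)
  if (n_foreground(mask) == 0L)
    stop("mask is empty: no foreground voxels in ", mask_path)
  list(grid = grid, mask = mask)
}

#' @param grid a [voxel_grid] to write.
#' @param mask the paired [roi_mask].
#' @rdname read_volume_pair
#' @export
write_volume_pair <- function(grid, mask, image_path, mask_path) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(mask, "roi_mask"))
  img <- grid$values
  attr(img, "pixdim") <- grid$spacing_mm
  RNifti::writeNifti(RNifti::asNifti(img, datatype = "double"), image_path)
  m <- array(as.integer(mask$values), dim = dim(mask$values))
  attr(m, "pixdim") <- mask$spacing_mm
  RNifti::writeNifti(RNifti::asNifti(m, datatype = "int16"), mask_path)
  invisible(c(image_path, mask_path))
}
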