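# Spatial preprocessing: probability-threshold masks, Gaussian smoothing at a
# stated FWHM, grid checks and NIfTI I/O. Registration is out of scope:
# phantoms share a grid, and mismatched grids are refused, never resampled.

#' Binary mask from a tissue-probability map
#'
#' Voxels whose probability strictly exceeds `threshold` become mask members
#' (a probability exactly at the threshold is excluded).
#'
#' @param prob_volume 3D array of probabilities in \[0, 1\].
#' @param threshold probability cut (default 0.5, the gray-matter convention).
#' @return logical array of the same shape.
#' @export
probability_to_mask <- function(prob_volume, threshold = 0.5) {
  if (any(prob_volume < -1e-6 | prob_volume > 1 + 1e-6, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]")
  m <- prob_volume > threshold
  m[is.na(m)] <- FALSE
  m
}

# FWHM (mm) to Gaussian sigma in voxels, per axis
fwhm_to_sigma_vox <- function(fwhm_mm, voxdim) {
  (fwhm_mm / sqrt(8 * log(2))) / voxdim
}

#' Gaussian smoothing of a 3D volume
#'
#' Separable Gaussian convolution with kernel width given as full width at
#' half maximum in millimetres, converted per axis to voxels via
#' `sigma = FWHM / sqrt(8 ln 2)`. Two boundary conventions:
#' * `mode = "volume"`: zero padding outside the grid (mass-preserving over
#'   the full grid);
#' * `mode = "mask"`: mask-renormalized smoothing,
#'   `smooth(x * m) / smooth(m)` inside the mask, which avoids edge
#'   attenuation and is the default input convention for voxel statistics.
#'
#' @param volume 3D numeric array.
#' @param fwhm_mm kernel FWHM in mm (0 = identity).
#' @param voxdim voxel size in mm per axis.
#' @param mode `"volume"` or `"mask"`.
#' @param mask logical array, required for `mode = "mask"`.
#' @return smoothed array (outside-mask voxels are `NA` in mask mode).
#' @export
smooth_volume <- function(volume, fwhm_mm = 6, voxdim = c(2, 2, 2),
                          mode = c("volume", "mask"), mask = NULL) {
  mode <- match.arg(mode)
  if (fwhm_mm < 0) stop("fwhm must be non-negative")
  if (fwhm_mm == 0) return(volume)
  dm <- dim(volume)
  stopifnot(length(dm) == 3L)
  sig <- fwhm_to_sigma_vox(fwhm_mm, rep(voxdim, length.out = 3))
  if (mode == "volume")
    return(cpp_smooth3d(volume, dm, sig))
  if (is.null(mask)) stop("mask mode needs a mask")
  stopifnot(all(dim(mask) == dm))
  eff <- mask & is.finite(volume)     # NA voxels inside the mask are excluded
  x <- volume
  x[!eff] <- 0
  num <- cpp_smooth3d(x, dm, sig)
  den <- cpp_smooth3d(array(as.numeric(eff), dm), dm, sig)
  out <- array(NA_real_, dm)
  out[mask] <- num[mask] / den[mask]
  out
}

# refuse mismatched grids instead of silently resampling
check_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b)))
    stop(what, " are on different grids (", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"), ")")
  invisible(TRUE)
}

#' Read and write volumes as NIfTI-1
#'
#' Thin wrappers over RNifti keeping the voxel size attached to plain R
#' arrays (attribute `voxdim`, mm).
#'
#' @param file path to a `.nii`/`.nii.gz` file.
#' @param volume 3D or 4D numeric array.
#' @param voxdim voxel size in mm.
#' @export
read_volume <- function(file) {
  img <- RNifti::readNifti(file)
  out <- array(as.numeric(img), dim(img))
  attr(out, "voxdim") <- RNifti::pixdim(img)[seq_len(min(3, length(dim(img))))]
  out
}

#' @rdname read_volume
#' @export
write_volume <- function(volume, file, voxdim = attr(volume, "voxdim")) {
  if (is.null(voxdim)) voxdim <- c(2, 2, 2)
  img <- RNifti::asNifti(array(as.numeric(volume), dim(volume)))
  RNifti::pixdim(img) <- rep(voxdim, length.out = min(3, length(dim(volume))))
  RNifti::writeNifti(img, file)
  invisible(file)
}
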