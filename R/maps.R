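# Scalar kurtosis maps: mean, axial and radial kurtosis from a voxelwise fit.

#' Derive mean, axial and radial kurtosis maps
#'
#' From a voxelwise kurtosis-model fit, computes per voxel the eigenframe
#' kurtoses `Khat_i = (MD^2 / lambda_i^2) * What_iiii` (the kurtosis along
#' each diffusion-tensor eigenvector, eigenvalues sorted descending), and
#' from them:
#' * `k_axial`: `Khat_1`, the kurtosis along the principal eigenvector;
#' * `k_radial`: `(Khat_2 + Khat_3) / 2`, the average kurtosis along the two
#'   non-principal eigenvectors;
#' * `mk`: the apparent kurtosis averaged over a direction set — by default
#'   the scheme's acquired nonzero-b directions, optionally a dense
#'   321-point quasi-uniform sphere.
#'
#' Values are clipped to `clip` (flagging the voxel) and voxels with a
#' non-positive-definite diffusion tensor are excluded from `valid_mask`.
#'
#' @param fit a [dki_fit()] object.
#' @param mk_directions `"acquired"` (default) or `"sphere321"`.
#' @param clip numeric length-2 clip range for all three metrics.
#' @return object of class `kurtosis_maps`: list of 3D arrays (or vectors if
#'   the fit had no grid) `mk`, `k_axial`, `k_radial`, logical `valid_mask`,
#'   integer `flags`, plus `voxdim`.
#' @export
kurtosis_maps <- function(fit, mk_directions = c("acquired", "sphere321"),
                          clip = c(0, 10)) {
  stopifnot(inherits(fit, "dki_fit"))
  mk_directions <- match.arg(mk_directions)
  dirs <- switch(mk_directions,
                 acquired = fit$scheme$dirs,
                 sphere321 = fibonacci_sphere(321L))
  res <- cpp_kurtosis_maps(t(fit$params), dirs, fit$flags, clip[1], clip[2])
  shape <- function(x) if (is.null(fit$dim)) x else array(x, fit$dim)
  bad <- .dki_flags[["fit_fail"]] + .dki_flags[["nonpd_d"]]
  valid <- !bitwAnd(res$flags, bad) & !is.na(res$mk)
  structure(list(mk = shape(res$mk), k_axial = shape(res$k_axial),
                 k_radial = shape(res$k_radial),
                 valid_mask = shape(valid), flags = shape(res$flags),
                 voxdim = fit$voxdim, mk_directions = mk_directions,
                 clip = clip),
            class = "kurtosis_maps")
}

#' @export
print.kurtosis_maps <- function(x, ...) {
  cat("Kurtosis maps (MK averaged over", x$mk_directions, "directions)\n")
  v <- x$valid_mask
  cat("  valid voxels:", sum(v), "of", length(v), "\n")
  for (m in c("mk", "k_axial", "k_radial")) {
    vals <- x[[m]][v]
    cat(sprintf("  %-9s median %.3f  IQR [%.3f, %.3f]\n", m,
                stats::median(vals), stats::quantile(vals, .25),
                stats::quantile(vals, .75)))
  }
  invisible(x)
}

#' @export
plot.kurtosis_maps <- function(x, metric = "mk", slice = NULL, ...) {
  vol <- x[[metric]]
  if (is.null(dim(vol))) stop("no grid attached to these maps")
  if (is.null(slice)) slice <- ceiling(dim(vol)[3] / 2)
  img <- vol[, , slice]
  img[!x$valid_mask[, , slice]] <- NA
  image(img, asp = 1, main = sprintf("%s, axial slice %d", metric, slice),
        useRaster = TRUE, ...)
  invisible(x)
}
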