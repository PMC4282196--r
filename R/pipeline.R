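# End-to-end phantom pipeline: simulate each subject's DWI, fit the kurtosis
# model, derive metric maps and smooth them — streaming subject by subject so
# a whole cohort never needs to hold 39 4D volumes at once.

#' Smoothed kurtosis metric maps for a simulated cohort
#'
#' Runs the full single-subject chain (signal simulation, voxelwise WLLS
#' kurtosis fit, map derivation, Gaussian smoothing) for every subject of a
#' two-group phantom cohort, and returns the smoothed metric maps ready for
#' voxel statistics.
#'
#' @inheritParams simulate_cohort
#' @param metrics which maps to compute and return.
#' @param fwhm_mm smoothing kernel FWHM in mm (0 disables smoothing).
#' @param smooth_mode `"mask"` (mask-renormalized, the default input
#'   convention for voxel statistics) or `"volume"`.
#' @param mk_directions passed to [kurtosis_maps()].
#' @return list with `maps` (per metric: list of per-subject 3D arrays),
#'   `group` factor, `mask`, `effect_voxels`, `truth`.
#' @export
cohort_metric_maps <- function(spec, effect, n_patients = 18L,
                               n_controls = 21L, scheme, seed = 1L,
                               metrics = c("mk", "k_axial", "k_radial"),
                               fwhm_mm = 6, smooth_mode = "mask",
                               mk_directions = "acquired") {
  stopifnot(n_patients >= 2L, n_controls >= 2L)
  spec_pat <- apply_effect(spec, effect)
  group <- factor(rep(c("patient", "control"), c(n_patients, n_controls)),
                  levels = c("patient", "control"))
  maps <- stats::setNames(rep(list(vector("list", length(group))), length(metrics)),
                          metrics)
  mask <- NULL; truth <- list()
  with_seed(seed, {
    for (i in seq_along(group)) {
      sp <- if (group[i] == "patient") spec_pat else spec
      key <- as.character(group[i])
      need_truth <- is.null(truth[[key]])
      sim <- simulate_signals(sp, scheme, seed = NULL,
                              noise_background = FALSE, truth = need_truth)
      if (is.null(mask)) mask <- sim$mask
      if (need_truth)
        truth[[key]] <- sim$truth[c("mk", "k_axial", "k_radial")]
      fit <- dki_fit(sim$signals, scheme, mask = sim$mask, voxdim = sp$voxdim)
      km <- kurtosis_maps(fit, mk_directions = mk_directions)
      for (m in metrics) {
        vol <- km[[m]]
        vol[!km$valid_mask] <- NA
        if (fwhm_mm > 0)
          vol <- smooth_volume(vol, fwhm_mm, sp$voxdim, mode = smooth_mode,
                               mask = mask)
        maps[[m]][[i]] <- vol
      }
    }
  })
  ids <- vapply(spec$regions, `[[`, "", "id")
  list(maps = maps, group = group, mask = mask,
       effect_voxels = spec$regions[[which(ids == effect$region_id)]]$voxels,
       truth = truth)
}
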