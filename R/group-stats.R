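# Voxelwise two-group comparison with Monte-Carlo cluster-extent correction:
# pooled-variance t maps, a simulated null distribution of maximum cluster
# size (the AlphaSim procedure), and cluster tables in the convention
# peak coordinate / extent / peak t.

#' Voxelwise two-sample t map
#'
#' Pooled-variance two-sample t statistic per voxel, sign convention
#' `group_a - group_b` (patients minus controls, so deficits are negative),
#' with two-tailed p from the t distribution on `n_a + n_b - 2` degrees of
#' freedom. Voxels with zero pooled variance are dropped from the mask.
#'
#' @param group_a,group_b lists of 3D arrays (or `nvox x n` matrices), one
#'   per subject.
#' @param mask logical array restricting the analysis.
#' @return object of class `stat_map`: list with `t`, `p` (arrays), `df`,
#'   `mask` (possibly reduced), `n` and `dropped` (zero-variance voxel count).
#' @export
two_sample_t_map <- function(group_a, group_b, mask) {
  a <- as_subject_matrix(group_a, mask)
  b <- as_subject_matrix(group_b, mask)
  n1 <- ncol(a); n2 <- ncol(b)
  stopifnot(n1 >= 2L, n2 >= 2L)
  df <- n1 + n2 - 2L
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2); v2 <- rowSums((b - m2)^2)
  sp2 <- (v1 + v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tval <- (m1 - m2) / se
  dm <- dim(mask)
  tvol <- array(NA_real_, dm); pvol <- array(NA_real_, dm)
  keep <- se > 0 & is.finite(tval)
  outmask <- array(FALSE, dm)
  outmask[mask][keep] <- TRUE
  tvol[mask][keep] <- tval[keep]
  pvol[mask][keep] <- 2 * pt(-abs(tval[keep]), df)
  dropped <- sum(!keep)
  if (dropped > 0)
    message(dropped, " zero-variance voxel(s) dropped from the analysis mask")
  structure(list(t = tvol, p = pvol, df = df, mask = outmask,
                 n = c(n1, n2), dropped = dropped),
            class = "stat_map")
}

# subjects-as-columns matrix of masked voxel values
as_subject_matrix <- function(x, mask) {
  if (is.list(x)) {
    for (s in x) check_same_grid(s, mask, "subject maps and mask")
    x <- vapply(x, function(s) as.numeric(s[mask]), numeric(sum(mask)))
  }
  as.matrix(x)
}

#' @export
print.stat_map <- function(x, ...) {
  cat("Two-sample t map: n =", paste(x$n, collapse = " vs "),
      "(df =", x$df, ")\n")
  tv <- x$t[x$mask]
  cat("  mask:", sum(x$mask), "voxels;  t range",
      sprintf("[%.2f, %.2f]\n", min(tv), max(tv)))
  invisible(x)
}

#' Monte-Carlo null specification for cluster-extent correction
#'
#' @param n_iter Monte-Carlo iterations (>= 100).
#' @param forming_p two-tailed cluster-forming p threshold.
#' @param fwe_p target family-wise (corrected) level.
#' @param connectivity 6, 18 or 26 neighbourhood.
#' @param smoothness_fwhm_mm assumed smoothness of the statistic field, mm;
#'   by convention the analysis' applied smoothing kernel.
#' @param seed RNG seed.
#' @export
mc_null_spec <- function(n_iter = 1000L, forming_p = 0.001, fwe_p = 0.05,
                         connectivity = 18L, smoothness_fwhm_mm = 6,
                         seed = 1L) {
  stopifnot(forming_p > 0, forming_p < 1, fwe_p > 0, fwe_p < 1,
            n_iter >= 100L, connectivity %in% c(6L, 18L, 26L))
  structure(list(n_iter = as.integer(n_iter), forming_p = forming_p,
                 fwe_p = fwe_p, connectivity = as.integer(connectivity),
                 smoothness_fwhm_mm = smoothness_fwhm_mm,
                 seed = as.integer(seed)),
            class = "mc_null_spec")
}

#' Monte-Carlo minimum cluster extent (AlphaSim-style)
#'
#' Simulates Gaussian white-noise fields on the mask's bounding grid,
#' smooths them to the assumed field smoothness, standardizes within the
#' mask, applies the two-tailed forming threshold and records the maximum
#' suprathreshold cluster size per iteration. The returned `k_min` is the
#' smallest extent k such that the fraction of iterations whose maximum
#' cluster reaches k is at most `fwe_p`; clusters of at least `k_min` voxels
#' are family-wise significant at `fwe_p`.
#'
#' @param mask logical 3D analysis mask.
#' @param spec an [mc_null_spec()].
#' @param voxdim voxel size in mm.
#' @return integer `k_min`, with the simulated max-cluster sizes in
#'   attribute `"max_sizes"`.
#' @export
mc_cluster_threshold <- function(mask, spec = mc_null_spec(),
                                 voxdim = c(2, 2, 2)) {
  stopifnot(any(mask))
  if (spec$n_iter * spec$fwe_p < 5)
    warning("n_iter too small to resolve fwe_p = ", spec$fwe_p)
  dm <- dim(mask)
  sig <- fwhm_to_sigma_vox(spec$smoothness_fwhm_mm, rep(voxdim, length.out = 3))
  zthr <- qnorm(1 - spec$forming_p / 2)
  maxsz <- integer(spec$n_iter)
  with_seed(spec$seed, {
    for (i in seq_len(spec$n_iter)) {
      f <- array(rnorm(prod(dm)), dm)
      if (spec$smoothness_fwhm_mm > 0) f <- cpp_smooth3d(f, dm, sig)
      v <- f[mask]
      z <- (f - mean(v)) / sd(v)
      maxsz[i] <- max(max_cluster_size(z > zthr & mask, spec$connectivity),
                      max_cluster_size(z < -zthr & mask, spec$connectivity))
    }
  })
  tab <- tabulate(maxsz + 1L, nbins = max(maxsz) + 1L)  # counts of size 0..max
  exceed <- rev(cumsum(rev(tab))) / spec$n_iter          # P(max >= k), k = 0..max
  k <- which(exceed <= spec$fwe_p)[1]
  k_min <- if (is.na(k)) max(maxsz) + 1L else k - 1L     # sizes are 0-based here
  k_min <- max(k_min, 1L)
  structure(as.integer(k_min), max_sizes = maxsz, spec = spec)
}

max_cluster_size <- function(bin, connectivity) {
  lab <- cpp_label3d(bin, dim(bin), connectivity)
  if (max(lab) == 0L) return(0L)
  max(tabulate(lab[lab > 0L]))
}

#' Extract suprathreshold clusters from a statistic map
#'
#' Thresholds the t map two-tailed at `forming_p` (sign kept; positive and
#' negative excursions are clustered separately), removes clusters smaller
#' than `k_min`, and reports each surviving cluster's peak world coordinate,
#' extent and signed peak t, sorted by extent descending.
#'
#' @param stat a [two_sample_t_map()] result.
#' @param forming_p two-tailed forming threshold.
#' @param k_min minimum cluster extent in voxels (from
#'   [mc_cluster_threshold()]).
#' @param connectivity 6, 18 or 26.
#' @param voxdim voxel size in mm.
#' @param origin world coordinate (mm) of the center of voxel (1,1,1).
#' @return data.frame of class `cluster_table` with columns `cluster`,
#'   `peak_x_mm`, `peak_y_mm`, `peak_z_mm`, `n_voxels`, `peak_t`; surviving
#'   clusters' voxel indices in attribute `"voxels"`.
#' @export
extract_clusters <- function(stat, forming_p = 0.001, k_min = 1L,
                             connectivity = 18L, voxdim = c(2, 2, 2),
                             origin = c(0, 0, 0)) {
  tthr <- qt(1 - forming_p / 2, stat$df)
  dm <- dim(stat$mask)
  recs <- list(); voxsets <- list()
  tv <- stat$t
  tv[is.na(tv)] <- 0
  for (sgn in c(1, -1)) {
    bin <- (sgn * tv > tthr) & stat$mask
    lab <- cpp_label3d(bin, dm, connectivity)
    nl <- max(lab)
    if (nl == 0L) next
    for (l in seq_len(nl)) {
      vox <- which(lab == l)
      if (length(vox) < k_min) next
      pk <- vox[which.max(abs(tv[vox]))]
      ijk <- arrayInd(pk, dm)
      recs[[length(recs) + 1L]] <- data.frame(
        peak_x_mm = (ijk[1] - 1) * voxdim[1] + origin[1],
        peak_y_mm = (ijk[2] - 1) * voxdim[2] + origin[2],
        peak_z_mm = (ijk[3] - 1) * voxdim[3] + origin[3],
        n_voxels = length(vox), peak_t = tv[pk])
      voxsets[[length(voxsets) + 1L]] <- vox
    }
  }
  if (length(recs) == 0L) {
    out <- data.frame(cluster = integer(0), peak_x_mm = numeric(0),
                      peak_y_mm = numeric(0), peak_z_mm = numeric(0),
                      n_voxels = integer(0), peak_t = numeric(0))
  } else {
    out <- do.call(rbind, recs)
    ord <- order(-out$n_voxels)
    out <- cbind(cluster = seq_along(ord), out[ord, ])
    voxsets <- voxsets[ord]
    rownames(out) <- NULL
  }
  structure(out, voxels = voxsets, k_min = k_min,
            class = c("cluster_table", "data.frame"))
}

#' Overlap of detected clusters with a known effect region
#'
#' Phantom-validation summary: the fraction of true effect voxels covered by
#' surviving clusters (hit rate) and the count of surviving voxels outside
#' the true region.
#'
#' @param clusters a [extract_clusters()] table.
#' @param truth_voxels linear indices of the true effect region.
#' @return list with `hit_rate`, `false_positive_voxels`, `n_clusters`,
#'   `detected_voxels`.
#' @export
effect_recovery_report <- function(clusters, truth_voxels) {
  det <- unique(unlist(attr(clusters, "voxels")))
  list(hit_rate = if (length(truth_voxels))
         length(intersect(det, truth_voxels)) / length(truth_voxels) else NA_real_,
       false_positive_voxels = length(setdiff(det, truth_voxels)),
       n_clusters = nrow(clusters),
       detected_voxels = length(det))
}
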