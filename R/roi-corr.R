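# ROI summaries of kurtosis maps and their correlation with symptom scores.

#' Per-subject ROI means of a metric map
#'
#' Unweighted mean of the metric over the ROI voxels, one value per subject.
#' `NA` voxels inside the ROI are excluded (with a message).
#'
#' @param metric_maps list of 3D arrays (one per subject) or a
#'   `nvox x nsubj` matrix.
#' @param roi_mask logical 3D array (nonempty).
#' @return numeric vector, one mean per subject.
#' @export
roi_means <- function(metric_maps, roi_mask) {
  if (!any(roi_mask)) stop("ROI mask is empty")
  if (is.list(metric_maps)) {
    for (s in metric_maps) check_same_grid(s, roi_mask, "metric maps and ROI")
    vals <- vapply(metric_maps, function(s) as.numeric(s[roi_mask]),
                   numeric(sum(roi_mask)))
  } else {
    vals <- metric_maps[as.numeric(which(roi_mask)), , drop = FALSE]
  }
  nbad <- sum(is.na(vals))
  if (nbad > 0)
    message(nbad, " NA voxel value(s) inside the ROI excluded from the means")
  colMeans(vals, na.rm = TRUE)
}

#' Pearson correlation with a t-based two-tailed p-value
#'
#' Sample Pearson r between a score and an ROI summary, with p computed from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom,
#' two-tailed. The conventional significance level for reporting is 0.05.
#'
#' @param x,y numeric vectors, length >= 3, each with nonzero variance.
#' @return object of class `correlation_result`: list with `r`, `p`, `n`.
#' @export
pearson_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: zero variance")
  r <- cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tt), n - 2)
  }
  structure(list(r = r, p = p, n = n), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f, P = %.4g (n = %d, two-tailed)\n",
              x$r, x$p, x$n))
  invisible(x)
}

#' Correlate ROI metric means with a clinical score across subjects
#'
#' Convenience wrapper running [roi_means()] then [pearson_test()] for each
#' ROI, returning a tidy table. Following the emulated design, correlations
#' are computed within the patient group only and no multiplicity
#' adjustment is applied across ROIs (the output notes this).
#'
#' @param metric_maps list of per-subject 3D arrays (patient group).
#' @param rois named list of logical ROI masks.
#' @param scores numeric clinical score per subject (e.g. CIAS).
#' @param metric label recorded in the output.
#' @return data.frame with columns `roi_id`, `metric`, `r`, `p`, `n`.
#' @export
roi_score_correlation <- function(metric_maps, rois, scores, metric = "mk") {
  stopifnot(length(rois) > 0)
  rows <- lapply(names(rois), function(id) {
    m <- roi_means(metric_maps, rois[[id]])
    ct <- pearson_test(scores, m)
    data.frame(roi_id = id, metric = metric, r = ct$r, p = ct$p, n = ct$n)
  })
  out <- do.call(rbind, rows)
  attr(out, "note") <- "uncorrected two-tailed p-values; no adjustment across ROIs"
  out
}
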