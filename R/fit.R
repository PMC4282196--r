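# Per-voxel estimation of the diffusional-kurtosis signal model
#   ln S(b,n) = ln S0 - b * n'Dn + (b^2/6) * sum n_i n_j n_k n_l V_ijkl,
# with V = MD^2 * W recovered as linear coefficients and the kurtosis tensor
# W = V / MD^2 computed afterwards.

.dki_flags <- c(nonpos_signal = 1L, fit_fail = 2L, nonpd_d = 4L, clipped = 8L)

# Design matrix of the 22-parameter log-linear model for a scheme.
dki_design <- function(scheme) {
  b <- scheme$bvals
  v <- scheme$bvecs
  n <- length(b)
  x2 <- matrix(0, n, 6)
  for (k in 1:6)
    x2[, k] <- .d_mult[k] * v[, .d_idx[k, 1]] * v[, .d_idx[k, 2]]
  x4 <- matrix(0, n, 15)
  for (k in 1:15)
    x4[, k] <- .w_mult[k] * v[, .w_idx[k, 1]] * v[, .w_idx[k, 2]] *
      v[, .w_idx[k, 3]] * v[, .w_idx[k, 4]]
  cbind(1, -b * x2, (b^2 / 6) * x4)
}

#' Fit the diffusional kurtosis model voxel by voxel
#'
#' Estimates, for every voxel, the baseline signal S0, the symmetric
#' diffusion tensor D (6 unique elements, mm^2/s) and the fully symmetric
#' 4th-order kurtosis tensor W (15 unique elements, dimensionless) from
#' multi-b-value diffusion-weighted signals, by weighted linear least
#' squares on the log signal. The model is linear in `(ln S0, D, V)` with
#' `V = MD^2 W`; an unweighted solve provides starting values and one
#' reweighting pass with weights equal to the squared predicted signal gives
#' the final estimate, the standard deterministic reference estimator for
#' this model.
#'
#' Voxels with non-positive signals have those volumes excluded (flag
#' `nonpos_signal`); voxels with too few usable volumes or a singular design
#' are flagged `fit_fail` rather than raising.
#'
#' @param signals a numeric vector (one voxel), a `nvox x nvol` matrix, or a
#'   4D array with the volume index last.
#' @param scheme a [gradient_scheme()]; needs >= 15 unique directions on
#'   >= 2 nonzero shells.
#' @param mask optional logical array/vector selecting voxels to fit.
#' @param voxdim voxel size in mm (kept for downstream spatial steps).
#' @return an object of class `dki_fit` with components `params` (nvox x 22
#'   matrix: `log_s0`, 6 `d*`, 15 `v*` columns), `md`, `flags`, `mask`,
#'   `dim`, `voxdim`, `scheme`, and the input `signals`. Methods:
#'   [coef.dki_fit()], [predict.dki_fit()], [residuals.dki_fit()],
#'   [simulate.dki_fit()], `print`, `summary`.
#' @seealso [kurtosis_maps()], [apparent_along()], [rotate_kt()]
#' @export
dki_fit <- function(signals, scheme, mask = NULL, voxdim = c(2, 2, 2)) {
  validate_scheme(scheme, for_kurtosis = TRUE)
  dm <- NULL
  if (is.array(signals) && length(dim(signals)) == 4L) {
    dm <- dim(signals)[1:3]
    signals <- matrix(signals, prod(dm), dim(signals)[4])
  } else if (is.vector(signals) && is.numeric(signals)) {
    signals <- matrix(signals, 1L)
  }
  nvox <- nrow(signals)
  nvol <- ncol(signals)
  if (nvol != length(scheme$bvals))
    stop("signals have ", nvol, " volumes but the scheme has ", length(scheme$bvals))
  if (is.null(mask)) mask <- rep(TRUE, nvox)
  mask <- as.logical(mask)
  if (length(mask) != nvox) stop("mask length does not match voxel count")

  X <- dki_design(scheme)
  idx <- which(mask)
  res <- cpp_wlls_fit(t(signals[idx, , drop = FALSE]), X)

  params <- matrix(NA_real_, nvox, 22)
  colnames(params) <- c("log_s0", .d_names, paste0("v", substring(.w_names, 2)))
  params[idx, ] <- t(res$beta)
  flags <- integer(nvox)
  flags[idx] <- res$flags
  flags[!mask] <- .dki_flags[["fit_fail"]]
  md <- rowMeans(params[, c("dxx", "dyy", "dzz"), drop = FALSE])

  structure(list(params = params, md = md, flags = flags, mask = mask,
                 dim = dm, voxdim = voxdim, scheme = scheme,
                 signals = signals, call = match.call()),
            class = "dki_fit")
}

#' @export
print.dki_fit <- function(x, ...) {
  nfit <- sum(!bitwAnd(x$flags, .dki_flags[["fit_fail"]]))
  cat("Diffusional kurtosis model fit\n")
  if (!is.null(x$dim)) cat("  grid: ", paste(x$dim, collapse = " x "), "\n", sep = "")
  cat("  voxels fitted: ", nfit, " of ", nrow(x$params), "\n", sep = "")
  cat("  volumes: ", length(x$scheme$bvals), " (b = ",
      paste(sort(unique(x$scheme$bvals)), collapse = ", "), " s/mm^2)\n", sep = "")
  infl <- x$flags[as.logical(x$mask)]   # out-of-mask voxels carry a
  fl <- vapply(names(.dki_flags), function(f)      # bookkeeping fit_fail bit
    sum(bitwAnd(infl, .dki_flags[[f]]) > 0), integer(1))
  if (any(fl > 0))
    cat("  flags: ", paste(names(fl)[fl > 0], fl[fl > 0], sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.dki_fit <- function(object, ...) {
  ok <- !bitwAnd(object$flags, .dki_flags[["fit_fail"]])
  co <- coef(object)
  out <- list(n_voxels = nrow(co), n_fitted = sum(ok),
              md = summary(object$md[ok]),
              s0 = summary(exp(object$params[ok, "log_s0"])),
              flags = object$flags)
  class(out) <- "summary.dki_fit"
  out
}

#' @export
print.summary.dki_fit <- function(x, ...) {
  cat("DKI fit:", x$n_fitted, "of", x$n_voxels, "voxels fitted\n")
  cat("mean diffusivity (mm^2/s):\n"); print(x$md)
  cat("S0:\n"); print(x$s0)
  invisible(x)
}

#' Extract fitted tensor parameters
#'
#' Returns the per-voxel parameter estimates on their natural scale: `s0`,
#' the six diffusion-tensor elements (mm^2/s) and the fifteen
#' kurtosis-tensor elements `W = V / MD^2` (dimensionless).
#'
#' @param object a `dki_fit`.
#' @param ... unused.
#' @export
coef.dki_fit <- function(object, ...) {
  w <- object$params[, 8:22, drop = FALSE] / object$md^2
  colnames(w) <- .w_names
  cbind(s0 = exp(object$params[, "log_s0"]),
        object$params[, 2:7, drop = FALSE], w)
}

#' @export
fitted.dki_fit <- function(object, ...) predict(object)

#' Predict noise-free signals from a fitted kurtosis model
#'
#' @param object a `dki_fit`.
#' @param scheme gradient scheme to predict for (default: the scheme used
#'   for fitting).
#' @param ... unused.
#' @return `nvox x nvol` matrix of predicted signals.
#' @export
predict.dki_fit <- function(object, scheme = object$scheme, ...) {
  X <- dki_design(scheme)
  exp(object$params %*% t(X))
}

#' @export
residuals.dki_fit <- function(object, ...) object$signals - fitted(object)

#' Simulate noisy signals from a fitted kurtosis model
#'
#' Draws Rician-distributed replicates of the fitted noise-free signals:
#' the magnitude of `(S + e1, e2)` with independent Gaussian `e` of standard
#' deviation `S0 / snr_b0`.
#'
#' @param object a `dki_fit`.
#' @param nsim number of replicate datasets.
#' @param seed optional integer seed.
#' @param snr_b0 signal-to-noise ratio at b = 0 (per voxel, from the fitted
#'   S0). `Inf` disables noise.
#' @param ... unused.
#' @return a list of `nsim` signal matrices.
#' @export
simulate.dki_fit <- function(object, nsim = 1, seed = NULL, snr_b0 = 46, ...) {
  s <- predict(object)
  sigma <- exp(object$params[, "log_s0"]) / snr_b0
  with_seed(seed, {
    lapply(seq_len(nsim), function(i) rician(s, sigma))
  })
}

# magnitude of a complex Gaussian perturbation; sigma recycled over columns
rician <- function(s, sigma) {
  if (all(!is.finite(sigma)) || all(sigma == 0)) return(s)
  sigma[!is.finite(sigma)] <- 0
  e1 <- matrix(rnorm(length(s), sd = 1), nrow(s)) * sigma
  e2 <- matrix(rnorm(length(s), sd = 1), nrow(s)) * sigma
  sqrt((s + e1)^2 + e2^2)
}

# Per-voxel eigendecomposition of the fitted diffusion tensors, eigenvalues
# sorted descending. Returns values (nvox x 3) and vectors (3 x 3 x nvox).
tensor_eigen <- function(fit) {
  nvox <- nrow(fit$params)
  vals <- matrix(NA_real_, nvox, 3)
  vecs <- array(NA_real_, c(3, 3, nvox))
  ok <- which(!bitwAnd(fit$flags, .dki_flags[["fit_fail"]]))
  for (v in ok) {
    e <- eigen(d_to_matrix(fit$params[v, 2:7]), symmetric = TRUE)
    vals[v, ] <- e$values           # eigen() returns descending order
    vecs[, , v] <- e$vectors
  }
  list(values = vals, vectors = vecs)
}

#' Apparent diffusivity and kurtosis along a direction
#'
#' Evaluates, per voxel, the directional projections of a fitted model:
#' `d_app = n' D n` (mm^2/s) and `k_app = (MD^2 / d_app^2) *
#' sum n_i n_j n_k n_l W_ijkl` (dimensionless).
#'
#' @param fit a `dki_fit`.
#' @param direction unit 3-vector.
#' @return data.frame with columns `d_app`, `k_app`; rows are voxels.
#'   Voxels where `d_app <= 0` (or the fit failed) return `NA`.
#' @export
apparent_along <- function(fit, direction) {
  n <- as.numeric(direction)
  if (abs(sqrt(sum(n^2)) - 1) > 1e-6) stop("direction must be unit-norm")
  nvox <- nrow(fit$params)
  out <- data.frame(d_app = rep(NA_real_, nvox), k_app = rep(NA_real_, nvox))
  ok <- which(!bitwAnd(fit$flags, .dki_flags[["fit_fail"]]))
  for (v in ok) {
    da <- quadratic_form(fit$params[v, 2:7], n)
    if (is.na(da) || da <= 0) next
    out$d_app[v] <- da
    out$k_app[v] <- quartic_form(fit$params[v, 8:22], n) / da^2
  }
  out
}
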