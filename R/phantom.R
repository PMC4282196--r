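# Multi-shell DWI phantoms: piecewise-constant diffusion/kurtosis tensor
# fields on a voxel grid, forward-simulated signals with Rician noise, and
# two-group cohorts with a localized kurtosis reduction in the patient group.

#' Specify a DKI phantom
#'
#' A phantom is a voxel grid carrying, per region, ground-truth diffusion
#' eigenvalues, kurtosis-tensor elements (given in the region's eigenframe)
#' and a principal-direction rotation. Voxels outside all regions are empty
#' background. `snr_b0` sets the Rician noise level: the Gaussian component
#' standard deviation is `s0 / snr_b0`, i.e. SNR is defined on the
#' unweighted (b = 0) image.
#'
#' @param grid_shape voxel counts per axis.
#' @param voxdim voxel size in mm per axis.
#' @param regions list of regions from [phantom_region()].
#' @param s0 baseline signal (arbitrary units).
#' @param snr_b0 signal-to-noise ratio at b = 0; `Inf` disables noise.
#' @param seed default RNG seed for noise draws.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(24L, 24L, 24L), voxdim = c(2, 2, 2),
                         regions = list(), s0 = 1000, snr_b0 = 46,
                         seed = 1L) {
  stopifnot(all(grid_shape > 0), snr_b0 > 0, s0 > 0)
  seen <- integer(0)
  for (r in regions) {
    stopifnot(inherits(r, "phantom_region"))
    if (any(r$voxels %in% seen))
      stop("regions overlap: every voxel may belong to at most one region")
    if (any(r$voxels < 1L | r$voxels > prod(grid_shape)))
      stop("region voxels outside the grid")
    seen <- c(seen, r$voxels)
  }
  structure(list(grid_shape = as.integer(grid_shape), voxdim = voxdim,
                 regions = regions, s0 = s0, snr_b0 = snr_b0,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @param id region identifier.
#' @param voxels linear voxel indices into the grid.
#' @param evals diffusion-tensor eigenvalues `lambda1 >= lambda2 >= lambda3 > 0`
#'   in mm^2/s.
#' @param w15 the 15 unique kurtosis-tensor elements in the region
#'   eigenframe (see [dki_fit()] for ordering); [isotropic_kurtosis()] builds
#'   the isotropic case.
#' @param rotation 3x3 rotation whose columns are the principal directions
#'   (eigenvectors) in the laboratory frame; identity by default.
#' @export
phantom_region <- function(id, voxels, evals, w15, rotation = diag(3)) {
  evals <- as.numeric(evals)
  if (length(evals) != 3L || any(diff(evals) > 0) || evals[3] <= 0)
    stop("eigenvalues must satisfy lambda1 >= lambda2 >= lambda3 > 0")
  stopifnot(length(w15) == 15L, all(dim(rotation) == c(3, 3)))
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation must be orthonormal")
  structure(list(id = id, voxels = as.integer(voxels), evals = evals,
                 w15 = as.numeric(w15), rotation = rotation),
            class = "phantom_region")
}

#' Isotropic kurtosis tensor elements
#'
#' Elements of the fully symmetric tensor whose quartic form equals `k` in
#' every direction: `W_iiii = k`, `W_iijj = k/3`, all others zero.
#'
#' @param k the apparent kurtosis value.
#' @export
isotropic_kurtosis <- function(k) isotropic_w(k)

#' Default two-region gray-matter phantom
#'
#' A 24^3 grid at 2 mm isotropic with a spherical "brain" of GM-like tissue
#' (eigenvalues `(1.2, 1.0, 0.9) x 1e-3` mm^2/s, isotropic kurtosis 0.9) of
#' radius 10 voxels, containing a 5^3-voxel cubic "lesion" region with the
#' same baseline tensors. The lesion is where a patient-group kurtosis
#' reduction is applied by [simulate_cohort()].
#'
#' @inheritParams phantom_spec
#' @param lesion_scale optional kurtosis scale applied to the lesion already
#'   in the spec (normally left 1; group effects are applied by
#'   [effect_spec()] instead).
#' @export
default_phantom <- function(grid_shape = c(24L, 24L, 24L), voxdim = c(2, 2, 2),
                            snr_b0 = 46, seed = 1L, lesion_scale = 1) {
  ctr <- (grid_shape + 1) / 2
  idx <- arrayInd(seq_len(prod(grid_shape)), grid_shape)
  dist2 <- rowSums(sweep(idx, 2, ctr)^2)
  brain <- which(dist2 <= 10^2)
  cube <- which(idx[, 1] %in% 11:15 & idx[, 2] %in% 11:15 & idx[, 3] %in% 11:15)
  evals <- c(1.2, 1.0, 0.9) * 1e-3
  phantom_spec(
    grid_shape = grid_shape, voxdim = voxdim,
    regions = list(
      phantom_region("gm", setdiff(brain, cube), evals, isotropic_w(0.9)),
      phantom_region("lesion", intersect(cube, brain), evals,
                     isotropic_w(0.9) * lesion_scale)),
    snr_b0 = snr_b0, seed = seed)
}

#' Patient-group effect specification
#'
#' Encodes a localized microstructural deficit: in the patient group the
#' kurtosis tensor inside one region is multiplied by `kurtosis_scale`
#' (0 < scale <= 1), lowering MK, axial and radial kurtosis there.
#'
#' @param region_id id of a region in the phantom spec.
#' @param kurtosis_scale multiplicative factor in (0, 1].
#' @param applies_to metrics expected to drop (metadata for reports).
#' @export
effect_spec <- function(region_id, kurtosis_scale,
                        applies_to = c("mk", "k_axial", "k_radial")) {
  if (kurtosis_scale <= 0 || kurtosis_scale > 1)
    stop("kurtosis_scale must be in (0, 1]")
  structure(list(region_id = region_id, kurtosis_scale = kurtosis_scale,
                 applies_to = applies_to), class = "effect_spec")
}

# lab-frame parameter vector (log s0, d6, v15) for a region
region_params <- function(region, s0) {
  R <- region$rotation
  D <- R %*% diag(region$evals) %*% t(R)
  # components of the eigenframe tensor expressed in the lab frame
  w_lab <- rotate_kt(region$w15, t(R))
  md <- mean(region$evals)
  c(log(s0), matrix_to_d(D), md^2 * w_lab)
}

#' Simulate multi-shell diffusion-weighted signals from a phantom
#'
#' Evaluates the noise-free kurtosis signal model
#' `S(b,n) = S0 exp(-b D_app(n) + b^2 D_app(n)^2 K_app(n) / 6)` per voxel
#' and volume, then applies Rician noise as the magnitude of
#' `(S + e1, e2)` with `e ~ Normal(0, S0 / snr_b0)`.
#'
#' @param spec a [phantom_spec()].
#' @param scheme a [gradient_scheme()].
#' @param seed RNG seed for the noise (default: the spec's seed).
#' @param noise set `FALSE` for noise-free signals.
#' @param noise_background add noise to empty background voxels too
#'   (Rayleigh-distributed background, as in magnitude MRI). Turning it off
#'   skips draws for voxels no fit will use.
#' @param truth compute the ground-truth metric maps (skippable when only
#'   signals are needed).
#' @return list with `signals` (4D array), `mask` (logical array of
#'   in-region voxels), `truth` (ground-truth `mk`, `k_axial`, `k_radial`
#'   arrays and the per-voxel `params` matrix), and `spec`.
#' @export
simulate_signals <- function(spec, scheme, seed = spec$seed, noise = TRUE,
                             noise_background = TRUE, truth = TRUE) {
  validate_scheme(scheme, for_kurtosis = FALSE)
  nvol <- length(scheme$bvals)
  nvox <- prod(spec$grid_shape)
  X <- dki_design(scheme)
  sig <- matrix(0, nvox, nvol)
  params <- matrix(NA_real_, nvox, 22)
  flags <- rep(.dki_flags[["fit_fail"]], nvox)
  for (r in spec$regions) {
    p <- region_params(r, spec$s0)
    dapp <- -(X[, 2:7, drop = FALSE] %*% p[2:7]) / pmax(scheme$bvals, 1)
    if (any(scheme$bvals > 0 & dapp <= 0))
      stop("invalid ground truth: D_app(n) <= 0 for some direction")
    s <- exp(as.numeric(X %*% p))
    sig[r$voxels, ] <- rep(s, each = length(r$voxels))
    params[r$voxels, ] <- rep(p, each = length(r$voxels))
    flags[r$voxels] <- 0L
  }
  mask <- flags == 0L
  tmaps <- if (truth)
    cpp_kurtosis_maps(t(params), scheme$dirs, flags, -Inf, Inf) else NULL
  if (noise && is.finite(spec$snr_b0)) {
    sigma <- spec$s0 / spec$snr_b0
    with_seed(seed, {
      if (noise_background) {
        sig <- rician(sig, sigma)
      } else {
        sig[mask, ] <- rician(sig[mask, , drop = FALSE], sigma)
      }
    })
  }
  shape <- function(x) array(x, spec$grid_shape)
  list(signals = array(sig, c(spec$grid_shape, nvol)),
       mask = shape(mask),
       truth = if (truth)
         list(mk = shape(tmaps$mk), k_axial = shape(tmaps$k_axial),
              k_radial = shape(tmaps$k_radial), params = params) else NULL,
       spec = spec)
}

# spec with the patient-group kurtosis reduction applied
apply_effect <- function(spec, effect) {
  ids <- vapply(spec$regions, `[[`, "", "id")
  hit <- which(ids == effect$region_id)
  if (length(hit) != 1L) stop("unknown region: ", effect$region_id)
  spec$regions[[hit]]$w15 <- spec$regions[[hit]]$w15 * effect$kurtosis_scale
  spec
}

#' Simulate a two-group phantom cohort
#'
#' Controls are drawn from `spec`; patients from `spec` with the kurtosis
#' tensor scaled by `effect$kurtosis_scale` inside the effect region. Each
#' subject receives independent Rician noise; the whole cohort is
#' deterministic under a fixed `seed`.
#'
#' @param spec a [phantom_spec()].
#' @param effect an [effect_spec()].
#' @param n_patients,n_controls group sizes (>= 2), defaults matching the
#'   emulated study (18 patients, 21 controls).
#' @param scheme a [gradient_scheme()].
#' @param seed integer seed.
#' @param noise_background see [simulate_signals()].
#' @return list with `subjects` (list of 4D signal arrays, patients first),
#'   `group` (factor `"patient"`/`"control"`), `mask`, `truth` (list with
#'   per-group ground-truth maps) and `effect_voxels` (linear indices of the
#'   effect region).
#' @export
simulate_cohort <- function(spec, effect, n_patients = 18L, n_controls = 21L,
                            scheme, seed = 1L, noise_background = TRUE) {
  stopifnot(n_patients >= 2L, n_controls >= 2L)
  spec_pat <- apply_effect(spec, effect)
  group <- factor(rep(c("patient", "control"), c(n_patients, n_controls)),
                  levels = c("patient", "control"))
  subjects <- vector("list", length(group))
  mask <- truth <- NULL
  with_seed(seed, {
    for (i in seq_along(group)) {
      s <- simulate_signals(if (group[i] == "patient") spec_pat else spec,
                            scheme, seed = NULL,
                            noise_background = noise_background)
      subjects[[i]] <- s$signals
      if (is.null(mask)) mask <- s$mask
      if (group[i] == "patient" && is.null(truth$patient))
        truth$patient <- s$truth
      if (group[i] == "control" && is.null(truth$control))
        truth$control <- s$truth
    }
  })
  ids <- vapply(spec$regions, `[[`, "", "id")
  list(subjects = subjects, group = group, mask = mask, truth = truth,
       effect_voxels = spec$regions[[which(ids == effect$region_id)]]$voxels,
       scheme = scheme, spec = spec)
}
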