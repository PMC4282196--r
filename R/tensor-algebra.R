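# Index bookkeeping for the symmetric 2nd-order diffusion tensor D (6 unique
# elements) and the fully symmetric 4th-order kurtosis tensor W (15 unique
# elements), plus the quadratic/quartic forms they induce along a direction.

# unique D elements, row-wise upper triangle
.d_names <- c("dxx", "dyy", "dzz", "dxy", "dxz", "dyz")
.d_idx <- rbind(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
.d_mult <- c(1, 1, 1, 2, 2, 2)

# unique W elements with multinomial multiplicities 4!/prod(counts!)
.w_idx <- rbind(
  c(1, 1, 1, 1), c(2, 2, 2, 2), c(3, 3, 3, 3),
  c(1, 1, 1, 2), c(1, 1, 1, 3), c(1, 2, 2, 2), c(2, 2, 2, 3),
  c(1, 3, 3, 3), c(2, 3, 3, 3),
  c(1, 1, 2, 2), c(1, 1, 3, 3), c(2, 2, 3, 3),
  c(1, 1, 2, 3), c(1, 2, 2, 3), c(1, 2, 3, 3))
.w_mult <- c(1, 1, 1, 4, 4, 4, 4, 4, 4, 6, 6, 6, 12, 12, 12)
.w_names <- apply(.w_idx, 1, function(q)
  paste0("w", paste(c("x", "y", "z")[q], collapse = "")))

d_to_matrix <- function(d6) {
  m <- matrix(0, 3, 3)
  m[cbind(.d_idx[, 1], .d_idx[, 2])] <- d6
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

matrix_to_d <- function(m) m[cbind(.d_idx[, 1], .d_idx[, 2])]

# quadratic form n' D n from the 6 unique elements
quadratic_form <- function(d6, n) {
  sum(.d_mult * d6 * n[.d_idx[, 1]] * n[.d_idx[, 2]])
}

# quartic form sum_ijkl n_i n_j n_k n_l W_ijkl from the 15 unique elements
quartic_form <- function(w15, n) {
  sum(.w_mult * w15 * n[.w_idx[, 1]] * n[.w_idx[, 2]] *
        n[.w_idx[, 3]] * n[.w_idx[, 4]])
}

# expand 15 unique elements to the full symmetric 3x3x3x3 array
w_to_array <- function(w15) {
  a <- array(0, c(3, 3, 3, 3))
  for (k in 1:15) {
    q <- .w_idx[k, ]
    perms <- unique(matrix(q[.all_perm4], ncol = 4))
    a[perms] <- w15[k]
  }
  a
}

# all 24 permutations of 4 indices, built once
.all_perm4 <- local({
  p <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  p <- as.matrix(p[apply(p, 1, function(r) length(unique(r)) == 4L), ])
  dimnames(p) <- NULL
  p
})

array_to_w <- function(a) {
  vapply(1:15, function(k) a[matrix(.w_idx[k, ], 1)], numeric(1))
}

# isotropic kurtosis tensor with apparent kurtosis k along every direction:
# W_ijkl = (k/3) (delta_ij delta_kl + delta_ik delta_jl + delta_il delta_jk)
isotropic_w <- function(k) {
  w <- numeric(15)
  w[1:3] <- k          # W_iiii
  w[10:12] <- k / 3    # W_iijj
  w
}

#' Rotate a kurtosis tensor into the diffusion-tensor eigenframe
#'
#' Transforms the fully symmetric 4th-order kurtosis tensor into the
#' coordinate system spanned by the three orthonormal eigenvectors of the
#' diffusion tensor (columns of `rotation`, ordered by descending
#' eigenvalue): `What_ijkl = sum_abcd R_ai R_bj R_ck R_dl W_abcd`. The
#' eigenframe kurtoses used for axial/radial kurtosis are the diagonal
#' elements `What_iiii` of the result.
#'
#' @param w15 the 15 unique kurtosis-tensor elements (see
#'   [dki_fit()] for the ordering), or a `dki_fit` object from which the
#'   per-voxel tensors and eigenvectors are taken.
#' @param rotation 3x3 orthonormal matrix whose columns are the target frame
#'   axes expressed in the laboratory frame. Ignored when `w15` is a fit
#'   object (the fitted eigenvectors are used).
#' @return the 15 unique elements of the transformed tensor (or an
#'   `nvox x 15` matrix for a fit object).
#' @export
rotate_kt <- function(w15, rotation) {
  if (inherits(w15, "dki_fit")) {
    fit <- w15
    eg <- tensor_eigen(fit)
    out <- matrix(NA_real_, nrow(fit$params), 15,
                  dimnames = list(NULL, .w_names))
    ok <- which(!bitwAnd(fit$flags, 2L))
    for (v in ok)
      out[v, ] <- rotate_kt(fit$params[v, 8:22] / fit$md[v]^2, eg$vectors[, , v])
    return(out)
  }
  r <- rotation
  stopifnot(length(w15) == 15L, all(dim(r) == c(3L, 3L)))
  if (max(abs(crossprod(r) - diag(3))) > 1e-8)
    stop("rotation must be orthonormal")
  a <- w_to_array(w15)
  # successive mode products with t(R): What = W x_n R^T, n = 1..4
  for (mode in 1:4) {
    m <- array(aperm(a, c(mode, setdiff(1:4, mode))), c(3, 27))
    m <- t(r) %*% m
    a <- aperm(array(m, c(3, 3, 3, 3)),
               order(c(mode, setdiff(1:4, mode))))
  }
  stats::setNames(array_to_w(a), .w_names)
}
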