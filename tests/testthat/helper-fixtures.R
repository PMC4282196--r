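# Shared fixtures, built once per test run.

.fixture_env <- new.env()

# the emulated acquisition: b = 0/1000/2000, 25 directions, 51 volumes
test_scheme <- function() {
  if (is.null(.fixture_env$scheme))
    .fixture_env$scheme <- gradient_scheme(25, c(0, 1000, 2000))
  .fixture_env$scheme
}

# a random single-voxel ground truth with positive-definite D and a kurtosis
# tensor of physiological size
random_voxel_truth <- function(seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(9), 3)
  D <- crossprod(A) * 1e-4 + diag(3) * 8e-4
  w15 <- rnorm(15, 0, 0.2)
  w15[1:3] <- abs(w15[1:3]) + 0.8
  list(s0 = 500, D = D,
       d6 = c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3]),
       md = mean(diag(D)), w15 = w15)
}

# noise-free signals for a single-voxel truth over a scheme
forward_signals <- function(truth, scheme) {
  X <- dkimaps:::dki_design(scheme)
  exp(as.numeric(X %*% c(log(truth$s0), truth$d6, truth$md^2 * truth$w15)))
}

# a rotation from ZYX Euler angles
rot3 <- function(a, b, c) {
  rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
  ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3)
  rx <- matrix(c(1, 0, 0, 0, cos(c), sin(c), 0, -sin(c), cos(c)), 3)
  rz %*% ry %*% rx
}

# rotate a scheme's direction vectors
rotate_scheme <- function(scheme, R) {
  scheme$bvecs <- scheme$bvecs %*% t(R)
  scheme$dirs <- scheme$dirs %*% t(R)
  scheme
}
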