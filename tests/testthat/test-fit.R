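test_that("noise-free signals are refit to machine precision", {
  sch <- test_scheme()
  for (seed in c(1, 7, 23)) {
    tr <- random_voxel_truth(seed)
    fit <- dki_fit(forward_signals(tr, sch), sch)
    co <- coef(fit)
    expect_equal(unname(co[1, "s0"]), tr$s0, tolerance = 1e-9)
    expect_lt(max(abs(co[1, 2:7] - tr$d6) / abs(tr$d6)), 1e-6)
    expect_lt(max(abs(co[1, 8:22] - tr$w15)) / max(abs(tr$w15)), 1e-6)
  }
})

test_that("the Gaussian limit W = 0 yields zero apparent kurtosis everywhere", {
  sch <- test_scheme()
  d <- 1e-3
  sig <- exp(as.numeric(dkimaps:::dki_design(sch) %*%
                          c(log(800), d, d, d, 0, 0, 0, rep(0, 15))))
  fit <- dki_fit(sig, sch)
  set.seed(4)
  for (i in 1:5) {
    n <- rnorm(3); n <- n / sqrt(sum(n^2))
    aa <- apparent_along(fit, n)
    expect_equal(aa$d_app, d, tolerance = 1e-10)
    expect_equal(aa$k_app, 0, tolerance = 1e-8)
  }
  km <- kurtosis_maps(fit)
  expect_equal(c(km$mk, km$k_axial, km$k_radial), c(0, 0, 0),
               tolerance = 1e-10)
})

test_that("per-direction estimates match the exact three-point inversion", {
  # independent oracle: along one direction, ln S is quadratic in b and the
  # three points b = 0, 1000, 2000 determine (D_app, K_app) in closed form
  sch <- test_scheme()
  tr <- random_voxel_truth(13)
  fit <- dki_fit(forward_signals(tr, sch), sch)
  for (d in c(2, 9, 17)) {
    n <- sch$dirs[d, ]
    X1 <- dkimaps:::dki_design(
      structure(list(bvals = c(0, 1000, 2000), bvecs = rbind(0, n, n)),
                class = "gradient_scheme"))
    s3 <- exp(as.numeric(X1 %*% c(log(tr$s0), tr$d6, tr$md^2 * tr$w15)))
    y1 <- log(s3[2] / s3[1]); y2 <- log(s3[3] / s3[1])
    d_app <- (y2 - 4 * y1) / 2000
    k_app <- 6 * (y1 + 1000 * d_app) / (1000^2 * d_app^2)
    aa <- apparent_along(fit, n)
    expect_equal(aa$d_app, d_app, tolerance = 1e-9)
    expect_equal(aa$k_app, k_app, tolerance = 1e-9)
  }
})

test_that("voxels with non-positive signals are flagged, not floored", {
  sch <- test_scheme()
  tr <- random_voxel_truth(2)
  s <- forward_signals(tr, sch)
  s_bad <- s; s_bad[10] <- 0
  fit <- dki_fit(rbind(s, s_bad, 0 * s), sch)
  expect_identical(fit$flags[1], 0L)
  expect_identical(fit$flags[2], 1L)                 # excluded volume, still fit
  expect_true(bitwAnd(fit$flags[3], 2L) > 0)         # all-zero voxel fails
  co <- coef(fit)
  expect_lt(max(abs(co[2, 2:7] - tr$d6) / abs(tr$d6)), 1e-6)
  expect_true(all(is.na(co[3, ])))
})

test_that("antipodal directions give identical directional estimates", {
  sch <- test_scheme()
  fit <- dki_fit(forward_signals(random_voxel_truth(8), sch), sch)
  n <- c(0.48, -0.6, sqrt(1 - 0.48^2 - 0.6^2))
  expect_equal(apparent_along(fit, n), apparent_along(fit, -n))
  expect_error(apparent_along(fit, c(1, 1, 0)), "unit-norm")
})

test_that("predict, residuals and simulate close the loop on the signal model", {
  sch <- test_scheme()
  tr <- random_voxel_truth(21)
  s <- forward_signals(tr, sch)
  fit <- dki_fit(s, sch)
  expect_equal(as.numeric(predict(fit)), s, tolerance = 1e-8)
  expect_lt(max(abs(residuals(fit))), 1e-6)
  r1 <- simulate(fit, nsim = 2, seed = 5, snr_b0 = 30)
  r2 <- simulate(fit, nsim = 2, seed = 5, snr_b0 = 30)
  expect_identical(r1, r2)                     # seeded determinism
  expect_false(identical(r1[[1]], r1[[2]]))    # independent replicates
  expect_true(all(r1[[1]] > 0))
})

test_that("fitting a 4D volume respects mask and grid bookkeeping", {
  sch <- test_scheme()
  tr <- random_voxel_truth(6)
  s <- forward_signals(tr, sch)
  vol <- array(rep(s, each = 8), c(2, 2, 2, 51))
  mask <- array(c(TRUE, FALSE), c(2, 2, 2))
  fit <- dki_fit(vol, sch, mask = mask)
  expect_equal(fit$dim, c(2, 2, 2))
  co <- coef(fit)
  expect_true(all(!is.na(co[as.logical(mask), "s0"])))
  expect_true(all(is.na(co[!as.logical(mask), "s0"])))
})
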