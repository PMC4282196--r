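test_that("an isotropic Gaussian voxel decays mono-exponentially", {
  # lambda = 1e-3 mm^2/s on every axis, W = 0, b = 1000 -> S = S0 exp(-1)
  sch <- gradient_scheme(6, c(0, 1000))
  reg <- phantom_region("iso", 1L, rep(1e-3, 3), numeric(15))
  spec <- phantom_spec(grid_shape = c(1L, 1L, 1L), regions = list(reg),
                       s0 = 1000, snr_b0 = 46)
  sim <- simulate_signals(spec, sch, noise = FALSE)
  expect_equal(as.numeric(sim$signals[1, 1, 1, -1]),
               rep(1000 * exp(-1), 6), tolerance = 1e-12)
})

test_that("noise-free phantoms round-trip through the fit to high precision", {
  sch <- test_scheme()
  spec <- default_phantom(snr_b0 = Inf)
  sim <- simulate_signals(spec, sch, noise = FALSE)
  fit <- dki_fit(sim$signals, sch, mask = sim$mask)
  co <- coef(fit)
  truep <- sim$truth$params
  wtrue <- truep[, 8:22] / rowMeans(truep[, 2:4])^2
  m <- as.logical(sim$mask)
  expect_lt(max(abs(co[m, 2:7] - truep[m, 2:7])), 1e-9)         # D, mm^2/s
  expect_lt(max(abs(co[m, 8:22] - wtrue[m, ])) / max(abs(wtrue[m, ])), 1e-6)
  km <- kurtosis_maps(fit)
  expect_lt(max(abs(km$mk[m] - sim$truth$mk[m])), 1e-8)
})

test_that("the requested b0 SNR is realised in the simulated noise", {
  sch <- test_scheme()
  for (snr in c(46, 26)) {
    # big single-region phantom so the SD estimate uses >= 10^4 voxels
    spec <- default_phantom(grid_shape = c(24L, 24L, 24L), snr_b0 = snr)
    spec$regions[[1]]$voxels <- setdiff(seq_len(24^3), spec$regions[[2]]$voxels)
    sim <- simulate_signals(spec, sch, seed = snr)
    b0 <- sim$signals[, , , 1][sim$mask]
    expect_gt(length(b0), 1e4)
    expect_equal(sd(b0), spec$s0 / snr, tolerance = 0.1)
  }
})

test_that("identical seeds reproduce phantoms bit for bit", {
  sch <- test_scheme()
  spec <- default_phantom(snr_b0 = 30)
  s1 <- simulate_signals(spec, sch, seed = 7)
  s2 <- simulate_signals(spec, sch, seed = 7)
  expect_identical(s1$signals, s2$signals)
  s3 <- simulate_signals(spec, sch, seed = 8)
  expect_false(identical(s1$signals, s3$signals))
})

test_that("overlapping regions and invalid effects are rejected", {
  reg1 <- phantom_region("a", 1:10, rep(1e-3, 3), numeric(15))
  reg2 <- phantom_region("b", 10:20, rep(1e-3, 3), numeric(15))
  expect_error(phantom_spec(c(3L, 3L, 3L), regions = list(reg1, reg2)),
               "overlap")
  expect_error(phantom_region("c", 1:2, c(1e-3, 2e-3, 0.5e-3), numeric(15)),
               "lambda")
  expect_error(effect_spec("lesion", 0), "kurtosis_scale")
  expect_error(effect_spec("lesion", 1.2), "kurtosis_scale")
})

test_that("cohorts have the right size, labels and ground-truth effect ratio", {
  sch <- test_scheme()
  idx <- arrayInd(seq_len(8^3), c(8, 8, 8))
  inner <- which(rowSums(sweep(idx, 2, 4.5)^2) <= 9)
  cube <- which(idx[, 1] %in% 4:5 & idx[, 2] %in% 4:5 & idx[, 3] %in% 4:5)
  ev <- c(1.2, 1.0, 0.9) * 1e-3
  spec <- phantom_spec(
    grid_shape = c(8L, 8L, 8L),
    regions = list(
      phantom_region("gm", setdiff(inner, cube), ev, isotropic_kurtosis(0.9)),
      phantom_region("lesion", cube, ev, isotropic_kurtosis(0.9))),
    snr_b0 = Inf)
  co <- simulate_cohort(spec, effect_spec("lesion", 0.6), 3, 2, sch, seed = 5)
  expect_length(co$subjects, 5L)
  expect_equal(as.character(co$group), c(rep("patient", 3), rep("control", 2)))
  # kurtosis is linear in W, so ground-truth regional MK scales exactly
  les <- co$effect_voxels
  expect_equal(mean(co$truth$patient$mk[les]) / mean(co$truth$control$mk[les]),
               0.6, tolerance = 1e-9)
  expect_error(simulate_cohort(spec, effect_spec("nope", 0.6), 3, 2, sch),
               "unknown region")
})
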