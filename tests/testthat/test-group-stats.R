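make_groups <- function(seed, dm = c(6, 6, 6), n1 = 5, n2 = 7, shift = 0) {
  set.seed(seed)
  a <- lapply(seq_len(n1), function(i) array(rnorm(prod(dm), shift), dm))
  b <- lapply(seq_len(n2), function(i) array(rnorm(prod(dm)), dm))
  list(a = a, b = b, mask = array(TRUE, dm))
}

test_that("the voxelwise t statistic matches t.test and flips sign", {
  g <- make_groups(1)
  # scalar oracle on one voxel against stats::t.test with pooled variance
  v1 <- vapply(g$a, function(x) x[2, 3, 4], 0)
  v2 <- vapply(g$b, function(x) x[2, 3, 4], 0)
  ref <- t.test(v1, v2, var.equal = TRUE)
  sm <- two_sample_t_map(g$a, g$b, g$mask)
  expect_equal(sm$t[2, 3, 4], unname(ref$statistic), tolerance = 1e-12)
  expect_equal(sm$p[2, 3, 4], ref$p.value, tolerance = 1e-12)
  expect_identical(sm$df, length(v1) + length(v2) - 2L)
  # antisymmetry under exchanging the groups
  sm2 <- two_sample_t_map(g$b, g$a, g$mask)
  expect_equal(sm2$t, -sm$t, tolerance = 1e-12)
  # equal group means (same generator) -> t centered on zero
  expect_lt(abs(mean(sm$t)), 0.2)
})

test_that("zero-variance voxels are dropped from the mask", {
  g <- make_groups(2)
  for (i in seq_along(g$a)) g$a[[i]][1, 1, 1] <- 5
  for (i in seq_along(g$b)) g$b[[i]][1, 1, 1] <- 5
  expect_message(sm <- two_sample_t_map(g$a, g$b, g$mask), "zero-variance")
  expect_false(sm$mask[1, 1, 1])
  expect_identical(sm$dropped, 1L)
  expect_true(is.na(sm$t[1, 1, 1]))
})

test_that("the voxelwise type-I rate matches the forming threshold", {
  dm <- c(12, 12, 12)
  set.seed(3)
  a <- lapply(1:18, function(i) array(rnorm(prod(dm)), dm))
  b <- lapply(1:21, function(i) array(rnorm(prod(dm)), dm))
  sm <- two_sample_t_map(a, b, array(TRUE, dm))
  rate <- mean(sm$p[sm$mask] < 0.05)
  # 1728 null voxels; binomial SD of the rate is ~0.005
  expect_lt(abs(rate - 0.05), 0.02)
})

test_that("the Monte-Carlo extent threshold behaves at its limits", {
  dm <- c(16, 16, 16)
  mask <- array(TRUE, dm)
  # unsmoothed noise at a very strict forming threshold: isolated voxels are
  # already rare, so single-voxel clusters control the FWE level
  spec <- mc_null_spec(n_iter = 200L, forming_p = 1e-6,
                       smoothness_fwhm_mm = 0, seed = 4L)
  expect_identical(as.integer(mc_cluster_threshold(mask, spec)), 1L)
  # seeded determinism
  spec2 <- mc_null_spec(n_iter = 200L, seed = 9L)
  k1 <- mc_cluster_threshold(mask, spec2)
  k2 <- mc_cluster_threshold(mask, spec2)
  expect_identical(as.integer(k1), as.integer(k2))
  expect_identical(attr(k1, "max_sizes"), attr(k2, "max_sizes"))
  # the returned k_min satisfies the defining tail inequalities
  ms <- attr(k1, "max_sizes")
  expect_lte(mean(ms >= as.integer(k1)), 0.05)
  if (as.integer(k1) > 1L) expect_gt(mean(ms >= as.integer(k1) - 1L), 0.05)
})

test_that("k_min grows with a more lenient forming threshold", {
  dm <- c(16, 16, 16)
  mask <- array(TRUE, dm)
  ks <- vapply(c(0.0001, 0.001, 0.01), function(p) {
    spec <- mc_null_spec(n_iter = 300L, forming_p = p, seed = 11L)
    as.integer(mc_cluster_threshold(mask, spec))
  }, integer(1))
  # a looser threshold admits more voxels, so larger null clusters form
  expect_true(all(diff(ks) >= 0))
  expect_gt(ks[3], ks[1])
})

fake_stat <- function(tvol, mask, df = 37L) {
  structure(list(t = tvol, p = 2 * pt(-abs(tvol), df), df = df,
                 mask = mask, n = c(18L, 21L), dropped = 0L),
            class = "stat_map")
}

test_that("cluster extraction respects connectivity and the extent filter", {
  dm <- c(8, 8, 8)
  tvol <- array(0, dm)
  # two corner-touching suprathreshold voxels
  tvol[2, 2, 2] <- 8; tvol[3, 3, 3] <- 7
  st <- fake_stat(tvol, array(TRUE, dm))
  c26 <- extract_clusters(st, connectivity = 26L)
  c6 <- extract_clusters(st, connectivity = 6L)
  expect_identical(nrow(c26), 1L)
  expect_identical(c26$n_voxels, 2L)
  expect_identical(nrow(c6), 2L)
  # corner neighbours are not 18-connected either
  expect_identical(nrow(extract_clusters(st, connectivity = 18L)), 2L)
  # extent filter removes both singleton clusters
  expect_identical(nrow(extract_clusters(st, k_min = 2L, connectivity = 6L)), 0L)
})

test_that("cluster tables report signed peaks, world coordinates and extents", {
  dm <- c(10, 10, 10)
  tvol <- array(0, dm)
  tvol[2:4, 2, 2] <- c(5, 9, 6)      # positive cluster of 3, peak at (3,2,2)
  tvol[7:8, 7, 7] <- -6              # negative cluster of 2
  st <- fake_stat(tvol, array(TRUE, dm))
  cl <- extract_clusters(st, voxdim = c(2, 2, 2), origin = c(-10, -10, -10))
  expect_identical(cl$n_voxels, c(3L, 2L))          # sorted by extent
  expect_equal(cl$peak_t, c(9, -6))
  expect_equal(unlist(cl[1, c("peak_x_mm", "peak_y_mm", "peak_z_mm")]),
               c(peak_x_mm = -6, peak_y_mm = -8, peak_z_mm = -8))
  # extents partition the suprathreshold voxel count at k_min = 1
  expect_identical(sum(cl$n_voxels),
                   sum(abs(tvol) > qt(1 - 0.001 / 2, st$df)))
  # opposite signs never merge even when adjacent
  tvol2 <- array(0, dm); tvol2[4, 4, 4] <- 7; tvol2[5, 4, 4] <- -7
  cl2 <- extract_clusters(fake_stat(tvol2, array(TRUE, dm)))
  expect_identical(nrow(cl2), 2L)
})

test_that("effect recovery reports hits and false positives exactly", {
  dm <- c(8, 8, 8)
  tvol <- array(0, dm); tvol[1:10] <- 8
  cl <- extract_clusters(fake_stat(tvol, array(TRUE, dm)), connectivity = 26L)
  rep1 <- effect_recovery_report(cl, truth_voxels = 3:12)
  expect_equal(rep1$hit_rate, 0.8)                  # 8 of 10 true voxels hit
  expect_identical(rep1$false_positive_voxels, 2L)  # voxels 1:2 outside truth
  expect_identical(rep1$detected_voxels, 10L)
})
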