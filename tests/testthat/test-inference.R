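test_that("spatial similarity matches the covariance-formula oracle", {
  set.seed(6)
  P <- matrix(rnorm(5 * 16), 5, 16)
  ref <- rnorm(16)
  sim <- spatial_similarity(P, ref)
  for (v in 1:5) expect_equal(sim$r[v], oracle_pearson(P[v, ], ref),
                              tolerance = 1e-12)
  # clipping keeps Fisher z finite at |r| = 1
  simd <- spatial_similarity(rbind(ref, -ref), ref)
  expect_equal(simd$r, c(1, -1))
  expect_equal(simd$z, c(atanh(1 - 1e-7), -atanh(1 - 1e-7)))
  expect_true(all(is.finite(simd$z)))
  # z strictly increasing in r on the clipped domain
  rr <- seq(-0.99, 0.99, by = 0.01)
  zz <- atanh(pmin(pmax(rr, -(1 - 1e-7)), 1 - 1e-7))
  expect_true(all(diff(zz) > 0))
  # zero-variance voxel flagged missing
  simz <- spatial_similarity(rbind(ref, rep(1, 16)), ref)
  expect_true(is.na(simz$r[2]))
})

test_that("cluster means respect the minimum-size filter", {
  z <- rbind(s1 = rep(0.5, 10), s2 = rep(1, 10))
  cl <- c(rep("A", 6), rep("B", 4))
  m <- cluster_mean_z(z, cl, min_voxels = 1)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(unname(m["s1", "A"]), 0.5)
  m2 <- cluster_mean_z(z, cl, min_voxels = 5)
  expect_equal(colnames(m2), "A")
  expect_error(cluster_mean_z(z, cl, min_voxels = 200), "minimum size")
  # boundary: a cluster of exactly min_voxels - 1 is excluded
  cl199 <- c(rep("big", 7), rep("small", 3))
  expect_equal(colnames(cluster_mean_z(z, cl199, min_voxels = 4)), "big")
})

test_that("tmax permutation enumerates the sign-flip null exhaustively", {
  set.seed(17)
  x <- matrix(rnorm(10 * 5), 10, 5)
  res <- tmax_permutation(x)
  expect_equal(res$n_permutations, 1024L)     # 2^10 assignments
  expect_true(res$exhaustive)
  expect_equal(res$df, 9L)
  # identity assignment in the null -> corrected p >= 1 / 2^n
  expect_true(all(res$p_corrected >= 1 / 1024))
  # observed t matches a direct t.test
  tt <- vapply(1:5, function(j) t.test(x[, j])$statistic, numeric(1))
  expect_equal(unname(res$t_obs), unname(tt), tolerance = 1e-10)
  # strong signal everywhere is detected
  res2 <- tmax_permutation(x + 3)
  expect_true(all(res2$p_corrected < 0.05))
})

test_that("degenerate tmax inputs are handled", {
  # all-zero data: no rejections at any level
  x0 <- matrix(0, 8, 3)
  res0 <- tmax_permutation(x0)
  expect_equal(unname(res0$t_obs), rep(0, 3))
  expect_equal(unname(res0$p_corrected), rep(1, 3))
  # constant nonzero cluster: t undefined, excluded with a warning
  set.seed(2)
  x <- cbind(rnorm(8), 1)
  expect_warning(res <- tmax_permutation(x), "zero-variance")
  expect_equal(length(res$t_obs), 1L)
  expect_error(suppressWarnings(tmax_permutation(matrix(1, 6, 2))),
               "no testable")
  # Monte-Carlo branch for large n includes the identity assignment
  xx <- matrix(rnorm(20 * 2), 20, 2)
  resmc <- tmax_permutation(xx, n_perm = 500, seed = 5)
  expect_false(resmc$exhaustive)
  expect_equal(resmc$n_permutations, 500L)
  expect_true(all(resmc$p_corrected >= 1 / 500))
})

test_that("voxel back-projection recovers contrast surfaces", {
  sp <- tiny_space()
  ids <- sp$candidates$id
  g <- setNames(5 * (sp$candidates$x1 - sp$candidates$x2), ids)
  hsurf <- setNames(rep(1, 4), ids)
  tr <- ground_truth(list(dfpn = g, vfpn = hsurf), noise_sd = 0,
                     voxel_noise_sd = 0.05)
  tasks <- rep(ids, 3)
  d <- block_design("exp1", 12, block_conditions = tasks)
  run <- simulate_run(sp, tr, d, voxels_per_roi = 2, seed = 8)
  vm <- voxel_prediction_maps(run, "vfpn", sp, tune = default_hyper())
  # dfpn voxels: predictions ~ g - h at candidates
  want <- unname(g[ids] - hsurf[ids])
  for (v in which(vm$roi == "dfpn"))
    expect_equal(unname(vm$predictions[v, ]), want, tolerance = 0.25)
  # vfpn voxels self-contrast to ~0
  for (v in which(vm$roi == "vfpn"))
    expect_lt(max(abs(vm$predictions[v, ])), 0.25)
})

test_that("comparison against hypothesized maps is null when maps agree", {
  sp <- tiny_space()
  ids <- sp$candidates$id
  ref <- setNames(c(3, 1, -1, -2), ids)
  # voxel maps = reference + tiny jitter, so group and hypothesized
  # similarities coincide when both references are the same map
  set.seed(31)
  mk_maps <- function() {
    P <- matrix(rep(ref, each = 6), 6, 4, dimnames = list(NULL, ids)) +
      matrix(rnorm(24, sd = 0.05), 6, 4)
    structure(list(predictions = P, roi = rep(c("A", "B"), each = 3),
                   space = sp), class = "voxel_maps")
  }
  maps <- lapply(1:6, function(i) mk_maps())
  out <- compare_with_hypothesized(maps, ref, ref,
                                   clusters = rep(c("A", "B"), each = 3),
                                   min_voxels = 2)
  expect_equal(max(abs(out$diff_matrix)), 0, tolerance = 1e-12)
  expect_true(all(out$perm$p_corrected >= 0.99))
  expect_equal(out$perm$n_permutations, 64L)
})
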