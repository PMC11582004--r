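aff4 <- diag(c(4, 4, 4, 1))

make_vols <- function(Y, dims, aff = aff4) {
  lapply(seq_len(nrow(Y)), function(i) new_volume(array(Y[i, ], dims), aff))
}

test_that("component labelling agrees with the transitive-closure oracle", {
  dims <- c(6L, 6L, 4L)
  set.seed(31)
  for (rep in 1:20) {
    lin <- sort(sample(prod(dims), 25))
    for (conn in c(6L, 18L, 26L)) {
      lab <- label_components(lin, dims, conn)
      orc <- oracle_components(lin, dims, conn)
      ## identical partitions (labels may be permuted)
      expect_true(all(outer(lab, lab, `==`) == outer(orc, orc, `==`)))
      expect_equal(max(lab), max(orc))
    }
  }
})

test_that("crafted plateaus give hand-countable clusters", {
  dims <- c(8L, 8L, 3L)
  arr <- array(FALSE, dims)
  arr[2:4, 2:4, 2] <- TRUE                     # 3x3x1 plateau
  arr[6:8, 6:8, 2] <- TRUE                     # disjoint 3x3x1 plateau
  lin <- which(arr)
  lab <- label_components(lin, dims, 18L)
  expect_equal(max(lab), 2L)
  expect_equal(sort(as.integer(table(lab))), c(9L, 9L))
  ## edge-connected diagonal pair: joined under 18, split under 6
  arr2 <- array(FALSE, dims)
  arr2[1, 1, 1] <- TRUE
  arr2[2, 2, 1] <- TRUE
  expect_equal(max(label_components(which(arr2), dims, 18L)), 1L)
  expect_equal(max(label_components(which(arr2), dims, 6L)), 2L)
})

test_that("voxelwise regression equals the per-voxel lm oracle", {
  dims <- c(6L, 6L, 6L)
  n <- 12L
  set.seed(5)
  Y <- matrix(rnorm(n * prod(dims)), n)
  x <- rnorm(n)
  mask <- new_mask(array(TRUE, dims), aff4)
  glm <- voxelwise_regression(make_vols(Y, dims), x, mask)
  orc <- oracle_ols(Y, x)
  expect_lt(max(abs(as.vector(glm$beta_map$data) - orc$beta) /
                  pmax(abs(orc$beta), 1e-12)), 1e-10)
  expect_lt(max(abs(as.vector(glm$t_map$data) - orc$t) /
                  pmax(abs(orc$t), 1e-12)), 1e-10)
  expect_identical(glm$df, n - 2L)
})

test_that("noise-free voxels hit the sentinel; null t-maps centre on zero", {
  dims <- c(4L, 4L, 2L)
  n <- 10L
  x <- seq_len(n)
  Y <- matrix(rep(2 * x + 1, prod(dims)), n)   # exact linear, every voxel
  Y[, 1] <- 5                                   # constant voxel
  mask <- new_mask(array(TRUE, dims), aff4)
  glm <- voxelwise_regression(make_vols(Y, dims), x, mask)
  tv <- as.vector(glm$t_map$data)
  expect_equal(tv[1], 0)                        # zero-variance voxel
  expect_true(all(tv[-1] == 1e6))               # clamped sentinel, right sign
  set.seed(8)
  Yn <- matrix(rnorm(n * prod(dims)), n)
  glm0 <- voxelwise_regression(make_vols(Yn, dims), sample(x), mask)
  expect_lt(abs(mean(as.vector(glm0$t_map$data))), 0.5)
  expect_error(voxelwise_regression(make_vols(Yn, dims), rep(1, n), mask),
               "constant")
  expect_error(voxelwise_regression(make_vols(Yn[1:2, , drop = FALSE], dims),
                                    x[1:2], mask), "at least 3")
})

test_that("cluster thresholding records extent, peak and direction", {
  dims <- c(8L, 8L, 3L)
  n <- 14L
  set.seed(77)
  x <- rnorm(n)
  Y <- matrix(rnorm(n * prod(dims), sd = 1), n)
  blob <- array(FALSE, dims)
  blob[2:4, 2:4, 2] <- TRUE
  Y[, which(blob)] <- Y[, which(blob)] + 3 * x  # strong positive effect
  mask <- new_mask(array(TRUE, dims), aff4)
  glm <- voxelwise_regression(make_vols(Y, dims), x, mask)
  cs <- cluster_threshold(glm, cdt_p = 0.001)
  expect_gte(nrow(cs$clusters), 1L)
  top <- cs$clusters[1L, ]
  expect_true(all(cs$voxels[[1L]] %in% which(blob)) ||
                top$extent >= sum(blob) * 0.8)
  expect_gt(top$peak_t, stats::qt(0.999, n - 2))
  ## nothing survives an absurdly strict threshold
  cs0 <- cluster_threshold(glm, cdt_p = 1e-12)
  expect_equal(nrow(cs0$clusters), 0L)
  ## negative direction finds the mirrored effect
  glmn <- voxelwise_regression(make_vols(-Y, dims), x, mask,
                               direction = "negative")
  csn <- cluster_threshold(glmn, cdt_p = 0.001)
  expect_gte(nrow(csn$clusters), 1L)
  expect_lt(csn$clusters$peak_t[1L], 0)
})

test_that("permutation inference is seeded, deterministic and floored", {
  dims <- c(6L, 6L, 4L)
  n <- 12L
  set.seed(13)
  x <- rnorm(n)
  Y <- matrix(rnorm(n * prod(dims)), n)
  blob <- array(FALSE, dims)
  blob[2:5, 2:5, 2:3] <- TRUE
  Y[, which(blob)] <- Y[, which(blob)] + 4 * x
  mask <- new_mask(array(TRUE, dims), aff4)
  vols <- make_vols(Y, dims)
  cs1 <- permutation_fwe(vols, x, mask, n_perm = 199, seed = 4)
  cs2 <- permutation_fwe(vols, x, mask, n_perm = 199, seed = 4)
  expect_identical(cs1$clusters, cs2$clusters)
  expect_identical(cs1$null_max_extent, cs2$null_max_extent)
  ## planted effect dwarfs every permuted maximum: p at the floor
  expect_equal(min(cs1$clusters$p_fwe), 1 / 200)
  expect_true(any(cs1$clusters$significant))
  expect_error(permutation_fwe(vols, x, mask, n_perm = 199), "seed")
  expect_error(permutation_fwe(vols, x, mask, n_perm = 10, seed = 1), "n_perm")
})

test_that("peak seeds sit on the strongest significant cluster", {
  dims <- c(10L, 10L, 6L)
  aff <- aff4
  aff[1:3, 4] <- c(-40, -16, -6)
  n <- 14L
  set.seed(3)
  x <- rnorm(n)
  Y <- matrix(rnorm(n * prod(dims)), n)
  geom <- new_volume(array(0, dims), aff)
  ijk <- mni_to_voxel(geom, c(-28, 0, 6))
  blob <- array(FALSE, dims)
  blob[ijk[1] + 0:1 + 1L, ijk[2] + 0:1 + 1L, ijk[3] + 0:1 + 1L] <- TRUE
  Y[, which(blob)] <- Y[, which(blob)] + 5 * x
  ## make the stated peak voxel the strongest by boosting it further
  pk <- (ijk[3]) * 100L + (ijk[2]) * 10L + ijk[1] + 1L  # linear by hand
  pk <- ijk[1] + 1L + dims[1] * ijk[2] + dims[1] * dims[2] * ijk[3]
  Y[, pk] <- Y[, pk] + 2 * x
  mask <- new_mask(array(TRUE, dims), aff)
  cs <- permutation_fwe(make_vols(Y, dims, aff), x, mask, n_perm = 199,
                        seed = 11)
  seed <- peak_seed(cs, radius = 5)
  expect_equal(seed$center_mni, c(-28, 0, 6))
  expect_equal(seed$radius, 5)
  ## sphere membership equals a brute-force distance scan
  sv <- seed_voxels(geom, seed)
  xyz <- voxel_grid_mni(geom)
  manual <- which(sqrt(colSums((t(xyz) - c(-28, 0, 6))^2)) <= 5)
  expect_identical(sv, manual)
  ## shrinking radius leaves only the centre voxel
  tiny <- seed_spec(c(-28, 0, 6), radius = 1e-6)
  expect_equal(length(seed_voxels(geom, tiny)), 1L)
  ## no significant cluster -> rejection
  null_cs <- permutation_fwe(make_vols(matrix(rnorm(n * prod(dims)), n), dims, aff),
                             x, mask, n_perm = 199, seed = 12)
  if (!any(null_cs$clusters$significant)) {
    expect_error(peak_seed(null_cs), "no significant cluster")
  }
  expect_error(seed_spec(c(0, 0, 0), radius = 0), "radius")
})

test_that("null family-wise rejection stays within the valid range", {
  r <- simulate_cluster_fwer(n_datasets = 60, n_perm = 199, seed = 99)
  expect_lte(r$fwer, 0.05 + 2 * sqrt(0.05 * 0.95 / 60))
})
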