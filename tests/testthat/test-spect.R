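geom4 <- function(dims = c(6L, 6L, 6L)) {
  aff <- diag(c(4, 4, 4, 1))
  aff[1:3, 4] <- -4 * (dims - 1) / 2
  aff
}

test_that("occipital rescaling yields local SBR with unit reference mean", {
  dims <- c(6L, 6L, 6L)
  aff <- geom4(dims)
  arr <- array(0.8, dims)
  arr[5, 5, 5] <- 2.0
  occ <- array(FALSE, dims)
  occ[, 1, ] <- TRUE
  vol <- new_volume(arr, aff)
  msk <- new_mask(occ, aff)
  out <- rescale_local_sbr(vol, msk)
  expect_equal(mean(out$data[occ]), 1)
  expect_equal(out$data[5, 5, 5], 2.5)        # 2.0 / 0.8
  ## scale invariance and idempotence
  scaled <- vol
  scaled$data <- vol$data * 3.7
  expect_equal(rescale_local_sbr(scaled, msk)$data, out$data)
  expect_equal(rescale_local_sbr(out, msk)$data, out$data)
  zero <- vol
  zero$data[] <- 0
  expect_error(rescale_local_sbr(zero, msk), "positive")
})

test_that("DaTStriatum mask thresholds the cohort mean at 2.0 inclusively", {
  dims <- c(4L, 4L, 4L)
  aff <- geom4(dims)
  a <- array(1, dims)
  a[1, 1, 1] <- 2.0
  a[2, 1, 1] <- 1.999
  a[3, 3, 3] <- 3.0
  m <- build_datstriatum_mask(list(new_volume(a, aff)), 2.0)
  expect_true(m$data[1, 1, 1])                 # boundary included
  expect_false(m$data[2, 1, 1])                # strictly below excluded
  expect_true(m$data[3, 3, 3])
  ## raising the threshold never adds voxels
  m25 <- build_datstriatum_mask(list(new_volume(a, aff)), 2.5)
  expect_true(all(which(m25$data) %in% which(m$data)))
  ## plateau phantom equals the voxel-by-voxel thresholding oracle
  set.seed(9)
  vols <- lapply(1:5, function(i) new_volume(array(runif(64, 0, 4), dims), aff))
  mm <- build_datstriatum_mask(vols, 2.0)
  avg <- Reduce(`+`, lapply(vols, `[[`, "data")) / 5
  expect_identical(mm$data, avg >= 2.0)
  bad <- new_volume(array(1, c(5L, 4L, 4L)), aff)
  expect_error(build_datstriatum_mask(list(vols[[1]], bad)), "geometry mismatch")
})

test_that("mirroring reflects across the mid-sagittal plane exactly", {
  geom <- phantom_geometry()
  arr <- geom$data
  idx <- mni_to_voxel(geom, c(-26, 0, 6)) + 1L   # on-grid coordinate
  arr[idx[1], idx[2], idx[3]] <- 5
  vol <- new_volume(arr, geom$affine)
  mir <- mirror_volume(vol)
  ridx <- mni_to_voxel(geom, c(26, 0, 6)) + 1L
  expect_equal(mir$data[ridx[1], ridx[2], ridx[3]], 5)
  expect_identical(mirror_volume(mir)$data, vol$data)   # involution, bit-exact
  ## centre of gravity flips its x sign, y/z unchanged (the zero-valued
  ## background is dropped from the weights, with a warning by design)
  msk <- new_mask(array(TRUE, dim(arr)), geom$affine)
  s1 <- suppressWarnings(striatal_summary(vol, msk))
  s2 <- suppressWarnings(striatal_summary(mir, msk))
  expect_equal(s2$cog_mni * c(-1, 1, 1), s1$cog_mni)
  ## asymmetric grid is rejected with an offset diagnostic
  off <- vol
  off$affine[1, 4] <- off$affine[1, 4] + 2
  expect_error(mirror_volume(off), "not symmetric")
})

test_that("striatal summary matches a brute-force loop over masked voxels", {
  dims <- c(5L, 5L, 5L)
  aff <- geom4(dims)
  set.seed(21)
  arr <- array(runif(prod(dims), 0.2, 3), dims)
  msk <- new_mask(array(runif(prod(dims)) < 0.4, dims), aff)
  s <- striatal_summary(new_volume(arr, aff), msk)
  ## brute force
  vals <- c()
  best <- -Inf
  best_xyz <- NULL
  num <- c(0, 0, 0)
  den <- 0
  for (k in 1:dims[3]) for (j in 1:dims[2]) for (i in 1:dims[1]) {
    if (!msk$data[i, j, k]) next
    v <- arr[i, j, k]
    vals <- c(vals, v)
    xyz <- drop(aff %*% c(i - 1, j - 1, k - 1, 1))[1:3]
    if (v > best) { best <- v; best_xyz <- xyz }
    num <- num + v * xyz
    den <- den + v
  }
  expect_equal(s$mean_local_sbr, mean(vals))
  expect_equal(s$max_local_sbr, best)
  expect_equal(s$max_voxel_mni, best_xyz)
  expect_equal(s$cog_mni, num / den)
  expect_gte(s$max_local_sbr, s$mean_local_sbr)
})

test_that("degenerate summaries behave: single voxel, midpoint, empty mask", {
  dims <- c(5L, 3L, 3L)
  aff <- geom4(dims)
  arr <- array(0, dims)
  msk_arr <- array(FALSE, dims)
  arr[2, 2, 2] <- 1.5
  msk_arr[2, 2, 2] <- TRUE
  s1 <- striatal_summary(new_volume(arr, aff), new_mask(msk_arr, aff))
  expect_equal(s1$cog_mni, s1$max_voxel_mni)
  ## two equal voxels: CoG at midpoint, argmax tie broken lexicographically
  arr2 <- array(0, dims)
  arr2[1, 2, 2] <- 2
  arr2[4, 2, 2] <- 2
  msk2 <- new_mask(arr2 > 0, aff)
  s2 <- striatal_summary(new_volume(arr2, aff), msk2)
  mid <- (drop(aff %*% c(0, 1, 1, 1))[1:3] + drop(aff %*% c(3, 1, 1, 1))[1:3]) / 2
  expect_equal(s2$cog_mni, mid)
  expect_equal(s2$max_voxel_mni, drop(aff %*% c(0, 1, 1, 1))[1:3])
  expect_error(striatal_summary(new_volume(arr, aff),
                                new_mask(array(FALSE, dims), aff)), "empty")
})

test_that("rising cohort deficit shifts the surviving intensity medially", {
  geom <- phantom_geometry()
  reg <- phantom_regions(geom)
  defs <- seq(0.02, 0.98, length.out = 48)
  ## centre of gravity: deterministic medial (x -> 0) drift, noise-free
  cogx <- vapply(seq(0.05, 0.95, length.out = 10), function(d) {
    v <- gen_striatal_volume(geom, d, 0, noise_sd = 0, regions = reg)
    lv <- rescale_local_sbr(v, reg$occipital)
    striatal_summary(lv, reg$striatum_left)$cog_mni[1]
  }, numeric(1))
  expect_true(all(diff(cogx) > 0))
  ## maximum-intensity voxel: severely depleted subjects peak more medially
  ## than mildly depleted ones at realistic voxel noise
  mx <- vapply(seq_along(defs), function(i) {
    v <- gen_striatal_volume(geom, defs[i], 0, noise_sd = 0.1,
                             seed = i, regions = reg)
    lv <- rescale_local_sbr(v, reg$occipital)
    striatal_summary(lv, reg$striatum_left)$max_voxel_mni[1]
  }, numeric(1))
  expect_gt(mean(mx[defs > 0.5]), mean(mx[defs < 0.5]))
})

test_that("volumes round-trip through NIfTI with affine intact", {
  geom <- phantom_geometry()
  v <- gen_striatal_volume(geom, 0.4, 0.2, seed = 1)
  path <- tempfile(fileext = ".nii.gz")
  write_volume(v, path)
  back <- read_volume(path)
  expect_equal(back$data, v$data, tolerance = 1e-6)
  expect_equal(back$affine, v$affine, tolerance = 1e-5)
})
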