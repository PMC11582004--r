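aff4c <- diag(c(4, 4, 4, 1))

toy_run <- function(Y, dims, tr = 0.72, motion = NULL) {
  new_bold_run(array(t(Y), c(dims, nrow(Y))), aff4c, tr = tr, motion = motion)
}

test_that("framewise displacement sums translations and scaled rotations", {
  nt <- 20L
  m <- matrix(0, nt, 6)
  expect_equal(framewise_displacement(m), rep(0, nt))
  m2 <- m
  m2[10:nt, 1] <- 0.6                            # 0.6 mm step at frame 10
  fd <- framewise_displacement(m2)
  expect_equal(fd[10], 0.6)
  expect_equal(sum(fd), 0.6)
  m3 <- m
  m3[5:nt, 4] <- 0.01                            # 0.01 rad on one axis
  expect_equal(framewise_displacement(m3)[5], 0.5)  # 50 mm sphere arc
  expect_error(framewise_displacement(m[, 1:5]), "6 columns")
  ## scrubbing drops exactly the offending frame at the 0.5 mm threshold
  run <- new_bold_run(array(rnorm(8 * nt), c(2, 2, 2, nt)), aff4c, motion = m2)
  run <- scrub_run(run, 0.5)
  expect_false(run$frame_keep[10])
  expect_equal(sum(!run$frame_keep), 1L)
})

test_that("nuisance regression projects out confounds exactly", {
  dims <- c(4L, 4L, 2L)
  nv <- prod(dims)
  nt <- 80L
  set.seed(12)
  Y <- matrix(rnorm(nt * nv), nt)
  wm <- array(FALSE, dims); wm[1, , ] <- TRUE
  csf <- array(FALSE, dims); csf[4, , ] <- TRUE
  wm_m <- new_mask(wm, aff4c); csf_m <- new_mask(csf, aff4c)
  motion <- matrix(rnorm(nt * 6, sd = 0.01), nt)
  run <- toy_run(Y, dims, motion = motion)
  res <- nuisance_regress(run, wm_m, csf_m)
  R <- t(matrix(res$data, nv, nt))
  ## residuals orthogonal to every regressor
  X <- cbind(1, motion, rowMeans(Y[, which(wm)]), rowMeans(Y[, which(csf)]),
             rowMeans(Y))
  expect_lt(max(abs(crossprod(X, R))), 1e-8)
  ## matches a brute-force per-voxel projection oracle
  Q <- qr.Q(qr(X))
  expect_equal(R, Y - Q %*% crossprod(Q, Y), tolerance = 1e-10)
  ## a voxel equal to the global signal (of its own dataset) is annihilated
  Y2 <- Y
  Y2[, 5] <- rowSums(Y2[, -5]) / (nv - 1)      # fixed point: col 5 = global mean
  r2 <- nuisance_regress(toy_run(Y2, dims, motion = motion), wm_m, csf_m)
  gs_resid <- t(matrix(r2$data, nv, nt))[, 5]
  expect_lt(max(abs(gs_resid)), 1e-8)
  ## rank-deficient confounds are rejected with the column named
  bad_motion <- motion
  bad_motion[, 2] <- bad_motion[, 1]
  expect_error(nuisance_regress(toy_run(Y, dims, motion = bad_motion),
                                wm_m, csf_m), "rank-deficient")
})

test_that("band-pass keeps 0.04 Hz, rejects DC and 0.2 Hz", {
  nt <- 200L
  tr <- 0.72
  tt <- (0:(nt - 1)) * tr
  gain_at <- function(f) {
    y <- sin(2 * pi * f * tt)
    run <- new_bold_run(array(y, c(1, 1, 1, nt)), aff4c, tr = tr)
    out <- as.vector(bandpass_run(run)$data)
    fit <- lm(out ~ sin(2 * pi * f * tt) + cos(2 * pi * f * tt))
    sqrt(sum(coef(fit)[2:3]^2))
  }
  expect_gt(gain_at(0.04), 0.95)
  expect_lt(gain_at(0.20), 0.10)
  dc <- new_bold_run(array(3, c(1, 1, 1, nt)), aff4c, tr = tr)
  expect_lt(max(abs(bandpass_run(dc)$data)), 1e-6)
  expect_error(bandpass_run(dc, low = 0.08, high = 0.01), "exceed")
})

test_that("seed maps use unsmoothed seeds, clamp r and attenuate with noise", {
  dims <- c(7L, 7L, 5L)
  nv <- prod(dims)
  nt <- 400L
  set.seed(44)
  s <- rnorm(nt)
  geom <- new_volume(array(0, dims), aff4c)
  centre_lin <- 4L + dims[1] * 3L + dims[1] * dims[2] * 2L  # voxel (4,4,3)
  Y <- matrix(rnorm(nt * nv), nt)
  Y[, centre_lin] <- s                          # seed voxel = latent exactly
  sigma <- 0.8
  targets <- c(2, 9, 30, 100, 200)
  Y[, targets] <- s + sigma * matrix(rnorm(nt * length(targets)), nt)
  run <- toy_run(Y, dims)
  centre_mni <- drop(voxel_to_mni(geom, matrix(c(3, 3, 2), 1)))
  sp <- seed_spec(centre_mni, radius = 1)      # single-voxel seed
  cm <- seed_map(run, sp, fwhm = 0)            # no smoothing: analytic check
  z <- cm$z_map$data
  ## seed voxel correlates perfectly -> clamped Fisher z
  expect_gt(z[4, 4, 3], atanh(1 - 1e-9))
  expect_true(is.finite(z[4, 4, 3]))
  ## attenuation r = 1/sqrt(1 + sigma^2) at the planted targets
  r_obs <- tanh(z[targets])
  expect_equal(mean(r_obs), 1 / sqrt(1 + sigma^2), tolerance = 0.05)
  ## independent voxels stay near zero
  others <- setdiff(seq_len(nv), c(centre_lin, targets))
  expect_lt(abs(mean(z[others])), 0.02)
  ## Fisher antisymmetry under signal negation
  Yn <- Y
  Yn[, targets] <- -Y[, targets]
  zn <- seed_map(toy_run(Yn, dims), sp, fwhm = 0)$z_map$data
  expect_equal(zn[targets], -z[targets], tolerance = 1e-12)
  ## zero-variance seed is rejected
  Yz <- Y
  Yz[, centre_lin] <- 0
  expect_error(seed_map(toy_run(Yz, dims), sp, fwhm = 0), "zero variance")
})

test_that("z-map averaging is commutative and idempotent", {
  lay <- rsfmri_layout()
  r1 <- gen_rsfmri(lay, n_frames = 60, seed = 1)
  r2 <- gen_rsfmri(lay, n_frames = 60, seed = 2)
  m1 <- seed_map(r1, lay$seed, fwhm = 0, subject_id = "a")
  m2 <- seed_map(r2, lay$seed, fwhm = 0, subject_id = "a")
  avg12 <- average_z_maps(list(m1, m2))
  avg21 <- average_z_maps(list(m2, m1))
  expect_equal(avg12$z_map$data, avg21$z_map$data)
  expect_equal(average_z_maps(list(m1, m1))$z_map$data, m1$z_map$data)
})

test_that("group inference flags identical positive maps at the p floor", {
  dims <- c(6L, 6L, 4L)
  blob <- array(FALSE, dims)
  blob[2:4, 2:4, 2] <- TRUE
  mk_map <- function(eps) {
    arr <- array(rnorm(prod(dims), sd = 0.01), dims)
    arr[blob] <- arr[blob] + 1
    structure(list(z_map = new_volume(arr + eps, aff4c), subject_id = "x",
                   seed = seed_spec(c(0, 0, 0))), class = "connectivity_map")
  }
  set.seed(10)
  maps <- lapply(rnorm(10, sd = 0.001), mk_map)
  g <- group_connectivity(maps, n_perm = 500, seed = 6)
  expect_true(any(g$clusters$significant))
  expect_equal(min(g$clusters$p_fwe), 1 / 501)
  top <- g$voxels[[1L]]
  expect_setequal(top, which(blob))
  expect_error(group_connectivity(maps[1:2], n_perm = 500, seed = 6),
               "at least 3")
  g2 <- group_connectivity(maps, n_perm = 500, seed = 6)
  expect_identical(g$clusters, g2$clusters)
})

test_that("overlap maps intersect significance masks voxelwise", {
  dims <- c(6L, 6L, 4L)
  mk_cs <- function(voxels) {
    tab <- data.frame(cluster_id = 1L, extent = length(voxels), peak_t = 5,
                      peak_x = 0, peak_y = 0, peak_z = 0, p_fwe = 0.001,
                      significant = TRUE)
    structure(list(clusters = tab, voxels = list(voxels), dims = dims,
                   affine = aff4c, cdt_p = 0.001, alpha = 0.05, df = 10L,
                   direction = "positive", n_perm = 100L),
              class = "cluster_set")
  }
  a <- mk_cs(1:20)
  b <- mk_cs(11:30)
  ov <- overlap_map(a, b)
  expect_identical(which(ov$data), 11:20)
  expect_equal(sum(overlap_map(a, mk_cs(40:50))$data), 0L)
  expect_identical(which(overlap_map(a, a)$data), 1:20)
})

test_that("preprocessing order runs scrub, regress, filter end to end", {
  lay <- rsfmri_layout()
  run <- gen_rsfmri(lay, n_frames = 120, motion_spike_frames = 60, seed = 77)
  run <- scrub_run(run, 0.5)
  expect_false(all(run$frame_keep))
  run <- nuisance_regress(run, lay$wm_mask, lay$csf_mask)
  expect_equal(dim(run$data)[4], sum(run$frame_keep))
  run <- bandpass_run(run)
  cm <- seed_map(run, lay$seed, fwhm = 5, subject_id = "s")
  expect_true(all(is.finite(cm$z_map$data)))
  ## target blob carries clearly higher z than background
  targ_z <- mean(cm$z_map$data[lay$target_region])
  bg <- setdiff(seq_len(prod(dim(cm$z_map$data))),
                c(lay$target_region, lay$seed_region))
  expect_gt(targ_z, mean(cm$z_map$data[bg]) + 0.2)
})
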