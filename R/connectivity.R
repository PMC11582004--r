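#' Resting-state BOLD run container
#'
#' @param data 4D numeric array (x, y, z, frame).
#' @param affine 4x4 voxel-to-MNI affine.
#' @param tr repetition time in seconds (0.72 for the normative data).
#' @param motion per-frame 6-column matrix: 3 translations (mm) then 3
#'   rotations (rad).
#' @param frame_keep logical per frame; frames flagged FALSE are censored
#'   before any regression or filtering.
#' @return object of class `bold_run`.
#' @export
new_bold_run <- function(data, affine, tr = 0.72, motion = NULL,
                         frame_keep = NULL) {
  if (length(dim(data)) != 4L) stop("BOLD data must be a 4D array")
  nt <- dim(data)[4L]
  if (nt < 2L) stop("a run needs at least 2 frames")
  if (is.null(motion)) motion <- matrix(0, nt, 6L)
  motion <- as.matrix(motion)
  if (nrow(motion) != nt || ncol(motion) != 6L) {
    stop("motion must be a ", nt, " x 6 matrix (3 translations mm, 3 rotations rad)")
  }
  if (is.null(frame_keep)) frame_keep <- rep(TRUE, nt)
  stopifnot(length(frame_keep) == nt)
  structure(list(data = data, affine = as.matrix(affine), tr = tr,
                 motion = motion, frame_keep = frame_keep),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("<bold_run> %s grid, %d frames (TR %.3g s), %d kept\n",
              paste(dim(x$data)[1:3], collapse = "x"), dim(x$data)[4L],
              x$tr, sum(x$frame_keep)))
  invisible(x)
}

run_geometry <- function(run) new_volume(array(0, dim(run$data)[1:3]), run$affine)

run_matrix <- function(run) {
  d <- dim(run$data)
  t(matrix(run$data, prod(d[1:3]), d[4L]))
}

matrix_to_run <- function(M, run) {
  d <- dim(run$data)
  out <- run
  out$data <- array(t(M), dim = c(d[1:3], nrow(M)))
  out$motion <- run$motion[seq_len(nrow(M)), , drop = FALSE]
  out$frame_keep <- rep(TRUE, nrow(M))
  out
}

#' Framewise displacement from motion parameters
#'
#' Power-style scalar head-motion summary: the sum of absolute backward
#' differences of the six motion parameters, with rotations converted to mm
#' as arc length on a 50 mm sphere. The first frame has FD = 0.
#'
#' @param motion frames x 6 matrix (3 translations mm, 3 rotations rad).
#' @param rotation_radius_mm sphere radius for the rotation-to-mm
#'   conversion.
#' @return numeric FD per frame, in mm.
#' @export
framewise_displacement <- function(motion, rotation_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop("motion must have 6 columns, got ", ncol(motion))
  if (nrow(motion) < 2L) stop("need at least 2 frames")
  d <- abs(diff(motion))
  c(0, rowSums(d[, 1:3, drop = FALSE]) +
      rotation_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
}

#' Flag high-motion frames for exclusion
#'
#' @param run a `bold_run`.
#' @param fd_threshold frames with FD above this (mm) are censored.
#' @return the run with `frame_keep` updated (and `fd` attached).
#' @export
scrub_run <- function(run, fd_threshold = 0.5) {
  fd <- framewise_displacement(run$motion)
  run$frame_keep <- run$frame_keep & fd <= fd_threshold
  run$fd <- fd
  run
}

drop_censored <- function(run) {
  keep <- which(run$frame_keep)
  out <- run
  out$data <- run$data[, , , keep, drop = FALSE]
  out$motion <- run$motion[keep, , drop = FALSE]
  out$frame_keep <- rep(TRUE, length(keep))
  out
}

#' Nuisance regression of confound signals
#'
#' Removes, per voxel, the least-squares fit on an intercept, the six motion
#' parameters, mean white-matter signal, mean CSF signal and (optionally)
#' the global mean signal. Censored frames are dropped before the fit, so
#' residuals are computed on kept frames only and are orthogonal to every
#' regressor.
#'
#' @param run a `bold_run` (typically after [scrub_run()]).
#' @param wm_mask,csf_mask `dat_mask`s of white matter / CSF on the run grid.
#' @param use_gsr include the global mean signal regressor.
#' @return a `bold_run` of residuals over the kept frames.
#' @export
nuisance_regress <- function(run, wm_mask, csf_mask, use_gsr = TRUE) {
  geom <- run_geometry(run)
  stopifnot_same_geometry(geom, wm_mask, "run and WM mask")
  stopifnot_same_geometry(geom, csf_mask, "run and CSF mask")
  run <- drop_censored(run)
  Y <- run_matrix(run)
  nt <- nrow(Y)
  wm <- rowMeans(Y[, which(wm_mask$data), drop = FALSE])
  csf <- rowMeans(Y[, which(csf_mask$data), drop = FALSE])
  X <- cbind(intercept = 1, run$motion, wm = wm, csf = csf)
  colnames(X)[2:7] <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")
  if (use_gsr) X <- cbind(X, global = rowMeans(Y))
  if (nt < ncol(X) + 2L) {
    stop("only ", nt, " kept frames for ", ncol(X), " regressors")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("confound matrix is rank-deficient; offending column(s): ",
         paste(dropped, collapse = ", "))
  }
  resid <- Y - qr.fitted(qrX, Y)
  matrix_to_run(resid, run)
}

#' Temporal band-pass filter
#'
#' Zero-phase 4th-order Butterworth band-pass (applied forward and backward
#' via `signal::filtfilt`) retaining the canonical resting-state band. The
#' series is treated as contiguous: censored frames must have been dropped
#' beforehand.
#'
#' @param run a `bold_run` (all frames kept).
#' @param low,high band edges in Hz (defaults 0.01 and 0.08).
#' @return the filtered `bold_run`.
#' @export
bandpass_run <- function(run, low = 0.01, high = 0.08) {
  if (high <= low) stop("high cutoff must exceed low cutoff")
  run <- drop_censored(run)
  fs <- 1 / run$tr
  if (high >= fs / 2) stop("high cutoff at/above Nyquist frequency")
  bf <- signal::butter(2, c(low, high) / (fs / 2), type = "pass")
  Y <- run_matrix(run)
  mu <- colMeans(Y)
  Yc <- sweep(Y, 2L, mu, `-`)                  # demean: avoids step transients
  Yf <- apply(Yc, 2L, function(y) signal::filtfilt(bf, y))
  matrix_to_run(Yf, run)
}

gaussian_kernel_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  half <- ceiling(3 * sigma_vox)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- max(1L, i - half):min(n, i + half)
    w <- exp(-((j - i)^2) / (2 * sigma_vox^2))
    K[i, j] <- w / sum(w)
  }
  K
}

apply_axis <- function(arr, ax, K) {
  d <- dim(arr)
  perm <- c(ax, setdiff(1:3, ax))
  a <- aperm(arr, perm)
  a <- array(K %*% matrix(a, d[ax]), dim = d[perm])
  aperm(a, order(perm))
}

#' Separable Gaussian smoothing of a 3D array or volume
#'
#' FWHM is converted per axis to a voxel-space sigma via
#' `sigma = FWHM / (2 sqrt(2 ln 2)) / voxel_size`; boundary kernels are
#' truncated and renormalised.
#'
#' @param x a 3D array or `dat_volume`.
#' @param fwhm full width at half maximum, mm.
#' @param voxel_mm voxel sizes (length 3); taken from the volume if omitted.
#' @return smoothed object of the same type.
#' @export
smooth_gaussian <- function(x, fwhm = 5, voxel_mm = NULL) {
  is_vol <- inherits(x, "dat_volume")
  arr <- if (is_vol) x$data else x
  if (is_vol && is.null(voxel_mm)) voxel_mm <- voxel_size(x)
  if (is.null(voxel_mm)) stop("voxel_mm required for bare arrays")
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / voxel_mm
  d <- dim(arr)
  for (ax in 1:3) arr <- apply_axis(arr, ax, gaussian_kernel_matrix(d[ax], sigma[ax]))
  if (is_vol) {
    x$data <- arr
    x
  } else {
    arr
  }
}

#' Seed-to-voxel connectivity map
#'
#' The seed time series is the mean over the seed voxels of the *unsmoothed*
#' residual data; target voxel series are smoothed with a Gaussian kernel
#' before correlation. The map holds Fisher-transformed Pearson
#' correlations; |r| is clamped at 1 - 1e-12 before atanh so z stays finite.
#'
#' @param run a preprocessed `bold_run` (censored, regressed, filtered).
#' @param seed a `seed_spec`.
#' @param fwhm smoothing FWHM in mm for target series (5 mm default).
#' @param subject_id label carried into the result.
#' @return object of class `connectivity_map` with a `z_map` `dat_volume`.
#' @export
seed_map <- function(run, seed, fwhm = 5, subject_id = NA_character_) {
  run <- drop_censored(run)
  nt <- dim(run$data)[4L]
  if (nt < 10L) stop("need at least 10 kept frames, got ", nt)
  geom <- run_geometry(run)
  sv <- seed_voxels(geom, seed)
  if (length(sv) == 0L) stop("seed sphere contains no voxels on this grid")
  Y <- run_matrix(run)
  s <- rowMeans(Y[, sv, drop = FALSE])
  if (stats::sd(s) == 0) stop("seed time series has zero variance")
  sm <- run
  vm <- voxel_size(geom)
  for (f in seq_len(nt)) {
    sm$data[, , , f] <- smooth_gaussian(run$data[, , , f], fwhm, vm)
  }
  Ys <- run_matrix(sm)
  r <- drop(stats::cor(s, Ys))
  r[is.na(r)] <- 0   # zero-variance targets carry no connectivity
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  z <- atanh(r)
  arr <- array(z, dim(run$data)[1:3])
  structure(list(z_map = new_volume(arr, run$affine), subject_id = subject_id,
                 seed = seed),
            class = "connectivity_map")
}

#' Average connectivity maps at the Fisher-z level
#'
#' Two runs per subject (opposite phase encodings) are combined by averaging
#' their z maps; the operation is commutative and idempotent for identical
#' runs.
#'
#' @param maps list of `connectivity_map`s on one grid.
#' @return a single `connectivity_map`.
#' @export
average_z_maps <- function(maps) {
  stopifnot(length(maps) >= 1L)
  ref <- maps[[1L]]
  for (m in maps[-1L]) stopifnot_same_geometry(ref$z_map, m$z_map, "z maps")
  avg <- Reduce(`+`, lapply(maps, function(m) m$z_map$data)) / length(maps)
  out <- ref
  out$z_map$data <- avg
  out
}

#' Group-level seed connectivity by one-sample t and sign-flipping
#'
#' Per voxel, a one-sample t-test of the subjects' Fisher-z values against
#' zero; cluster-extent inference exactly as in [permutation_fwe()], with
#' the null obtained by randomly flipping the sign of each subject's map
#' (valid under a symmetric null).
#'
#' @param maps list of `connectivity_map`s, one per subject (>= 3).
#' @param mask optional analysis `dat_mask`; default whole grid.
#' @param direction one-sided direction of interest ("positive" =
#'   connectivity with the seed).
#' @param cdt_p cluster-defining one-sided p threshold.
#' @param alpha family-wise level.
#' @param n_perm number of sign-flip permutations.
#' @param seed RNG seed (mandatory).
#' @param connectivity component-labelling neighbourhood.
#' @return a `cluster_set` with `p_fwe` per cluster.
#' @export
group_connectivity <- function(maps, mask = NULL,
                               direction = c("positive", "negative"),
                               cdt_p = 0.001, alpha = 0.05, n_perm = 2000L,
                               seed, connectivity = 18L) {
  direction <- match.arg(direction)
  if (missing(seed) || is.null(seed)) stop("seed is required for sign-flip inference")
  n <- length(maps)
  if (n < 3L) stop("need at least 3 subjects, got ", n)
  geom <- maps[[1L]]$z_map
  if (is.null(mask)) mask <- new_mask(array(TRUE, dim(geom$data)), geom$affine,
                                      provenance = "whole grid")
  for (m in maps) stopifnot_same_geometry(mask, m$z_map, "mask and z map")
  lin <- which(mask$data)
  Z <- t(vapply(maps, function(m) m$z_map$data[lin], numeric(length(lin))))
  df <- n - 1L
  mu <- colMeans(Z)
  sdv <- sqrt(colSums(sweep(Z, 2L, mu, `-`)^2) / df)
  tt <- ifelse(sdv > 0, mu / (sdv / sqrt(n)), sign(mu) * T_SENTINEL)
  tt[mu == 0 & sdv == 0] <- 0
  thr <- stats::qt(1 - cdt_p, df)
  dims <- dim(mask$data)
  t_dir <- if (direction == "negative") -tt else tt
  obs <- clusters_from_t(t_dir, tt, lin, dims, mask$affine, thr, connectivity)

  ss <- colSums(Z^2)
  S <- withr::with_seed(seed,
                        matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n, n_perm))
  M <- crossprod(S, Z) / n                      # n_perm x V flipped means
  Vfl <- sweep(-(n) * M^2, 2L, ss, `+`) / df     # flipped variances
  Tperm <- M / sqrt(pmax(Vfl, .Machine$double.eps) / n)
  Tperm[Tperm > T_SENTINEL] <- T_SENTINEL
  Tperm[Tperm < -T_SENTINEL] <- -T_SENTINEL
  if (direction == "negative") Tperm <- -Tperm
  null_max <- max_extent_null(Tperm, thr, lin, dims, connectivity)

  tab <- obs$clusters
  if (nrow(tab)) {
    tab$p_fwe <- vapply(tab$extent, function(k) {
      (1 + sum(null_max >= k)) / (n_perm + 1)
    }, numeric(1))
    tab$significant <- tab$p_fwe < alpha
  } else {
    tab$p_fwe <- numeric(0)
    tab$significant <- logical(0)
  }
  cs <- new_cluster_set(tab, obs$voxels, dims, mask$affine, cdt_p, alpha, df,
                        direction, as.integer(n_perm))
  cs$null_max_extent <- null_max
  cs
}

#' Binary overlap of two thresholded connectivity networks
#'
#' @param a,b `cluster_set`s (with `p_fwe`) on one grid.
#' @param alpha significance level applied to both.
#' @return a `dat_mask`: voxelwise intersection of the two significance
#'   masks.
#' @export
overlap_map <- function(a, b, alpha = 0.05) {
  ma <- significance_mask(a, alpha)
  mb <- significance_mask(b, alpha)
  stopifnot_same_geometry(ma, mb, "the two significance masks")
  new_mask(ma$data & mb$data, ma$affine,
           provenance = sprintf("intersection of two cluster sets at alpha %g",
                                alpha))
}

#' Read a whitespace-delimited 6-column motion parameter file
#' @param path text file, one row per frame: 3 translations (mm), 3
#'   rotations (rad).
#' @return frames x 6 numeric matrix.
#' @export
read_motion <- function(path) {
  m <- as.matrix(utils::read.table(path))
  if (ncol(m) != 6L) stop("motion file must have 6 columns, got ", ncol(m))
  dimnames(m) <- NULL
  m
}

#' Write motion parameters
#' @param motion frames x 6 matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_motion <- function(motion, path) {
  utils::write.table(motion, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
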