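## Sentinel magnitude reported for t statistics at noise-free voxels
## (zero residual variance), and for Fisher z at |r| ~ 1.
T_SENTINEL <- 1e6

neighbor_deltas <- function(connectivity = 18L) {
  d <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  s <- rowSums(abs(d))
  keep <- switch(as.character(connectivity),
                 "6" = s == 1, "18" = s >= 1 & s <= 2, "26" = s >= 1,
                 stop("connectivity must be 6, 18 or 26"))
  d[keep, , drop = FALSE]
}

#' Label connected components of a voxel set
#'
#' Flood-fill component labelling of a set of voxels on a 3D grid. The
#' default 18-neighbourhood (faces + edges) matches common neuroimaging
#' practice for cluster-forming.
#'
#' @param lin 1-based linear (column-major) voxel indices of the set.
#' @param dims grid dimensions, length 3.
#' @param connectivity 6, 18 or 26.
#' @return integer component label per element of `lin` (labels start at 1).
#' @export
label_components <- function(lin, dims, connectivity = 18L) {
  nl <- length(lin)
  if (nl == 0L) return(integer(0))
  member <- integer(prod(dims))
  member[lin] <- seq_len(nl)
  labels <- integer(nl)
  coords <- arrayInd(lin, dims)
  deltas <- neighbor_deltas(connectivity)
  nd <- nrow(deltas)
  doff <- as.integer(deltas %*% c(1L, dims[1L], dims[1L] * dims[2L]))
  stack <- integer(nl)
  cur <- 0L
  for (s in seq_len(nl)) {
    if (labels[s] > 0L) next
    cur <- cur + 1L
    labels[s] <- cur
    stack[1L] <- s
    top <- 1L
    while (top > 0L) {
      v <- stack[top]
      top <- top - 1L
      cv <- coords[v, ]
      lv <- lin[v]
      for (t in seq_len(nd)) {
        ci <- cv[1L] + deltas[t, 1L]
        cj <- cv[2L] + deltas[t, 2L]
        ck <- cv[3L] + deltas[t, 3L]
        if (ci < 1L || ci > dims[1L] || cj < 1L || cj > dims[2L] ||
            ck < 1L || ck > dims[3L]) next
        m <- member[lv + doff[t]]
        if (m > 0L && labels[m] == 0L) {
          labels[m] <- cur
          top <- top + 1L
          stack[top] <- m
        }
      }
    }
  }
  labels
}

## Per-voxel OLS of Y (n x V) on [intercept, x]: slope and t statistic.
## Zero-variance voxels get beta = t = 0; zero residual variance gives the
## signed T_SENTINEL.
ols_fit_matrix <- function(Y, x) {
  n <- nrow(Y)
  if (n < 3L) stop("need at least 3 subjects (n = ", n, ")")
  if (stats::sd(x) == 0) stop("covariate is constant: design is rank-deficient")
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  Yc <- sweep(Y, 2L, colMeans(Y), `-`)
  beta <- drop(crossprod(xc, Yc)) / sxx
  rss <- colSums(Yc^2) - beta^2 * sxx
  rss[rss < 0] <- 0
  df <- n - 2L
  se <- sqrt(rss / df / sxx)
  tval <- beta / se
  novar <- colSums(Yc^2) == 0
  tval[novar] <- 0
  beta[novar] <- 0
  exact <- !novar & se == 0
  tval[exact] <- sign(beta[exact]) * T_SENTINEL
  list(beta = beta, t = tval, df = df)
}

## t statistics for many permuted covariates at once: X (n x B) permuted
## covariate columns, Y (n x V). Returns B x V matrix.
perm_t_matrix <- function(Y, X) {
  n <- nrow(Y)
  df <- n - 2L
  Zy <- scale(Y)
  Zy[, attr(Zy, "scaled:scale") == 0] <- 0
  Zx <- scale(X)
  r <- crossprod(Zx, Zy) / (n - 1)
  r[r > 1] <- 1
  r[r < -1] <- -1
  tt <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  tt[tt > T_SENTINEL] <- T_SENTINEL
  tt[tt < -T_SENTINEL] <- -T_SENTINEL
  tt
}

volumes_to_matrix <- function(volumes, mask) {
  for (v in volumes) stopifnot_same_geometry(mask, v, "volume and mask")
  lin <- which(mask$data)
  t(vapply(volumes, function(v) v$data[lin], numeric(length(lin))))
}

#' Voxelwise regression of local SBR on a behavioural covariate
#'
#' Mass-univariate ordinary least squares per masked voxel on the design
#' `[intercept, covariate]`, giving a slope (beta) map and a t map with
#' `n - 2` degrees of freedom. Voxels outside the mask carry NA. Noise-free
#' voxels (zero residual variance) receive a clamped sentinel t of signed
#' 1e6.
#'
#' @param volumes list of `dat_volume`s, one per subject, shared geometry.
#' @param covariate numeric vector, one value per subject (e.g. UES or the
#'   online-learning measure).
#' @param mask analysis `dat_mask` (the DaTStriatum volume).
#' @param direction "positive" or "negative": the one-sided association of
#'   interest.
#' @param covariate_name label carried into outputs.
#' @return object of class `glm_result`: `beta_map`, `t_map` (both
#'   `dat_volume`), `df`, `direction`, `covariate_name`, `mask`.
#' @export
voxelwise_regression <- function(volumes, covariate, mask,
                                 direction = c("positive", "negative"),
                                 covariate_name = deparse(substitute(covariate))) {
  direction <- match.arg(direction)
  if (length(volumes) != length(covariate)) {
    stop("one covariate value per volume required")
  }
  Y <- volumes_to_matrix(volumes, mask)
  fit <- ols_fit_matrix(Y, covariate)
  lin <- which(mask$data)
  shape <- function(vals) {
    arr <- array(NA_real_, dim(mask$data))
    arr[lin] <- vals
    new_volume(arr, mask$affine)
  }
  structure(list(beta_map = shape(fit$beta), t_map = shape(fit$t),
                 df = fit$df, direction = direction,
                 covariate_name = covariate_name, mask = mask),
            class = "glm_result")
}

new_cluster_set <- function(clusters, voxels, dims, affine, cdt_p, alpha, df,
                            direction, n_perm = NA_integer_) {
  structure(list(clusters = clusters, voxels = voxels, dims = dims,
                 affine = affine, cdt_p = cdt_p, alpha = alpha, df = df,
                 direction = direction, n_perm = n_perm),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d cluster(s), CDT p < %g (%s direction)\n",
              nrow(x$clusters), x$cdt_p, x$direction))
  if (nrow(x$clusters)) print(x$clusters, ...)
  invisible(x)
}

## Build a cluster table from directional t values over mask voxels.
## t_dir is the t statistic oriented so that large positive = effect.
clusters_from_t <- function(t_dir, t_raw, mask_lin, dims, affine, thr,
                            connectivity = 18L) {
  supra <- t_dir > thr
  supra_lin <- mask_lin[supra]
  if (length(supra_lin) == 0L) {
    return(list(clusters = data.frame(cluster_id = integer(),
                                      extent = integer(),
                                      peak_t = numeric(), peak_x = numeric(),
                                      peak_y = numeric(), peak_z = numeric()),
                voxels = list()))
  }
  lab <- label_components(supra_lin, dims, connectivity)
  td <- t_dir[supra]
  tr <- t_raw[supra]
  ids <- sort(unique(lab))
  rows <- lapply(ids, function(k) {
    sel <- lab == k
    pk <- which(sel)[which.max(td[sel])]
    ijk <- arrayInd(supra_lin[pk], dims) - 1L
    xyz <- drop(cbind(ijk, 1) %*% t(affine))[1:3]
    data.frame(extent = sum(sel), peak_t = tr[pk],
               peak_x = xyz[1], peak_y = xyz[2], peak_z = xyz[3])
  })
  tab <- do.call(rbind, rows)
  ord <- order(-tab$extent, -abs(tab$peak_t))
  tab <- tab[ord, ]
  tab <- cbind(cluster_id = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  voxels <- lapply(ids[ord], function(k) supra_lin[lab == k])
  list(clusters = tab, voxels = voxels)
}

#' Cluster-forming threshold on a voxelwise regression result
#'
#' Marks voxels whose one-sided uncorrected p is below the cluster-defining
#' threshold in the requested direction and groups them into connected
#' components (18-connectivity by default). No family-wise correction is
#' attached; see [permutation_fwe()].
#'
#' @param glm a `glm_result` from [voxelwise_regression()].
#' @param cdt_p cluster-defining (uncorrected, one-sided) p threshold.
#' @param connectivity neighbourhood for component labelling.
#' @return a `cluster_set` (without `p_fwe`); empty when nothing survives.
#' @export
cluster_threshold <- function(glm, cdt_p = 0.001, connectivity = 18L) {
  if (glm$df < 1L) stop("degrees of freedom must be >= 1")
  thr <- stats::qt(1 - cdt_p, glm$df)
  mask_lin <- which(glm$mask$data)
  t_raw <- glm$t_map$data[mask_lin]
  t_dir <- if (glm$direction == "negative") -t_raw else t_raw
  cl <- clusters_from_t(t_dir, t_raw, mask_lin, dim(glm$mask$data),
                        glm$mask$affine, thr, connectivity)
  new_cluster_set(cl$clusters, cl$voxels, dim(glm$mask$data),
                  glm$mask$affine, cdt_p, NA_real_, glm$df, glm$direction)
}

## Null distribution of the maximum cluster extent under permutation of the
## covariate (or sign flipping, when X is generated that way upstream).
max_extent_null <- function(Tmat, thr, mask_lin, dims, connectivity = 18L) {
  apply(Tmat, 1L, function(tr) {
    supra_lin <- mask_lin[tr > thr]
    if (length(supra_lin) == 0L) return(0L)
    max(tabulate(label_components(supra_lin, dims, connectivity)))
  })
}

#' Cluster-level family-wise inference by covariate permutation
#'
#' Runs the voxelwise regression, forms clusters at the cluster-defining
#' threshold, and assesses cluster extents against the permutation null of
#' the maximum cluster extent obtained by shuffling the covariate across
#' subjects. The family-wise p of a cluster of extent k is
#' `(1 + #\{permutation max extent >= k\}) / (n_perm + 1)`; clusters with
#' `p_fwe < alpha` are flagged significant.
#'
#' @inheritParams voxelwise_regression
#' @param cdt_p cluster-defining one-sided p threshold.
#' @param alpha family-wise significance level.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed (mandatory: permutation inference must be
#'   reproducible).
#' @param connectivity neighbourhood for component labelling.
#' @return a `cluster_set` whose table carries `p_fwe` and `significant`.
#' @export
permutation_fwe <- function(volumes, covariate, mask,
                            direction = c("positive", "negative"),
                            cdt_p = 0.001, alpha = 0.05, n_perm = 5000L,
                            seed, connectivity = 18L,
                            covariate_name = "covariate") {
  direction <- match.arg(direction)
  if (missing(seed) || is.null(seed)) stop("seed is required for permutation inference")
  if (n_perm < 100L) stop("n_perm must be >= 100")
  Y <- volumes_to_matrix(volumes, mask)
  n <- nrow(Y)
  fit <- ols_fit_matrix(Y, covariate)
  thr <- stats::qt(1 - cdt_p, fit$df)
  mask_lin <- which(mask$data)
  dims <- dim(mask$data)
  t_dir <- if (direction == "negative") -fit$t else fit$t
  obs <- clusters_from_t(t_dir, fit$t, mask_lin, dims, mask$affine, thr,
                         connectivity)

  X <- withr::with_seed(seed, vapply(seq_len(n_perm),
                                     function(b) covariate[sample.int(n)],
                                     numeric(n)))
  Tperm <- perm_t_matrix(Y, X)
  if (direction == "negative") Tperm <- -Tperm
  null_max <- max_extent_null(Tperm, thr, mask_lin, dims, connectivity)

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
  cs <- new_cluster_set(tab, obs$voxels, dims, mask$affine, cdt_p, alpha,
                        fit$df, direction, as.integer(n_perm))
  cs$null_max_extent <- null_max
  cs$covariate_name <- covariate_name
  cs
}

#' Monte-Carlo calibration of the cluster-level family-wise error rate
#'
#' Simulates null cohorts (smooth Gaussian random-field volumes - matching
#' the spatial autocorrelation of reconstructed SPECT data, which is what
#' cluster-extent inference is built for - with a covariate independent of
#' the data), runs the full permutation cluster inference on each, and
#' reports the proportion of datasets with at least one significant
#' cluster. For a valid procedure this family-wise rejection rate is at
#' most (and, up to permutation discreteness, close to) `alpha`.
#'
#' @param n_datasets number of simulated null cohorts.
#' @param n_subjects subjects per cohort.
#' @param dims phantom grid dimensions (whole grid is the analysis mask).
#' @param fwhm_mm smoothness of the null field (Gaussian FWHM, mm; voxels
#'   are 4 mm).
#' @param cdt_p,alpha,n_perm,connectivity passed to [permutation_fwe()].
#' @param seed root RNG seed.
#' @return list with `fwer` (observed rate), `n_datasets`, `mc_se`
#'   (binomial Monte-Carlo standard error at `alpha`), and `rejections`.
#' @export
simulate_cluster_fwer <- function(n_datasets = 500L, n_subjects = 12L,
                                  dims = c(12L, 12L, 12L), cdt_p = 0.001,
                                  alpha = 0.05, n_perm = 399L, seed,
                                  connectivity = 18L, fwhm_mm = 12) {
  if (missing(seed)) stop("seed is required")
  affine <- diag(c(4, 4, 4, 1))
  mask <- new_mask(array(TRUE, dims), affine, provenance = "null phantom")
  sub_seeds <- withr::with_seed(seed, sample.int(2^30, n_datasets))
  rejections <- vapply(seq_len(n_datasets), function(i) {
    dat <- withr::with_seed(sub_seeds[i], list(
      vols = lapply(seq_len(n_subjects), function(j) {
        noise <- array(stats::rnorm(prod(dims)), dims)
        new_volume(smooth_gaussian(noise, fwhm_mm, rep(4, 3)), affine)
      }),
      x = stats::rnorm(n_subjects)))
    cs <- permutation_fwe(dat$vols, dat$x, mask, direction = "positive",
                          cdt_p = cdt_p, alpha = alpha, n_perm = n_perm,
                          seed = sub_seeds[i], connectivity = connectivity)
    any(cs$clusters$significant)
  }, logical(1))
  list(fwer = mean(rejections), n_datasets = n_datasets,
       mc_se = sqrt(alpha * (1 - alpha) / n_datasets),
       rejections = rejections)
}

#' Binary significance mask of a cluster set
#'
#' @param cs a `cluster_set` with family-wise p-values.
#' @param alpha significance level; defaults to the set's own alpha.
#' @return a `dat_mask` marking all voxels of significant clusters.
#' @export
significance_mask <- function(cs, alpha = cs$alpha) {
  arr <- array(FALSE, cs$dims)
  if (nrow(cs$clusters) && !is.null(cs$clusters$p_fwe)) {
    keep <- which(cs$clusters$p_fwe < alpha)
    for (k in keep) arr[cs$voxels[[k]]] <- TRUE
  }
  new_mask(arr, cs$affine,
           provenance = sprintf("clusters with p_fwe < %g (CDT p < %g)",
                                alpha, cs$cdt_p))
}

#' Spherical seed at the peak of the most significant cluster
#'
#' @param clusters a `cluster_set` with `p_fwe` and at least one significant
#'   cluster.
#' @param radius sphere radius in mm (default 5).
#' @return a `seed_spec`: list with `center_mni` (mm) and `radius`.
#' @export
peak_seed <- function(clusters, radius = 5) {
  tab <- clusters$clusters
  if (is.null(tab$p_fwe) || !any(tab$significant)) {
    stop("no significant cluster to seed from")
  }
  tab <- tab[tab$significant, ]
  best <- tab[order(tab$p_fwe, -tab$extent), ][1L, ]
  seed_spec(c(best$peak_x, best$peak_y, best$peak_z), radius)
}

#' Construct a spherical seed specification
#' @param center_mni length-3 MNI coordinate in mm.
#' @param radius sphere radius in mm (> 0).
#' @return a `seed_spec` object.
#' @export
seed_spec <- function(center_mni, radius = 5) {
  stopifnot(length(center_mni) == 3L)
  if (radius <= 0) stop("seed radius must be > 0")
  structure(list(center_mni = as.numeric(center_mni), radius = radius),
            class = "seed_spec")
}

#' Voxels belonging to a spherical seed
#'
#' @param vol a `dat_volume` (or mask) fixing the grid geometry.
#' @param seed a `seed_spec`.
#' @return 1-based linear indices of voxels whose MNI centre lies within
#'   Euclidean distance `radius` of the seed centre.
#' @export
seed_voxels <- function(vol, seed) {
  xyz <- voxel_grid_mni(vol)
  d2 <- (xyz[, 1] - seed$center_mni[1])^2 +
    (xyz[, 2] - seed$center_mni[2])^2 +
    (xyz[, 3] - seed$center_mni[3])^2
  which(d2 <= seed$radius^2)
}

#' Write a cluster table as CSV
#' @param cs a `cluster_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(cs, path) {
  utils::write.csv(cs$clusters, path, row.names = FALSE)
  invisible(path)
}
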