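## Independent brute-force oracles used to validate the package's
## implementations. These deliberately use different algorithms from the
## production code paths.

## Maximum number of non-overlapping exact template occurrences, by dynamic
## programming over all occurrence positions (independent of the greedy
## scanner in match_sequences).
oracle_match_count <- function(keys, template) {
  m <- length(template)
  n <- length(keys)
  if (n < m) return(0L)
  is_occ <- vapply(seq_len(n - m + 1L), function(i) {
    all(keys[i:(i + m - 1L)] == template)
  }, logical(1))
  best <- integer(n + 2L)
  for (i in n:1) {
    best[i] <- best[i + 1L]
    if (i <= n - m + 1L && is_occ[i]) {
      best[i] <- max(best[i], 1L + best[min(i + m, n + 1L)])
    }
  }
  best[1L]
}

## Per-voxel OLS via stats::lm, voxel by voxel.
oracle_ols <- function(Y, x) {
  out <- t(vapply(seq_len(ncol(Y)), function(v) {
    f <- stats::lm(Y[, v] ~ x)
    s <- summary(f)$coefficients
    c(beta = unname(coef(f)[2L]), t = unname(s[2L, 3L]))
  }, c(beta = 0, t = 0)))
  list(beta = out[, 1L], t = out[, 2L])
}

## Connected components by boolean transitive closure of the adjacency
## matrix (independent of the flood-fill in label_components).
oracle_components <- function(lin, dims, connectivity = 18L) {
  n <- length(lin)
  if (n == 0L) return(integer(0))
  co <- arrayInd(lin, dims)
  R <- diag(n) > 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d <- abs(co[i, ] - co[j, ])
      s <- sum(d)
      lim <- switch(as.character(connectivity), "6" = 1L, "18" = 2L, "26" = 3L)
      if (all(d <= 1L) && s >= 1L && s <= lim) R[i, j] <- TRUE
    }
  }
  repeat {
    R2 <- (R %*% R) > 0
    if (identical(R2, R)) break
    R <- R2
  }
  match(apply(R, 1L, paste, collapse = ""),
        unique(apply(R, 1L, paste, collapse = "")))
}

## Textbook balanced mixed-design SS decomposition from cell means (equal
## group sizes only).
oracle_mixed_ss <- function(Y, group) {
  group <- factor(group)
  N <- nrow(Y); J <- ncol(Y); g <- nlevels(group)
  stopifnot(length(unique(table(group))) == 1L)
  gm <- mean(Y)
  subj_m <- rowMeans(Y)
  grp_m <- as.numeric(tapply(subj_m, group, mean))
  lvl_m <- colMeans(Y)
  cell_m <- apply(Y, 2L, function(col) as.numeric(tapply(col, group, mean)))
  list(
    ss_total = sum((Y - gm)^2),
    ss_group = J * sum(table(group) * (grp_m - gm)^2),
    ss_subj = J * sum((subj_m - grp_m[group])^2),
    ss_within = N * sum((lvl_m - gm)^2),
    ss_inter = (N / g) * sum((cell_m - outer(grp_m, lvl_m, `+`) + gm)^2),
    ss_werr = sum((Y - cell_m[cbind(as.integer(group), rep(seq_len(J), each = N))] -
                     subj_m + grp_m[group])^2))
}

## Small keystroke block builder: given keys and uniform gap, a timed block.
timed_block <- function(keys, gap = 0.25) {
  list(t = cumsum(rep(gap, length(keys))), keys = as.integer(keys))
}
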