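#' Pearson correlation with two-sided p-value
#'
#' @param x,y numeric vectors, length >= 3, both non-constant.
#' @return list with `r`, `p` (two-sided, t distribution with n - 2 df),
#'   `n`, `df`.
#' @export
pearson_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n, df = n - 2L)
}

## Greenhouse-Geisser epsilon from a J x J within-level covariance matrix.
epsilon_gg <- function(S) {
  J <- nrow(S)
  C <- diag(J) - matrix(1 / J, J, J)
  E <- C %*% S %*% C
  tr <- sum(diag(E))
  tr2 <- sum(E * E)
  if (tr2 <= .Machine$double.eps) return(NA_real_)
  (tr^2) / ((J - 1) * tr2)
}

## Huynh-Feldt correction of the GG estimate for a mixed design with g
## groups and N subjects; capped at 1 and floored at the lower bound.
epsilon_hf <- function(eps_gg, N, J, g) {
  num <- N * (J - 1) * eps_gg - 2
  den <- (J - 1) * (N - g - (J - 1) * eps_gg)
  hf <- num / den
  min(max(hf, 1 / (J - 1)), 1)
}

#' Mixed repeated-measures ANOVA with sphericity correction
#'
#' Two-factor mixed design: one between-subject factor (group) and one
#' within-subject factor with J levels (e.g. practice block), every subject
#' measured at every level. Sums of squares follow the classical univariate
#' decomposition (Type III; computed from orthonormal within-subject
#' contrasts with unweighted group means, matching standard statistical
#' packages under unequal group sizes). Sphericity of the within factor is
#' quantified by the Greenhouse-Geisser epsilon from the pooled
#' within-group covariance of the levels; the Huynh-Feldt correction of
#' that estimate (capped at 1) rescales the degrees of freedom of the
#' within-factor and interaction tests whenever `epsilon_gg < 1`. Two-level
#' within factors trivially satisfy sphericity (`epsilon_hf = 1`).
#'
#' @param data numeric matrix, subjects x within-levels.
#' @param group factor (or coercible) of per-subject group labels; >= 2
#'   subjects per group.
#' @return an `anova_table` data.frame with rows `group`,
#'   `subjects_within_group` (between error), `within`, `within:group` and
#'   `within_error`; columns `ss`, `df`, `ms`, `F`, `p_uncorrected`,
#'   `epsilon_gg`, `epsilon_hf`, `df1_corrected`, `df2_corrected`,
#'   `p_corrected`. The total sum of squares is attached as attribute
#'   `ss_total`.
#' @export
mixed_rmanova <- function(data, group) {
  data <- as.matrix(data)
  group <- factor(group)
  N <- nrow(data)
  J <- ncol(data)
  if (length(group) != N) stop("one group label per subject required")
  if (J < 2L) stop("within factor needs at least 2 levels")
  if (anyNA(data)) stop("unbalanced design: missing cells are not supported")
  n_i <- table(group)
  if (any(n_i < 2L)) stop("each group needs at least 2 subjects")
  g <- nlevels(group)

  ## between-subject part: one-way ANOVA on subject means, scaled by J
  m_s <- rowMeans(data)
  gm <- mean(data)
  m_i <- tapply(m_s, group, mean)
  ss_group <- J * sum(n_i * (m_i - gm)^2)
  ss_subj <- J * sum((m_s - m_i[group])^2)
  df_group <- g - 1L
  df_subj <- N - g

  ## within-subject part via orthonormal contrasts of the levels
  C <- contr_orthonormal(J)                    # J x (J-1)
  W <- data %*% C                              # N x (J-1)
  u_i <- apply(W, 2L, function(w) tapply(w, group, mean))  # g x (J-1)
  u_i <- matrix(u_i, nrow = g)
  n_h <- g / sum(1 / n_i)                      # harmonic mean group size
  b0 <- colMeans(u_i)                          # unweighted grand effects
  ss_within <- n_h * g * sum(b0^2)
  ss_inter <- sum(vapply(seq_len(J - 1L), function(k) {
    sum(n_i * (u_i[, k] - sum(n_i * u_i[, k]) / N)^2)
  }, numeric(1)))
  ss_werr <- sum(vapply(seq_len(J - 1L), function(k) {
    sum((W[, k] - u_i[group, k])^2)
  }, numeric(1)))
  df_within <- J - 1L
  df_inter <- (g - 1L) * (J - 1L)
  df_werr <- (N - g) * (J - 1L)

  ## sphericity: pooled within-group covariance of the raw levels
  grp_means <- t(vapply(levels(group), function(l) {
    colMeans(data[group == l, , drop = FALSE])
  }, numeric(J)))                              # g x J
  centred <- data - grp_means[as.integer(group), , drop = FALSE]
  S <- crossprod(centred) / (N - g)
  if (J == 2L) {
    e_gg <- 1
    e_hf <- 1
  } else {
    e_gg <- epsilon_gg(S)
    if (is.na(e_gg)) {
      warning("singular within-level covariance; using lower-bound epsilon")
      e_gg <- 1 / (J - 1)
      e_hf <- 1 / (J - 1)
    } else {
      e_hf <- epsilon_hf(e_gg, N, J, g)
    }
  }

  f_group <- (ss_group / df_group) / (ss_subj / df_subj)
  f_within <- (ss_within / df_within) / (ss_werr / df_werr)
  f_inter <- (ss_inter / df_inter) / (ss_werr / df_werr)
  eps_use <- if (e_gg < 1) e_hf else 1

  row <- function(effect, ss, df, F = NA, p = NA, egg = NA, ehf = NA,
                  eps = NA) {
    d1c <- if (!is.na(eps)) eps * df else NA_real_
    data.frame(effect = effect, ss = ss, df = df, ms = ss / df, F = F,
               p_uncorrected = p, epsilon_gg = egg, epsilon_hf = ehf,
               df1_corrected = d1c, df2_corrected = NA_real_,
               p_corrected = NA_real_)
  }
  tab <- rbind(
    row("group", ss_group, df_group, f_group,
        stats::pf(f_group, df_group, df_subj, lower.tail = FALSE)),
    row("subjects_within_group", ss_subj, df_subj),
    row("within", ss_within, df_within, f_within,
        stats::pf(f_within, df_within, df_werr, lower.tail = FALSE),
        e_gg, e_hf, eps_use),
    row("within:group", ss_inter, df_inter, f_inter,
        stats::pf(f_inter, df_inter, df_werr, lower.tail = FALSE),
        e_gg, e_hf, eps_use),
    row("within_error", ss_werr, df_werr)
  )
  tab$df2_corrected[3:4] <- eps_use * df_werr
  tab$p_corrected[3L] <- stats::pf(f_within, eps_use * df_within,
                                   eps_use * df_werr, lower.tail = FALSE)
  tab$p_corrected[4L] <- stats::pf(f_inter, eps_use * df_inter,
                                   eps_use * df_werr, lower.tail = FALSE)
  rownames(tab) <- NULL
  attr(tab, "ss_total") <- sum((data - gm)^2)
  class(tab) <- c("anova_table", "data.frame")
  tab
}

contr_orthonormal <- function(J) {
  H <- stats::contr.helmert(J)
  sweep(H, 2L, sqrt(colSums(H^2)), `/`)
}

#' Mann-Whitney U test (normal approximation, tie correction)
#'
#' U statistic from midranks; two-sided p from the tie-corrected normal
#' approximation (no continuity correction). `U + U' = n1 * n2` always.
#'
#' @param a,b numeric samples (both non-empty).
#' @return list with `U` (for sample `a`), `U_prime`, `z`, `p`.
#' @export
mann_whitney_u <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  n1 <- length(a)
  n2 <- length(b)
  if (n1 == 0L || n2 == 0L) stop("both samples must be non-empty")
  r <- rank(c(a, b))
  R1 <- sum(r[seq_len(n1)])
  U <- R1 - n1 * (n1 + 1) / 2
  n <- n1 + n2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  mu <- n1 * n2 / 2
  z <- if (sigma2 > 0) (U - mu) / sqrt(sigma2) else 0
  p <- 2 * stats::pnorm(-abs(z))
  list(U = U, U_prime = n1 * n2 - U, z = z, p = min(p, 1))
}

#' Dichotomize a clinical cohort on the putaminal z-score
#'
#' Participants with age-adjusted putaminal z below the cutoff (default
#' -2.5, the conventional threshold suggestive of a neurodegenerative
#' Parkinsonian syndrome) form the DaT- group; z >= cutoff is DaT+.
#'
#' @param records data.frame of clinical records with at least `z_putamen`;
#'   `sex`, `age`, `ues` are summarised when present.
#' @param cutoff z cutoff (strict `<` assigns DaT-).
#' @return list with `labels` (factor "DaT-"/"DaT+") and `summary` (per
#'   group: n, n female, mean/sd of age and UES).
#' @export
dichotomize_dat <- function(records, cutoff = -2.5) {
  if (!"z_putamen" %in% names(records)) stop("records need a z_putamen column")
  miss <- which(is.na(records$z_putamen))
  if (length(miss)) {
    stop("missing putaminal z for subject(s): ",
         paste(if (!is.null(records$subject_id)) records$subject_id[miss]
               else miss, collapse = ", "))
  }
  lab <- factor(ifelse(records$z_putamen < cutoff, "DaT-", "DaT+"),
                levels = c("DaT-", "DaT+"))
  summ <- do.call(rbind, lapply(levels(lab), function(l) {
    sub <- records[lab == l, , drop = FALSE]
    data.frame(
      group = l, n = nrow(sub),
      n_female = if ("sex" %in% names(sub)) sum(sub$sex %in% c("F", "female")) else NA_integer_,
      mean_age = if ("age" %in% names(sub)) mean(sub$age) else NA_real_,
      sd_age = if ("age" %in% names(sub)) stats::sd(sub$age) else NA_real_,
      mean_ues = if ("ues" %in% names(sub)) mean(sub$ues) else NA_real_,
      sd_ues = if ("ues" %in% names(sub)) stats::sd(sub$ues) else NA_real_)
  }))
  list(labels = lab, summary = summ)
}

#' Two-sample (or paired) t-test
#'
#' Pooled-variance independent t by default (Welch available), or a paired
#' t; one- or two-sided. Degenerate zero-variance comparisons with equal
#' means report t = 0, p = 1.
#'
#' @param a,b numeric samples (n >= 2 each; equal length when paired).
#' @param sides "two" or "one". One-sided tests the alternative mean(a) >
#'   mean(b).
#' @param paired paired test flag.
#' @param welch use Welch's unequal-variance t instead of pooled.
#' @return list with `t`, `df`, `p`.
#' @export
ttest2 <- function(a, b, sides = c("two", "one"), paired = FALSE,
                   welch = FALSE) {
  sides <- match.arg(sides)
  alt <- if (sides == "two") "two.sided" else "greater"
  if (length(a) < 2L || length(b) < 2L) stop("need at least 2 values per sample")
  degenerate <- if (paired) stats::sd(a - b) == 0 else
    stats::sd(a) == 0 && stats::sd(b) == 0
  if (degenerate && isTRUE(all.equal(mean(a), mean(b)))) {
    df <- if (paired) length(a) - 1L else length(a) + length(b) - 2L
    return(list(t = 0, df = df, p = 1))
  }
  tt <- stats::t.test(a, b, alternative = alt, paired = paired,
                      var.equal = !welch && !paired)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}
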