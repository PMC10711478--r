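#' Two-way mixed / repeated-measures ANOVA with Greenhouse-Geisser
#' correction
#'
#' Classical split-plot decomposition for a design with one
#' between-subject factor (`group`, optional) and one within-subject
#' factor (`day`): the between effect is tested against
#' subjects-within-groups, the within and interaction effects against
#' the subject-by-day residual.  Sphericity of the within factor is
#' handled by the Greenhouse-Geisser estimate \eqn{\hat\epsilon} from
#' the pooled within-group covariance of the subject-by-day score
#' matrix; within-effect degrees of freedom are multiplied by
#' \eqn{\hat\epsilon} for the corrected p-value.  With two within
#' levels sphericity holds trivially and \eqn{\hat\epsilon = 1}.  When
#' `between` is `NULL` (or one group) the model reduces to a one-way
#' repeated-measures ANOVA on the within factor.
#'
#' The design must be complete: every subject observed at every within
#' level exactly once (no imputation is attempted).
#'
#' @param data long-format data.frame.
#' @param value,subject,within,between column names; `between = NULL`
#'   for a pure repeated-measures design.
#' @return data.frame with one row per effect (`group`, `day`,
#'   `group:day` as applicable): `F`, `df1`, `df2`, `p_uncorrected`,
#'   `epsilon_GG`, `p_GG`.  For the between effect, which has no
#'   sphericity assumption, `epsilon_GG` is NA and `p_GG` equals
#'   `p_uncorrected`.
#' @examples
#' d <- expand.grid(subject = paste0("m", 1:6), day = 1:3)
#' d$group <- rep(c("a", "b"), each = 3)[match(d$subject, paste0("m", 1:6))]
#' set.seed(1); d$value <- rnorm(nrow(d))
#' mixed_anova_gg(d, "value", "subject", "day", "group")
#' @export
mixed_anova_gg <- function(data, value = "value", subject = "subject",
                           within = "day", between = NULL) {
  y <- data[[value]]
  subj <- factor(data[[subject]])
  day <- factor(data[[within]])
  grp <- if (is.null(between)) factor(rep("all", nrow(data)))
         else factor(data[[between]])
  if (any(is.na(y))) stop("missing values in the response")
  tab <- table(subj, day)
  if (any(tab != 1))
    stop("incomplete design: every subject must be observed once per ",
         within, " level")
  sg <- table(subj, grp)
  if (any(rowSums(sg > 0) != 1))
    stop("each subject must belong to exactly one group")
  k <- nlevels(day)
  if (k < 2) stop("need at least 2 within-factor levels")
  subj_group <- factor(apply(sg > 0, 1, function(r) colnames(sg)[r]),
                       levels = levels(grp))
  g <- nlevels(grp)
  N <- nlevels(subj)
  if (any(table(subj_group) < 2))
    stop("need at least 2 subjects per group")

  # subjects x days score matrix
  Y <- matrix(NA_real_, N, k, dimnames = list(levels(subj), levels(day)))
  Y[cbind(as.integer(subj), as.integer(day))] <- y
  grand <- mean(Y)
  subj_means <- rowMeans(Y)
  day_means <- colMeans(Y)
  grp_means <- tapply(subj_means, subj_group, mean)
  n_per_group <- as.integer(table(subj_group))

  ss_total <- sum((Y - grand)^2)
  ss_between_subj <- k * sum((subj_means - grand)^2)
  ss_group <- k * sum(n_per_group * (grp_means - grand)^2)
  ss_subj <- ss_between_subj - ss_group
  ss_day <- N * sum((day_means - grand)^2)
  cell_means <- apply(Y, 2, function(col) tapply(col, subj_group, mean))
  cell_means <- matrix(cell_means, nrow = g)   # groups x days
  ss_int <- sum(n_per_group *
                  (cell_means - outer(as.numeric(grp_means), rep(1, k)) -
                     outer(rep(1, g), day_means) + grand)^2)
  ss_err <- ss_total - ss_between_subj - ss_day - ss_int

  df_day <- k - 1
  df_err <- (N - g) * (k - 1)
  df_int <- (g - 1) * (k - 1)
  ms_err <- ss_err / df_err
  if (ms_err <= .Machine$double.eps * abs(ss_total + 1))
    stop("zero residual variance: F statistics undefined")

  # Greenhouse-Geisser epsilon from the pooled within-group covariance
  Yc <- Y - cell_means[as.integer(subj_group), , drop = FALSE]
  S <- crossprod(Yc) / (N - g)
  M <- contrast_basis(k)
  SS <- t(M) %*% S %*% M
  eps <- sum(diag(SS))^2 / ((k - 1) * sum(SS^2))
  eps <- min(1, max(eps, 1 / (k - 1)))

  res <- list()
  if (g > 1) {
    f_group <- (ss_group / (g - 1)) / (ss_subj / (N - g))
    res$group <- data.frame(
      effect = "group", F = f_group, df1 = g - 1, df2 = N - g,
      p_uncorrected = stats::pf(f_group, g - 1, N - g, lower.tail = FALSE),
      epsilon_GG = NA_real_,
      p_GG = stats::pf(f_group, g - 1, N - g, lower.tail = FALSE))
  }
  f_day <- (ss_day / df_day) / ms_err
  res$day <- data.frame(
    effect = within, F = f_day, df1 = df_day, df2 = df_err,
    p_uncorrected = stats::pf(f_day, df_day, df_err, lower.tail = FALSE),
    epsilon_GG = eps,
    p_GG = stats::pf(f_day, eps * df_day, eps * df_err, lower.tail = FALSE))
  if (g > 1) {
    f_int <- (ss_int / df_int) / ms_err
    res$int <- data.frame(
      effect = paste0("group:", within), F = f_int, df1 = df_int,
      df2 = df_err,
      p_uncorrected = stats::pf(f_int, df_int, df_err, lower.tail = FALSE),
      epsilon_GG = eps,
      p_GG = stats::pf(f_int, eps * df_int, eps * df_err,
                       lower.tail = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Orthonormal basis of contrasts orthogonal to the unit vector.
contrast_basis <- function(k) {
  M <- stats::contr.helmert(k)
  sweep(M, 2, sqrt(colSums(M^2)), "/")
}

#' Wilcoxon signed-rank test (exact by enumeration for small n)
#'
#' Paired two-sided test.  Zero differences are dropped (Wilcoxon's
#' convention).  For `n <= exact_max` non-zero differences the p-value
#' is computed by enumerating all 2^n sign patterns of the observed
#' absolute ranks (valid under ties); above that, a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y paired samples, or differences in `x` with `y = NULL`.
#' @param exact_max largest n for exact enumeration.
#' @return list with `statistic` (W, sum of positive-difference ranks),
#'   `p_value`, `n_used`, `n_zero_dropped`, `method`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 12) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all paired differences are zero: test undefined")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    W_all <- as.numeric(signs %*% r)
    p_ge <- mean(W_all >= W - 1e-9)
    p_le <- mean(W_all <= W + 1e-9)
    p <- min(1, 2 * min(p_ge, p_le))
    method <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = W, p_value = p, n_used = n, n_zero_dropped = n_zero,
       method = method)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided two-sample test.  Exact by enumeration of all group
#' assignments when `choose(n+m, n) <= exact_max_comb` (valid under
#' ties); otherwise normal approximation with tie and continuity
#' corrections.
#'
#' @param a,b the two samples.
#' @param exact_max_comb enumeration budget.
#' @return list with `statistic` (U for sample `a`), `p_value`, `method`.
#' @export
wilcoxon_rank_sum <- function(a, b, exact_max_comb = 20000) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n <- length(a); m <- length(b)
  if (n == 0 || m == 0) stop("both samples must be nonempty")
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  if (choose(n + m, n) <= exact_max_comb) {
    combos <- utils::combn(n + m, n)
    U_all <- colSums(matrix(r[combos], nrow = n)) - n * (n + 1) / 2
    p_ge <- mean(U_all >= U - 1e-9)
    p_le <- mean(U_all <= U + 1e-9)
    p <- min(1, 2 * min(p_ge, p_le))
    method <- "exact enumeration"
  } else {
    mu <- n * m / 2
    ties <- table(r)
    sigma2 <- n * m / 12 *
      ((n + m + 1) - sum(ties^3 - ties) / ((n + m) * (n + m - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = U, p_value = p, method = method)
}

#' Bonferroni adjustment
#'
#' @param p vector of p-values.
#' @param m number of comparisons; must be at least `length(p)`.
#' @return adjusted p-values, `min(1, m * p)`.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (m < length(p)) stop("m must be >= number of p-values")
  pmin(1, m * p)
}
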