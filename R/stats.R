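#' Two-sample Student's t-test
#'
#' Classic pooled-variance two-sample t computed from its defining formulas:
#' `t = (mean_a - mean_b) / sqrt(s2_p * (1/n_a + 1/n_b))` with
#' `s2_p = ((n_a - 1) s2_a + (n_b - 1) s2_b) / (n_a + n_b - 2)` and
#' `df = n_a + n_b - 2`; two-tailed p from the t distribution. A Welch
#' variant (Satterthwaite df) is available for unequal variances.
#'
#' Degenerate inputs (zero pooled variance) yield `p = 1` when the means are
#' equal and `p = 0`, flagged, when they differ.
#'
#' @param a,b Numeric vectors of per-cell measurements, each of length >= 2.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return List: `statistic`, `df`, `p`, `mean_a`, `mean_b`, `degenerate`.
#' @examples
#' students_t(c(1, 2, 3), c(4, 5, 6))$statistic  # -3.674
#' @export
students_t <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(is.numeric(a), is.numeric(b))
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each group needs n >= 2", call. = FALSE)
  ma <- mean(a); mb <- mean(b)
  va <- var(a); vb <- var(b)
  if (variant == "pooled") {
    s2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(s2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  if (se == 0 || !is.finite(df)) {
    if (ma == mb) {
      return(list(statistic = 0, df = na + nb - 2, p = 1,
                  mean_a = ma, mean_b = mb, degenerate = TRUE))
    }
    return(list(statistic = sign(ma - mb) * Inf, df = na + nb - 2, p = 0,
                mean_a = ma, mean_b = mb, degenerate = TRUE))
  }
  t <- (ma - mb) / se
  list(statistic = t, df = df, p = 2 * pt(-abs(t), df),
       mean_a = ma, mean_b = mb, degenerate = FALSE)
}

#' One-way fixed-effects ANOVA
#'
#' Omnibus test of equal means across k independent groups, computed from
#' sums of squares: `F = MS_between / MS_within` with
#' `df = (k - 1, N - k)`. When both sums of squares vanish (all observations
#' identical) the test reports `F = 0, p = 1`.
#'
#' @param groups List of numeric vectors, each of length >= 2.
#' @return List: `statistic` (F), `df` (`c(df1, df2)`), `p`, `ms_within`,
#'   `ss_between`, `ss_within`, `grand_mean`.
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  n <- lengths(groups)
  if (any(n < 2)) stop("each group needs n >= 2", call. = FALSE)
  k <- length(groups)
  N <- sum(n)
  all_x <- unlist(groups)
  gm <- mean(all_x)
  means <- vapply(groups, mean, 0)
  ssb <- sum(n * (means - gm)^2)
  ssw <- sum(vapply(seq_len(k), function(i) sum((groups[[i]] - means[i])^2), 0))
  df1 <- k - 1; df2 <- N - k
  msw <- ssw / df2
  if (ssw == 0 && ssb == 0) {
    f <- 0; p <- 1
  } else if (ssw == 0) {
    f <- Inf; p <- 0
  } else {
    f <- (ssb / df1) / msw
    p <- pf(f, df1, df2, lower.tail = FALSE)
  }
  list(statistic = f, df = c(df1, df2), p = p, ms_within = msw,
       ss_between = ssb, ss_within = ssw, grand_mean = gm)
}

#' Repeated-measures one-way ANOVA
#'
#' One-way ANOVA with subject (cell) as block, for designs where every cell
#' is measured under every condition (e.g. the glucose ramp). Sums of
#' squares: total = subjects + conditions + error, and
#' `F = MS_cond / MS_error` with `df = (k - 1, (n - 1)(k - 1))`.
#'
#' @param x Numeric matrix, subjects x conditions (complete, no NA).
#' @return Same shape as [one_way_anova()] (`ms_within` is the residual
#'   mean square used by the post-hoc comparisons).
#' @export
rm_one_way_anova <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("repeated-measures design must be complete", call. = FALSE)
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 conditions", call. = FALSE)
  gm <- mean(x)
  ss_subj <- k * sum((rowMeans(x) - gm)^2)
  ss_cond <- n * sum((colMeans(x) - gm)^2)
  ss_tot <- sum((x - gm)^2)
  ss_err <- ss_tot - ss_subj - ss_cond
  ss_err <- max(ss_err, 0)                     # guard tiny negative rounding
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  mse <- ss_err / df2
  if (ss_err == 0 && ss_cond == 0) {
    f <- 0; p <- 1
  } else if (ss_err == 0) {
    f <- Inf; p <- 0
  } else {
    f <- (ss_cond / df1) / mse
    p <- pf(f, df1, df2, lower.tail = FALSE)
  }
  list(statistic = f, df = c(df1, df2), p = p, ms_within = mse,
       ss_between = ss_cond, ss_within = ss_err, grand_mean = gm)
}

#' Balanced two-way fixed-effects ANOVA
#'
#' Two-factor ANOVA with interaction for a balanced design (equal
#' replication r in every factor-A x factor-B cell), via the cell-means
#' decomposition: `SS_A`, `SS_B`, `SS_AB` and `SS_error`, each tested
#' against `MS_error`. Unbalanced tables are rejected.
#'
#' @param values Numeric vector of observations.
#' @param factor_a,factor_b Factors (or coercible) of the same length.
#' @return List of three test results (`A`, `B`, `interaction`), each with
#'   `statistic`, `df`, `p`, plus `ms_error` and `df_error`.
#' @export
two_way_anova <- function(values, factor_a, factor_b) {
  fa <- factor(factor_a); fb <- factor(factor_b)
  stopifnot(length(values) == length(fa), length(values) == length(fb))
  tab <- table(fa, fb)
  if (length(unique(as.vector(tab))) != 1) {
    stop("two_way_anova requires a balanced design (equal cell counts)",
         call. = FALSE)
  }
  r <- as.vector(tab)[1]
  if (r < 2) stop("need >= 2 replicates per cell", call. = FALSE)
  a <- nlevels(fa); b <- nlevels(fb)
  gm <- mean(values)
  m_a <- tapply(values, fa, mean)
  m_b <- tapply(values, fb, mean)
  m_ab <- tapply(values, list(fa, fb), mean)
  ss_a <- r * b * sum((m_a - gm)^2)
  ss_b <- r * a * sum((m_b - gm)^2)
  ss_ab <- r * sum((m_ab - outer(m_a - gm, m_b - gm, `+`) - gm)^2)
  ss_e <- sum((values - m_ab[cbind(fa, fb)])^2)
  df_e <- a * b * (r - 1)
  mse <- ss_e / df_e
  one <- function(ss, df) {
    if (ss_e == 0 && ss == 0) return(list(statistic = 0, df = c(df, df_e), p = 1))
    if (ss_e == 0) return(list(statistic = Inf, df = c(df, df_e), p = 0))
    f <- (ss / df) / mse
    list(statistic = f, df = c(df, df_e),
         p = pf(f, df, df_e, lower.tail = FALSE))
  }
  list(A = one(ss_a, a - 1), B = one(ss_b, b - 1),
       interaction = one(ss_ab, (a - 1) * (b - 1)),
       ms_error = mse, df_error = df_e)
}

#' Scheffe post-hoc means comparisons
#'
#' All pairwise comparisons following an ANOVA, using Scheffe's criterion:
#' the pair (i, j) differs significantly iff
#' `S = (mean_i - mean_j)^2 / (MS_within (1/n_i + 1/n_j))` exceeds
#' `(k - 1) F_crit(alpha; k - 1, df_within)`; the p-value is the upper tail
#' of `F(k - 1, df_within)` at `S / (k - 1)`. The criterion is
#' simultaneously valid for all contrasts, so no pair can be significant
#' when the omnibus F is below its critical value.
#'
#' @param groups List of numeric vectors (per-group observations); only
#'   their means and sizes enter the statistic.
#' @param ms_within,df_within Residual mean square and df from the
#'   accompanying ANOVA; computed from a one-way ANOVA on `groups` when
#'   omitted. Pass the repeated-measures residuals for ramp designs.
#' @param alpha Family-wise significance level.
#' @param labels Optional group labels.
#' @return Data frame: `i`, `j`, `label_i`, `label_j`, `mean_diff`,
#'   `statistic`, `p`, `significant`.
#' @export
scheffe_posthoc <- function(groups, ms_within = NULL, df_within = NULL,
                            alpha = 0.05, labels = NULL) {
  stopifnot(is.list(groups), length(groups) >= 2)
  k <- length(groups)
  if (is.null(ms_within) || is.null(df_within)) {
    an <- one_way_anova(groups)
    ms_within <- an$ms_within
    df_within <- an$df[2]
  }
  if (df_within <= 0) stop("df_within must be positive", call. = FALSE)
  if (is.null(labels)) labels <- as.character(seq_len(k))
  means <- vapply(groups, mean, 0)
  n <- lengths(groups)
  crit <- (k - 1) * qf(1 - alpha, k - 1, df_within)
  pairs <- utils::combn(k, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(q) {
    i <- pairs[1, q]; j <- pairs[2, q]
    d <- means[i] - means[j]
    denom <- ms_within * (1 / n[i] + 1 / n[j])
    s <- if (denom == 0) {
      if (d == 0) 0 else Inf
    } else d^2 / denom
    data.frame(i = i, j = j, label_i = labels[i], label_j = labels[j],
               mean_diff = d, statistic = s,
               p = pf(s / (k - 1), k - 1, df_within, lower.tail = FALSE),
               significant = s > crit)
  }))
  rownames(out) <- NULL
  attr(out, "critical_value") <- crit
  out
}
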