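#' Welch's two-sample t-test
#'
#' Two-tailed Student's t-test assuming unequal variances:
#' `t = (m_a - m_b) / sqrt(s_a^2/n_a + s_b^2/n_b)` with
#' Welch-Satterthwaite degrees of freedom. When both groups have zero
#' variance, equal means give `p = 1` by convention and unequal means
#' `p = 0`.
#'
#' @param a,b numeric samples, each of size >= 2.
#' @param comparison label for the result row.
#' @param alpha significance level for the flag (default 0.05).
#' @return One-row data frame (class `test_result`): `comparison`,
#'   `statistic`, `df`, `p`, `significant`.
#' @export
welch_ttest <- function(a, b, comparison = "a vs b", alpha = 0.05) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 values")
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  dm <- mean(a) - mean(b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    t <- if (dm == 0) 0 else sign(dm) * Inf
    p <- if (dm == 0) 1 else 0
    df <- NA_real_
  } else {
    t <- dm / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * stats::pt(-abs(t), df)
  }
  out <- data.frame(comparison = comparison, statistic = t, df = df, p = p,
                    significant = p < alpha)
  class(out) <- c("test_result", "data.frame")
  out
}

#' One-way ANOVA with Games-Howell post hoc comparisons
#'
#' Omnibus one-way ANOVA across all groups, followed by Games-Howell
#' pairwise comparisons, the post hoc test for unequal variances and
#' unequal sample sizes: for each pair,
#' `q = |m_i - m_j| / sqrt((s_i^2/n_i + s_j^2/n_j) / 2)` with a Welch-type
#' per-pair df, and the p-value from the studentized range distribution
#' with the total number of groups as the number of means.
#'
#' @param groups named list of numeric samples (>= 3 groups, each n >= 2).
#' @param alpha significance level for the flags.
#' @return List: `anova` (one-row data frame `F`, `df1`, `df2`, `p`) and
#'   `pairwise` (`test_result` data frame, one row per pair, `statistic`
#'   being the studentized-range q).
#' @export
anova_games_howell <- function(groups, alpha = 0.05) {
  k <- length(groups)
  if (k < 3L) stop("need at least 3 groups")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("g", seq_len(k))
  if (any(vapply(groups, length, 0L) < 2L))
    stop("each group needs at least 2 values")
  dat <- data.frame(value = unlist(groups, use.names = FALSE),
                    group = factor(rep(names(groups),
                                       vapply(groups, length, 0L))))
  av <- stats::anova(stats::aov(value ~ group, data = dat))
  an <- data.frame(F = av$`F value`[1], df1 = av$Df[1], df2 = av$Df[2],
                   p = av$`Pr(>F)`[1])
  m <- vapply(groups, mean, 0); v <- vapply(groups, stats::var, 0)
  n <- vapply(groups, length, 0L)
  pairs <- utils::combn(k, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(c0) {
    i <- pairs[1, c0]; j <- pairs[2, c0]
    se2 <- v[i] / n[i] + v[j] / n[j]
    lbl <- paste(names(groups)[i], "vs", names(groups)[j])
    if (se2 == 0) {
      warning("zero variance in pair ", lbl, "; limiting df used")
      q <- if (m[i] == m[j]) 0 else Inf
      p <- if (m[i] == m[j]) 1 else 0
      return(data.frame(comparison = lbl, statistic = q, df = Inf, p = p,
                        significant = p < alpha))
    }
    q <- abs(m[i] - m[j]) / sqrt(se2 / 2)
    df <- se2^2 / ((v[i] / n[i])^2 / (n[i] - 1) +
                   (v[j] / n[j])^2 / (n[j] - 1))
    p <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    data.frame(comparison = lbl, statistic = q, df = df, p = p,
               significant = p < alpha)
  })
  pw <- do.call(rbind, rows)
  class(pw) <- c("test_result", "data.frame")
  list(anova = an, pairwise = pw)
}

#' Notched-boxplot summary of one group
#'
#' Quartiles by linear interpolation of order statistics, notch half-width
#' `1.57 x IQR / sqrt(n)` (the McGill convention for 95% confidence on the
#' median), and outliers flagged by the 1.5 x IQR rule: values more than
#' 1.5 interquartile ranges beyond the box edges.
#'
#' @param values numeric sample (n >= 1).
#' @return List of class `group_summary`: `n`, `mean`, `sd`, `median`,
#'   `q1`, `q3`, `iqr`, `notch_half_width`, `whisker_lo`, `whisker_hi`,
#'   `outliers`.
#' @export
box_summary <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 1L) stop("need at least one value")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  out <- values[values < lo_fence | values > hi_fence]
  inr <- values[values >= lo_fence & values <= hi_fence]
  structure(list(n = n, mean = mean(values),
                 sd = if (n > 1) stats::sd(values) else 0,
                 median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
                 notch_half_width = 1.57 * iqr / sqrt(n),
                 whisker_lo = min(inr), whisker_hi = max(inr),
                 outliers = sort(out)),
            class = "group_summary")
}
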