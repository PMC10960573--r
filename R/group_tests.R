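# Vectorised per-column two-group tests used for promoter feature
# selection inside cross-validation folds. Re-selecting features in every
# training fold over thousands of promoters makes per-column calls to
# stats::wilcox.test the bottleneck, so both tests are computed in bulk;
# tests check them against oneway.test/t.test and wilcox.test.

# One-way ANOVA p-value (two groups: identical to the equal-variance
# t-test) per column, NA-aware. Columns where either group has fewer than
# two observations, or with zero within- and between-group variance, get
# p = 1; zero within-group variance with distinct means gets p = 0.
colAnovaP <- function(x, isG1) {
  x1 <- x[isG1, , drop = FALSE]
  x2 <- x[!isG1, , drop = FALSE]
  n1 <- colSums(!is.na(x1)); n2 <- colSums(!is.na(x2))
  s1 <- colSums(x1, na.rm = TRUE); s2 <- colSums(x2, na.rm = TRUE)
  q1 <- colSums(x1 * x1, na.rm = TRUE); q2 <- colSums(x2 * x2, na.rm = TRUE)
  m1 <- s1 / n1; m2 <- s2 / n2
  n <- n1 + n2
  m <- (s1 + s2) / n
  ssw <- (q1 - s1^2 / n1) + (q2 - s2^2 / n2)
  ssb <- n1 * (m1 - m)^2 + n2 * (m2 - m)^2
  df2 <- n - 2
  f <- ssb / (ssw / df2)
  p <- stats::pf(f, 1, df2, lower.tail = FALSE)
  degen <- ssw <= 0
  p[degen] <- ifelse(ssb[degen] <= 1e-24, 1, 0)
  p[n1 < 2 | n2 < 2] <- 1
  unname(p)
}

# Two-sided Wilcoxon rank-sum p-value per column via the normal
# approximation with tie correction and continuity correction (the
# wilcox.test(exact = FALSE, correct = TRUE) computation), NA-aware.
colWilcoxP <- function(x, isG1) {
  vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    ok <- !is.na(v)
    g <- isG1[ok]
    n1 <- sum(g); n2 <- sum(!g)
    if (n1 == 0L || n2 == 0L) return(1)
    r <- rank(v[ok])
    w <- sum(r[g]) - n1 * (n1 + 1) / 2
    nn <- n1 + n2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 *
      ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
    if (sigma2 <= 0) return(1)
    z <- w - n1 * n2 / 2
    z <- z - sign(z) * 0.5
    min(1, 2 * stats::pnorm(-abs(z) / sqrt(sigma2)))
  }, numeric(1))
}

#' Rank-based AUC estimator
#'
#' Area under the ROC curve computed from the rank-sum (Mann-Whitney)
#' statistic of the scores of positive versus negative samples; tied
#' scores contribute 0.5 through midranks.
#'
#' @param scores numeric prediction scores.
#' @param labels parallel 0/1 vector (or `"Birth"`/`"Failed"` labels,
#'   birth positive).
#' @return AUC in \[0, 1\].
#' @export
rankAuc <- function(scores, labels) {
  if (is.character(labels) || is.factor(labels))
    labels <- as.integer(as.character(labels) == "Birth")
  stopifnot(length(scores) == length(labels),
            all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes required for an AUC")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
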