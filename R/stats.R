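## Statistical validation: 2x2 chi-square association test with effect
## sizes, and the exact Wilcoxon signed-rank test.

#' 2x2 contingency table of predicted vs actual classes
#'
#' Rows are predicted classes (1 then 0), columns actual classes (1 then
#' 0), so the table reads \[TP, FP; FN, TN\].
#'
#' @param predicted,actual 0/1 vectors of equal length.
#' @return 2x2 integer matrix with dimnames `predicted`/`actual`.
#' @export
confusionTable <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    stopf("length mismatch: %d vs %d", length(predicted), length(actual))
  }
  if (!all(predicted %in% c(0, 1)) || !all(actual %in% c(0, 1))) {
    stopf("inputs must be binary 0/1")
  }
  m <- matrix(c(sum(predicted == 1 & actual == 1),
                sum(predicted == 0 & actual == 1),
                sum(predicted == 1 & actual == 0),
                sum(predicted == 0 & actual == 0)), 2L, 2L)
  dimnames(m) <- list(predicted = c("1", "0"), actual = c("1", "0"))
  m
}

#' Chi-square test of association for a 2x2 table, with effect sizes
#'
#' Computes the Pearson chi-square statistic `sum((O - E)^2 / E)` with
#' expected counts from the row/column margins, df = 1, and the p-value
#' from the chi-square distribution. Effect sizes: Cramer's V, the phi
#' coefficient and Cohen's w, which all equal `sqrt(chi2 / n)` for a 2x2
#' table. The Yates continuity correction is off by default (the plain
#' Pearson statistic), available via `correct = TRUE`.
#'
#' @param table 2x2 matrix of nonnegative counts (e.g. [confusionTable()]).
#' @param correct apply the Yates continuity correction.
#' @return list of class `ChiSquareResult`: `chi2`, `df`, `p_value`,
#'   `cramers_v`, `phi`, `cohens_w`, `expected`, `n`.
#' @examples
#' chiSquare2x2(matrix(c(10, 0, 0, 10), 2))  # perfect association: V = 1
#' @export
chiSquare2x2 <- function(table, correct = FALSE) {
  O <- as.matrix(table)
  if (!all(dim(O) == c(2L, 2L))) stopf("table must be 2x2")
  if (any(O < 0) || any(O != round(O))) stopf("counts must be nonnegative integers")
  n <- sum(O)
  E <- outer(rowSums(O), colSums(O)) / n
  if (any(E == 0)) stopf("zero margin: expected count of 0")
  dev <- abs(O - E)
  if (correct) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / E)
  v <- sqrt(chi2 / n)
  structure(list(chi2 = chi2, df = 1L,
                 p_value = stats::pchisq(chi2, df = 1L, lower.tail = FALSE),
                 cramers_v = v, phi = v, cohens_w = v,
                 expected = E, n = n, correct = correct),
            class = "ChiSquareResult")
}

#' @export
print.ChiSquareResult <- function(x, ...) {
  cat(sprintf(
    "Chi-square association (2x2%s): chi2 = %.4g, df = %d, p = %.4g\n  Cramer's V = phi = Cohen's w = %.4g (n = %d)\n",
    if (x$correct) ", Yates-corrected" else "", x$chi2, x$df, x$p_value,
    x$cramers_v, x$n))
  invisible(x)
}

## Exact null distribution of W (sum of positive ranks) by convolution of
## the rank generating function. Ranks may be half-integers under average-
## rank ties, so everything is doubled to stay on an integer lattice.
## Under H0 the signs are independent fair coins, so P(W = w) is the
## coefficient of z^w in prod_i (1 + z^(r_i)) / 2^n -- exact for any tie
## pattern.
signedRankNullCdf <- function(ranks2) {
  total <- sum(ranks2)
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), f[seq_len(total + 1L - r)])
    f <- (f + shifted) / 2
  }
  f  # f[w + 1] = P(2W = w)
}

#' Exact Wilcoxon signed-rank test
#'
#' Ranks the absolute paired differences (average ranks for ties; zero
#' differences dropped), takes `W` as the sum of positive ranks, and
#' computes exact p-values from the full null distribution of `W`
#' (generating-function convolution over the realized ranks — no normal
#' approximation at any n; ties are handled exactly because the signs
#' remain independent under the null). The one-sided p-value is the upper
#' tail `P(W >= w)`; the two-sided p-value doubles the smaller tail
#' (capped at 1).
#'
#' @param x paired differences, or the first sample when `y` is given.
#' @param y optional second sample; the test is on `x - y`.
#' @return list of class `WilcoxonResult`: `W`, `n_effective`,
#'   `p_one_sided`, `p_two_sided`, `ranks`.
#' @examples
#' wilcoxonSignedRankExact(1:44)  # W = 990, p = 2^-44
#' @export
wilcoxonSignedRankExact <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stopf("all differences are zero; test undefined")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ranks2 <- as.integer(round(2 * r))
  f <- signedRankNullCdf(ranks2)
  w2 <- as.integer(round(2 * W))
  pGe <- sum(f[(w2 + 1L):length(f)])
  pLe <- sum(f[1L:(w2 + 1L)])
  structure(list(W = W, n_effective = n,
                 p_one_sided = pGe,
                 p_two_sided = min(1, 2 * min(pGe, pLe)),
                 ranks = r),
            class = "WilcoxonResult")
}

#' @export
print.WilcoxonResult <- function(x, ...) {
  cat(sprintf(
    "Exact Wilcoxon signed-rank: W = %g on %d nonzero differences\n  one-sided p = %.4g, two-sided p = %.4g\n",
    x$W, x$n_effective, x$p_one_sided, x$p_two_sided))
  invisible(x)
}
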