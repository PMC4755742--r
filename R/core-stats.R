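#' Geometric mean
#'
#' Geometric mean of a vector of strictly positive values, computed on the
#' log scale for numerical stability. Used by the nCounter positive-control
#' normalization, where per-sample scaling factors are derived from the
#' geometric mean of the spike-in positive probes.
#'
#' @param x Numeric vector of strictly positive values.
#' @return A single positive number, `exp(mean(log(x)))`.
#' @examples
#' geometric_mean(c(2, 8, 4)) # 4
#' @export
geometric_mean <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0L) stop("'x' must contain at least one value")
  if (anyNA(x) || any(x <= 0)) stop("all values must be positive and non-missing")
  exp(mean(log(x)))
}

#' One-tailed two-sample Student's t-test
#'
#' Pooled-variance ("classic" Student) two-sample t-test of the alternative
#' mean(a) > mean(b). This is the detection test used to call a gene present
#' against the negative-control probes. When both samples are constant and
#' equal, the test is uninformative and p = 0.5 is returned by convention;
#' constant samples with unequal means give p = 0 or 1 according to the
#' direction of the difference.
#'
#' @param a,b Numeric vectors with at least two values each.
#' @return One-sided p-value for mean(a) > mean(b).
#' @export
one_tailed_t_test <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample must contain at least 2 values")
  if (anyNA(a) || anyNA(b)) stop("missing values are not allowed")
  pooled_ss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
  if (pooled_ss == 0) {
    d <- mean(a) - mean(b)
    return(if (d == 0) 0.5 else if (d > 0) 0 else 1)
  }
  stats::t.test(a, b, alternative = "greater", var.equal = TRUE)$p.value
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact test of association in a 2x2 contingency table. The
#' two-sided p-value is the sum of hypergeometric probabilities, over tables
#' with the observed margins, that do not exceed the probability of the
#' observed table (the usual "point probability" convention; the doubling
#' convention is not used).
#'
#' @param tab 2x2 matrix of non-negative integer counts, or a length-4
#'   vector `(a, b, c, d)` filled by row.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  if (is.vector(tab) && length(tab) == 4L) tab <- matrix(tab, 2, 2, byrow = TRUE)
  if (!is.matrix(tab) || any(dim(tab) != 2L))
    stop("'tab' must be a 2x2 table")
  if (anyNA(tab) || any(tab < 0) || any(tab != round(tab)))
    stop("cells must be non-negative integers")
  if (sum(tab) == 0) return(1)
  stats::fisher.test(tab)$p.value
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment with monotonicity enforcement.
#' Input order is preserved; ties adjust identically.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @return An object of class `pvalue_set`: a list with `raw_p`,
#'   `adjusted_p` (same order as input) and `method`.
#' @export
bh_adjust <- function(p) {
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  structure(list(raw_p = p,
                 adjusted_p = stats::p.adjust(p, method = "BH"),
                 method = "BH"),
            class = "pvalue_set")
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples. With no ties and a combined sample
#' size of at most 20 the exact null distribution of U is used; otherwise
#' the normal approximation with midranks and the tie-corrected variance is
#' used (no continuity correction). The two-sided p-value is
#' `min(1, 2 * min(lower tail, upper tail))`.
#'
#' @param a,b Non-empty numeric vectors.
#' @return List with `U` (number of (a, b) pairs with a > b, ties counting
#'   1/2), `p` (two-sided), and `method` ("exact" or "normal").
#' @export
mann_whitney_u <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) stop("samples must be non-empty")
  if (anyNA(a) || anyNA(b)) stop("missing values are not allowed")
  ties <- any(duplicated(c(a, b)))
  exact <- !ties && (length(a) + length(b)) <= 20L
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = FALSE)
  )
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal")
}

#' Summarize per-replicate proportions
#'
#' Average of per-replicate success fractions with its standard error of the
#' mean. With a single replicate the s.e.m. is undefined and reported as 0,
#' with `n1_flag = TRUE`.
#'
#' @param successes,totals Integer vectors of per-replicate successes and
#'   totals (`totals > 0`).
#' @return List with `mean_fraction`, `sem`, `n`, `n1_flag`.
#' @export
proportion_summary <- function(successes, totals) {
  if (length(successes) != length(totals) || length(totals) == 0L)
    stop("'successes' and 'totals' must be non-empty and of equal length")
  if (any(totals <= 0)) stop("all totals must be positive")
  if (any(successes < 0 | successes > totals)) stop("successes must lie in [0, total]")
  f <- successes / totals
  n <- length(f)
  list(mean_fraction = mean(f),
       sem = if (n > 1L) stats::sd(f) / sqrt(n) else 0,
       n = n,
       n1_flag = n == 1L)
}
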