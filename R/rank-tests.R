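#' Mann-Whitney U test (Wilcoxon rank sum), two-sided, unpaired
#'
#' Exact enumeration when the pooled sample is small (`n_a + n_b <= 12`) and
#' tie-free, otherwise the normal approximation with tie/continuity
#' correction. U and p are invariant under any common monotone transform of
#' both samples.
#'
#' @param a,b numeric vectors (both nonempty).
#' @return A list with `U` (the rank-sum statistic for `a`) and
#'   `p_value` (two-sided).
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mann_whitney <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0)
    stop2("both samples must be nonempty")
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- (length(a) + length(b) <= 12) && !ties
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", paired = FALSE,
                exact = use_exact, correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value)
}

#' Two-sample two-sided Kolmogorov-Smirnov comparison
#'
#' D is the maximum gap between the two empirical cumulative distribution
#' functions; p is asymptotic. Used for both the integral TSS-signal and
#' the peak-breadth comparisons.
#'
#' @param a,b numeric vectors, each with at least 2 values.
#' @return A list with `D` and `p_value`.
#' @export
ks_compare <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    stop2("both samples need at least 2 values")
  if (length(unique(c(a, b))) < 2)
    stop2("degenerate samples: all values identical")
  kt <- suppressWarnings(ks.test(a, b, alternative = "two.sided",
                                 exact = FALSE))
  list(D = unname(kt$statistic), p_value = kt$p.value)
}
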