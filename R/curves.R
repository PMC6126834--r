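#' Stratified Q-Q points
#'
#' Compares the observed -log10(p) distribution to its null expectation.
#' Observed values are the sorted -log10 p (most significant first); the
#' expected value for rank i out of n uses the rank midpoint
#' -log10((i - 0.5) / n), which is distribution-free and depends only on n.
#'
#' @param pvals P-values in (0, 1]; nonempty.
#' @return data.frame with columns `expected`, `observed` (both -log10
#'   scale), ordered from most to least significant.
#' @export
qq_points <- function(pvals) {
  if (!length(pvals)) stop("empty p-value vector")
  if (any(pvals <= 0 | pvals > 1)) stop("p must lie in (0, 1]")
  n <- length(pvals)
  obs <- sort(-log10(pvals), decreasing = TRUE)
  exp <- -log10((seq_len(n) - 0.5) / n)
  data.frame(expected = exp, observed = obs)
}

#' Conditional fold-enrichment curve
#'
#' Ratio of complementary empirical CDFs of -log10(p) between an annotated
#' set S and a baseline set, across significance thresholds:
#' ratio(t) = \[#\{S: -log10 p >= t\} / |S|\] / \[#\{baseline: -log10 p >= t\}
#' / |baseline|\]. Thresholds are -log10(p) bin centers spaced `bin_width`
#' apart starting at 0 (where the ratio is identically 1 for complete sets);
#' the curve is truncated at the largest threshold whose baseline count is
#' at least `min_denominator`, so the tail is never a ratio of near-empty
#' bins. The baseline is typically the matched control set, but any set can
#' serve (e.g. one eQTL catalogue relative to another).
#'
#' @param pvals_s P-values of the annotated set S.
#' @param pvals_baseline P-values of the baseline set; nonempty.
#' @param bin_width Threshold spacing on the -log10 scale.
#' @param min_denominator Smallest baseline survivor count kept.
#' @return An object of class `fold_curve`: data.frame with columns
#'   `threshold`, `ratio`, `n_numerator`, `n_denominator`.
#' @export
fold_enrichment <- function(pvals_s, pvals_baseline, bin_width = 0.1,
                            min_denominator = 10) {
  if (!length(pvals_s)) stop("empty annotated set")
  if (!length(pvals_baseline)) stop("empty baseline set")
  ls <- -log10(pvals_s)
  lb <- -log10(pvals_baseline)
  tmax <- max(c(ls, lb))
  thresholds <- seq(0, tmax + bin_width, by = bin_width)
  n_num <- vapply(thresholds, function(t) sum(ls >= t), integer(1))
  n_den <- vapply(thresholds, function(t) sum(lb >= t), integer(1))
  # n_den is non-increasing in t: truncate at the last qualifying threshold
  qual <- which(n_den >= min_denominator)
  keep <- seq_len(if (length(qual)) max(qual) else 0L)
  thresholds <- thresholds[keep]; n_num <- n_num[keep]; n_den <- n_den[keep]
  ratio <- (n_num / length(ls)) / (n_den / length(lb))
  out <- data.frame(threshold = thresholds, ratio = ratio,
                    n_numerator = n_num, n_denominator = n_den)
  class(out) <- c("fold_curve", "data.frame")
  out
}

#' @export
plot.fold_curve <- function(x, log = "y", ...) {
  graphics::plot(x$threshold, x$ratio, type = "l", log = log,
                 xlab = expression(-log[10](p) ~ "threshold"),
                 ylab = "fold enrichment", ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' Mann-Whitney (Wilcoxon rank-sum) comparison of two samples
#'
#' Compares association statistics between two variant groups (e.g. eQTLs
#' vs matched controls). Uses the exact null distribution when both samples
#' are small (min n <= `exact_max`) and tie-free, and the normal
#' approximation with tie and continuity corrections otherwise.
#'
#' @param a,b Numeric samples (typically chi-squared statistics); nonempty.
#' @param exact_max Largest min(n) for which the exact branch is used.
#' @return List with `U` (the rank-sum statistic for `a`), `p` (two-sided),
#'   and `method` (`"exact"` or `"normal"`).
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p  # 0.1
#' @export
mann_whitney <- function(a, b, exact_max = 8) {
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- min(length(a), length(b)) <= exact_max && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = TRUE,
                       alternative = "two.sided")
  )
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (use_exact) "exact" else "normal")
}

#' Estimate the proportion of non-null associations (pi1)
#'
#' Storey-type estimator. For each lambda on the grid,
#' pi0(lambda) = #\{p > lambda\} / (n * (1 - lambda)); a cubic smoothing
#' spline (df = 3) of pi0(lambda) is evaluated at the largest lambda and
#' clamped to \[0, 1\], and pi1 = 1 - pi0. With `method = "fixed"` the raw
#' estimate at the largest grid value is used instead of the smoother.
#'
#' @param pvals P-values in (0, 1]; a warning is emitted below n = 100,
#'   where the tail counts are too noisy for the smoother.
#' @param lambda_grid Grid in (0, 1), ascending.
#' @param method `"smoother"` (default) or `"fixed"`.
#' @return An object of class `pi1_estimate`: list with `pi1`, `pi0`,
#'   `pi0_grid`, `lambda_grid`, `method`.
#' @export
estimate_pi1 <- function(pvals, lambda_grid = seq(0.05, 0.95, by = 0.05),
                         method = c("smoother", "fixed")) {
  method <- match.arg(method)
  n <- length(pvals)
  if (n == 0) stop("empty p-value vector")
  if (any(pvals <= 0 | pvals > 1)) stop("p must lie in (0, 1]")
  if (n < 100) warning("pi1 estimated from fewer than 100 p-values")
  stopifnot(all(lambda_grid > 0 & lambda_grid < 1))
  lambda_grid <- sort(lambda_grid)
  pi0_grid <- vapply(lambda_grid,
                     function(l) sum(pvals > l) / (n * (1 - l)), numeric(1))
  pi0 <- if (method == "smoother" && length(lambda_grid) >= 4) {
    fit <- stats::smooth.spline(lambda_grid, pi0_grid, df = 3)
    stats::predict(fit, x = max(lambda_grid))$y
  } else {
    pi0_grid[length(pi0_grid)]
  }
  pi0 <- min(max(pi0, 0), 1)
  structure(list(pi1 = 1 - pi0, pi0 = pi0, pi0_grid = pi0_grid,
                 lambda_grid = lambda_grid, method = method),
            class = "pi1_estimate")
}

#' @export
print.pi1_estimate <- function(x, ...) {
  cat(sprintf("<pi1_estimate> pi1 = %.4f (%s, grid of %d)\n",
              x$pi1, x$method, length(x$lambda_grid)))
  invisible(x)
}
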