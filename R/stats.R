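# Nonparametric statistics with exact small-sample behavior: Wilcoxon
# rank-sum (exact permutation distribution with mid-ranks), Fisher's exact
# test, Bonferroni and Benjamini-Hochberg adjustment, box-plot summaries.

#' Statistical test result container
#'
#' @param test_name test label.
#' @param statistic test statistic.
#' @param p_raw raw two-sided p-value.
#' @param n_per_group integer vector of group sizes.
#' @param p_adjusted adjusted p-value (defaults to `p_raw`).
#' @param adjust_method `"none"`, `"bonferroni"` or `"benjamini_hochberg"`.
#' @return an object of class `stat_result`.
#' @export
stat_result <- function(test_name, statistic, p_raw, n_per_group,
                        p_adjusted = p_raw, adjust_method = "none") {
  stopifnot(p_raw >= 0, p_raw <= 1, p_adjusted >= p_raw - 1e-12,
            p_adjusted <= 1)
  structure(list(test_name = test_name, statistic = statistic,
                 p_raw = p_raw, p_adjusted = p_adjusted,
                 adjust_method = adjust_method,
                 n_per_group = n_per_group),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<%s: statistic = %.4g, p = %.4g (adjusted %.4g, %s), n = %s>\n",
              x$test_name, x$statistic, x$p_raw, x$p_adjusted,
              x$adjust_method, paste(x$n_per_group, collapse = "/")))
  invisible(x)
}

# Exact permutation distribution of the rank sum of group 1 under the
# null, over doubled mid-ranks (integers even with ties). Returns the
# two-sided p as twice the smaller tail, capped at 1. Dynamic program:
# ways[k, s] = number of k-subsets of the doubled mid-ranks with sum s.
exact_ranksum_p <- function(ranks2, n1, obs2) {
  n <- length(ranks2)
  total <- sum(ranks2)
  # dp[[k]] is a vector of counts indexed by sum + 1 (sums start at 0)
  maxsum <- total
  dp <- vector("list", n1 + 1L)
  dp[[1L]] <- c(1, numeric(maxsum))
  for (k in seq_len(n1)) dp[[k + 1L]] <- numeric(maxsum + 1L)
  for (r in ranks2) {
    for (k in rev(seq_len(n1))) {
      shifted <- c(numeric(r), dp[[k]][seq_len(maxsum + 1L - r)])
      dp[[k + 1L]] <- dp[[k + 1L]] + shifted
    }
  }
  counts <- dp[[n1 + 1L]]
  n_total <- choose(n, n1)
  sums <- seq_along(counts) - 1L
  tol <- 1e-9
  p_le <- sum(counts[sums <= obs2 + tol]) / n_total
  p_ge <- sum(counts[sums >= obs2 - tol]) / n_total
  min(1, 2 * min(p_le, p_ge))
}

#' Wilcoxon rank-sum test (two-sided)
#'
#' Exact mode enumerates the permutation distribution of the group-1 rank
#' sum (mid-ranks under ties) and reports twice the smaller tail
#' probability, capped at 1. The normal approximation applies the usual
#' tie-corrected variance and a 0.5 continuity correction. By default the
#' exact mode is used for combined sample sizes up to 20.
#'
#' @param x,y numeric samples.
#' @param mode `"auto"` (default), `"exact"` or `"normal_approx"`.
#' @return a [stat_result()]; the statistic is the Mann-Whitney U of `x`.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p_raw # 0.1
#' @export
rank_sum_test <- function(x, y, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  if (!is.numeric(x) || !is.numeric(y) || length(x) < 1L || length(y) < 1L) {
    stop("'x' and 'y' must be non-empty numeric samples", call. = FALSE)
  }
  if (any(!is.finite(c(x, y)))) {
    stop("samples must be finite", call. = FALSE)
  }
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  rk <- rank(pooled) # mid-ranks for ties
  s_obs <- sum(rk[seq_len(n1)])
  u_obs <- s_obs - n1 * (n1 + 1) / 2
  if (length(unique(pooled)) == 1L) {
    warning("all pooled values identical; p = 1")
    return(stat_result("wilcoxon_rank_sum", u_obs, 1, c(n1, n2)))
  }
  if (mode == "auto") mode <- if (n <= 20L) "exact" else "normal_approx"
  p <- if (mode == "exact") {
    exact_ranksum_p(as.integer(round(2 * rk)), n1, round(2 * s_obs))
  } else {
    mu <- n1 * (n + 1) / 2
    ties <- table(rk)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    v <- n1 * n2 / 12 * ((n + 1) - tie_term)
    d <- s_obs - mu
    z <- (d - sign(d) * 0.5) / sqrt(v)
    min(1, 2 * stats::pnorm(-abs(z)))
  }
  stat_result(sprintf("wilcoxon_rank_sum_%s", mode), u_obs, p, c(n1, n2))
}

#' Fisher's exact test on a 2x2 table (two-sided)
#'
#' The two-sided p-value is the sum of hypergeometric probabilities of
#' every table with the observed margins whose probability does not
#' exceed the observed table's (with a `1 + 1e-7` relative tolerance) —
#' the probability-mass convention of mainstream implementations.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return a [stat_result()]; the statistic is the sample odds ratio.
#' @examples
#' fisher_exact_test(matrix(c(5, 0, 0, 5), 2))$p_raw # 2/252
#' @export
fisher_exact_test <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)) || any(table < 0) ||
      any(table != round(table)) || any(!is.finite(table))) {
    stop("'table' must be a 2x2 matrix of non-negative integers",
         call. = FALSE)
  }
  r1 <- sum(table[1, ]); c1 <- sum(table[, 1]); n <- sum(table)
  or <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) {
    warning("degenerate table (zero margin); p = 1")
    return(stat_result("fisher_exact", or, 1,
                       c(sum(table[1, ]), sum(table[2, ]))))
  }
  k <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(k, c1, n - c1, r1)
  p_obs <- stats::dhyper(table[1, 1], c1, n - c1, r1)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  stat_result("fisher_exact", or, p, c(sum(table[1, ]), sum(table[2, ])))
}

#' Adjust p-values for multiple comparisons
#'
#' Bonferroni multiplies each p by `m` and caps at 1. Benjamini-Hochberg
#' applies the step-up rule: sorted ascending, `p_(i) * m / i`, enforced
#' monotone from the largest down, capped at 1. Input order is preserved.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param method `"bonferroni"` or `"benjamini_hochberg"`.
#' @param m number of comparisons; defaults to `length(p)` and must be at
#'   least that (the effective family size is an explicit argument because
#'   figure-level families can exceed the p-values at hand).
#' @return adjusted p-values in the input order.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "benjamini_hochberg"),
                           m = length(p)) {
  method <- match.arg(method)
  if (!is.numeric(p) || length(p) < 1L) {
    stop("'p' must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  check_count(m, "m", min = length(p))
  if (method == "bonferroni") return(pmin(1, m * p))
  o <- order(p)
  ranked <- p[o] * m / seq_along(p)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(length(p))
  out[o] <- pmin(1, adj)
  out
}

#' Box-plot summary of a sample
#'
#' Quartiles use linear interpolation between order statistics (quantile
#' type 7). Whisker rules: `"tukey"` extends whiskers to the most extreme
#' data points within 1.5 IQR of the box and reports points beyond as
#' outliers; `"range"` extends whiskers to the data range (no outliers).
#'
#' @param x numeric sample, `n >= 1`.
#' @param whisker_rule `"tukey"` (default) or `"range"`.
#' @return an object of class `box_summary` with `median`, `q1`, `q3`,
#'   `whisker_low`, `whisker_high`, `outliers`.
#' @export
box_summary <- function(x, whisker_rule = c("tukey", "range")) {
  whisker_rule <- match.arg(whisker_rule)
  if (!is.numeric(x) || length(x) < 1L || any(!is.finite(x))) {
    stop("'x' must be a non-empty finite numeric sample", call. = FALSE)
  }
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  if (whisker_rule == "tukey") {
    iqr <- q[3] - q[1]
    lo_fence <- q[1] - 1.5 * iqr
    hi_fence <- q[3] + 1.5 * iqr
    inside <- x >= lo_fence & x <= hi_fence
    whisker_low <- min(x[inside]); whisker_high <- max(x[inside])
    outliers <- sort(x[!inside])
  } else {
    whisker_low <- min(x); whisker_high <- max(x)
    outliers <- numeric(0)
  }
  structure(list(median = q[2], q1 = q[1], q3 = q[3],
                 whisker_low = whisker_low, whisker_high = whisker_high,
                 outliers = outliers, whisker_rule = whisker_rule),
            class = "box_summary")
}

#' @export
print.box_summary <- function(x, ...) {
  cat(sprintf(
    "<box_summary: median %.4g [Q1 %.4g, Q3 %.4g], whiskers %.4g..%.4g, %d outlier(s)>\n",
    x$median, x$q1, x$q3, x$whisker_low, x$whisker_high, length(x$outliers)))
  invisible(x)
}
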