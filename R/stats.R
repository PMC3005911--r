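.test_result <- function(statistic = NA_real_, df = NA_real_, p = NA_real_,
                         n = NA_integer_, flags = character()) {
  structure(list(statistic = statistic, df = df, p = p, n = n, flags = flags),
            class = "aaflux_test")
}

#' Chi-square test for heterogeneity of two counts
#'
#' Tests whether two event counts are compatible with a null expectation
#' proportional to two positive weights (branch-length sums of the two
#' clades; equal weights give the equal-split null):
#' `expected_i = total * weight_i / sum(weights)`,
#' `chi2 = sum((obs - exp)^2 / exp)`, df = 1, two-sided p from the
#' chi-square survival function. No continuity correction by default.
#'
#' @param counts Numeric length-2, non-negative (fractional counts from
#'   split-weighted ambiguous events are accepted).
#' @param weights Positive length-2 weights; default equal split.
#' @param correct Apply the Yates continuity correction (default FALSE).
#' @return `aaflux_test` list: `statistic`, `df`, `p`, `n`, `flags`
#'   (may include `"undefined"` when both counts are 0, and
#'   `"low_expectation"` when an expected count is below 1).
#' @export
chi2_heterogeneity <- function(counts, weights = c(1, 1), correct = FALSE) {
  stopifnot(length(counts) == 2L, length(weights) == 2L)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(weights <= 0)) stop("weights must be positive")
  total <- sum(counts)
  if (total == 0) {
    return(.test_result(n = 0L, flags = "undefined"))
  }
  expected <- total * weights / sum(weights)
  dev <- abs(counts - expected)
  if (correct) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / expected)
  flags <- if (any(expected < 1)) "low_expectation" else character()
  .test_result(statistic = stat, df = 1,
               p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
               n = total, flags = flags)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of freedom
#' (pooled-variance Student test available via `pooled = TRUE`). Both groups
#' must hold at least two values; smaller groups raise an eligibility error
#' (duplications failing the two-unambiguous-substitutions-per-clade rule
#' are skipped, not tested).
#'
#' @param group1,group2 Numeric vectors, each of length >= 2.
#' @param pooled Use the pooled-variance Student test instead of Welch.
#' @return `aaflux_test` with `statistic` (t), `df`, two-sided `p`, `n`
#'   (per-group sizes).
#' @export
welch_t <- function(group1, group2, pooled = FALSE) {
  if (length(group1) < 2L || length(group2) < 2L) {
    stop(structure(class = c("aaflux_eligibility_error", "error", "condition"),
                   list(message = "both groups must hold at least 2 values",
                        call = sys.call())))
  }
  if (stats::sd(group1) == 0 && stats::sd(group2) == 0) {
    ## zero variance in both groups: t undefined unless means differ
    if (mean(group1) == mean(group2)) {
      return(.test_result(statistic = 0, df = length(c(group1, group2)) - 2,
                          p = 1, n = c(length(group1), length(group2)),
                          flags = "degenerate"))
    }
    return(.test_result(statistic = Inf, df = NA_real_, p = 0,
                        n = c(length(group1), length(group2)),
                        flags = "degenerate"))
  }
  tt <- stats::t.test(group1, group2, var.equal = pooled)
  .test_result(statistic = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, n = c(length(group1), length(group2)))
}

#' Exact two-sided sign test
#'
#' Exact binomial test of k successes in n trials against success
#' probability 1/2; two-tailed by doubling the smaller tail, capped at 1.
#' Ties must be excluded before the call.
#'
#' @param k Number of successes, `0 <= k <= n`.
#' @param n Number of trials, `n >= 1`.
#' @return `aaflux_test` with `statistic` (k), `p`, `n`.
#' @export
sign_test <- function(k, n) {
  if (n < 1L) return(.test_result(flags = "undefined"))
  stopifnot(k >= 0, k <= n)
  lower <- stats::pbinom(k, n, 0.5)
  upper <- stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  .test_result(statistic = k, p = min(1, 2 * min(lower, upper)), n = n)
}

#' Benjamini-Hochberg step-up rejection at level q
#'
#' Rejects all hypotheses with p at or below p(k*), where
#' k* = max{k : p(k) <= k q / m}; m counts the tests actually performed
#' (NA p-values — skipped, ineligible tests — are excluded from m and
#' returned as NA).
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @param q Target false discovery rate, in (0, 1).
#' @return Logical vector of rejection flags, NA where p was NA.
#' @export
bh_fdr <- function(p, q) {
  stopifnot(q > 0, q < 1, all(is.na(p) | (p >= 0 & p <= 1)))
  out <- rep(NA, length(p))
  ok <- !is.na(p)
  if (any(ok)) out[ok] <- stats::p.adjust(p[ok], method = "BH") <= q
  out
}

#' Bonferroni rejection at family-wise level alpha
#'
#' Rejects p_i iff p_i <= alpha / m, with m the number of non-NA tests.
#'
#' @param p Numeric vector of p-values (NAs allowed, excluded from m).
#' @param alpha Family-wise error level, in (0, 1).
#' @return Logical vector of rejection flags, NA where p was NA.
#' @export
bonferroni <- function(p, alpha) {
  stopifnot(alpha > 0, alpha < 1, all(is.na(p) | (p >= 0 & p <= 1)))
  out <- rep(NA, length(p))
  ok <- !is.na(p)
  if (any(ok)) out[ok] <- stats::p.adjust(p[ok], method = "bonferroni") <= alpha
  out
}

#' Rank (Spearman) or product-moment (Pearson) correlation
#'
#' Spearman uses average ranks for ties; two-sided p-values via the usual t
#' transform. A constant vector leaves the coefficient undefined (flagged).
#'
#' @param x,y Equal-length numeric vectors, n >= 3, finite.
#' @param method `"spearman"` or `"pearson"`.
#' @return `aaflux_test` with `statistic` (the coefficient), `p`, `n`.
#' @export
rank_and_product_correlations <- function(x, y,
                                          method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3L,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(.test_result(n = length(x), flags = "constant_input"))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  .test_result(statistic = unname(ct$estimate), p = ct$p.value, n = length(x))
}
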