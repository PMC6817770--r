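## Descriptive group summaries and the rank test.
##
## The Mann-Whitney U statistic is computed from rank sums with midranks for
## ties. The exact two-sided p-value enumerates the permutation distribution
## of the rank sum with a generating-function recursion (counts of subsets of
## each size attaining each rank sum), conditioning on the observed tie
## pattern; for larger samples a tie-corrected normal approximation with
## continuity correction is used.

#' Summarize one group's values for a metric
#'
#' @param values Non-empty numeric vector of finite values.
#' @param group_label Group name carried into the output.
#' @param metric_name Metric name carried into the output.
#' @return One-row data.frame: `group_label`, `metric_name`, `n`, `mean`,
#'   `min`, `max`.
#' @export
group_summary <- function(values, group_label, metric_name) {
  if (!length(values)) stop("group_summary: empty value list")
  if (!all(is.finite(values))) stop("group_summary: values must be finite")
  data.frame(group_label = group_label, metric_name = metric_name,
             n = length(values), mean = mean(values),
             min = min(values), max = max(values), stringsAsFactors = FALSE)
}

# exact permutation distribution of the doubled rank sum of sample 1:
# f[k+1, s+1] = number of n1-subsets of the pooled doubled midranks with sum s
.ranksum_distribution <- function(ranks2, n1) {
  total <- sum(ranks2)
  f <- matrix(0, nrow = n1 + 1L, ncol = total + 1L)
  f[1L, 1L] <- 1
  for (r in ranks2) {
    kmax <- n1
    # iterate k downward so each rank is used at most once
    for (k in seq(from = min(kmax, n1), to = 1L)) {
      cols <- seq_len(total + 1L - r)
      f[k + 1L, cols + r] <- f[k + 1L, cols + r] + f[k, cols]
    }
  }
  f[n1 + 1L, ]
}

#' Mann-Whitney U test for two independent samples
#'
#' Computes `U` for the first sample from rank sums with midranks, and a
#' two-sided p-value either by exact enumeration of all group-label
#' arrangements (conditional on ties) or by a tie-corrected normal
#' approximation with continuity correction. In `"auto"` mode (default) the
#' exact computation is used when `n1 + n2 <= 16`.
#'
#' When every pooled value is identical the test is degenerate: `p = 1` is
#' returned with a warning.
#'
#' @param x,y Non-empty numeric samples.
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @return An object of class `mwu_result`: list with `U`, `n1`, `n2`,
#'   `p_two_sided`, `method` (`"exact_enumeration"` or `"normal_approx"`),
#'   `tie_corrected` (logical).
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))   # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (!all(is.finite(c(x, y)))) stop("samples must be finite")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  rk <- rank(pooled)                       # midranks for ties
  has_ties <- anyDuplicated(pooled) > 0L
  r1 <- sum(rk[seq_len(n1)])
  u <- r1 - n1 * (n1 + 1) / 2

  degenerate <- length(unique(pooled)) == 1L
  if (degenerate) {
    warning("degenerate data: all pooled values identical; p = 1")
    return(structure(list(U = u, n1 = n1, n2 = n2, p_two_sided = 1,
                          method = "degenerate", tie_corrected = has_ties),
                     class = "mwu_result"))
  }

  use_exact <- mode == "exact" || (mode == "auto" && n <= 16L)
  if (use_exact) {
    ranks2 <- as.integer(round(2 * rk))    # midranks are multiples of 1/2
    dist <- .ranksum_distribution(ranks2, n1)
    total_arrangements <- choose(n, n1)
    s_obs <- as.integer(round(2 * r1))
    sums <- seq_along(dist) - 1L
    p_le <- sum(dist[sums <= s_obs]) / total_arrangements
    p_ge <- sum(dist[sums >= s_obs]) / total_arrangements
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact_enumeration"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    sigma <- sqrt(sigma2)
    dev <- u - mu
    z <- if (abs(dev) < 0.5) 0 else (abs(dev) - 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(-z))
    method <- "normal_approx"
  }
  structure(list(U = u, n1 = n1, n2 = n2, p_two_sided = p,
                 method = method, tie_corrected = has_ties),
            class = "mwu_result")
}

#' @export
print.mwu_result <- function(x, ...) {
  cat("Mann-Whitney U test (two-sided)\n")
  cat(sprintf("  U = %g, n1 = %d, n2 = %d\n", x$U, x$n1, x$n2))
  cat(sprintf("  p = %.4g  [%s%s]\n", x$p_two_sided, x$method,
              if (x$tie_corrected) ", ties present" else ""))
  invisible(x)
}

#' Re-test group separation below a diameter-ratio threshold
#'
#' Restricts both groups to vessels whose diameter ratio is strictly below
#' `threshold` and runs [mann_whitney_u()] on the restricted diameter ratios.
#' This probes whether the traditional criterion can distinguish the classes
#' among the small vessels where their ranges overlap.
#'
#' @param records_g1,records_g2 Morphometry data.frames (or vectors of
#'   diameter ratios) for the two groups.
#' @param threshold Restriction threshold; default
#'   [DIAMETER_RATIO_SUBGROUP_THRESHOLD].
#' @param mode Passed to [mann_whitney_u()].
#' @return An `mwu_result` with attributes `n1_below` and `n2_below`.
#' @export
below_threshold_retest <- function(records_g1, records_g2,
                                   threshold = DIAMETER_RATIO_SUBGROUP_THRESHOLD,
                                   mode = "auto") {
  pull <- function(r) if (is.data.frame(r)) r$diameter_ratio else as.numeric(r)
  d1 <- pull(records_g1); d2 <- pull(records_g2)
  d1 <- d1[is.finite(d1) & d1 < threshold]
  d2 <- d2[is.finite(d2) & d2 < threshold]
  if (!length(d1)) {
    stop("below_threshold_retest: group 1 has no vessels with diameter ratio below ",
         threshold)
  }
  if (!length(d2)) {
    stop("below_threshold_retest: group 2 has no vessels with diameter ratio below ",
         threshold)
  }
  res <- mann_whitney_u(d1, d2, mode = mode)
  attr(res, "n1_below") <- length(d1)
  attr(res, "n2_below") <- length(d2)
  res
}
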