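# Shared statistics: the size-matched Wilcoxon comparison and bootstrap
# confidence intervals for medians.

#' Wilcoxon rank-sum test (exact for small groups)
#'
#' Two-sided Mann-Whitney rank-sum test. For group sizes of at most
#' `exact_max` without ties the null distribution is enumerated exactly over
#' all assignments; otherwise the normal approximation with tie correction
#' (no continuity correction) is used.
#'
#' @param x,y Numeric samples.
#' @param exact_max Largest group size for exact enumeration (default 8).
#' @return List: `statistic` (rank-sum W of `x`, Mann-Whitney U form),
#'   `p`, `method`.
#' @export
rank_sum_test <- function(x, y, exact_max = 8) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2   # Mann-Whitney U
  has_ties <- any(duplicated(c(x, y)))
  if (n1 <= exact_max && n2 <= exact_max && !has_ties) {
    cmb <- utils::combn(n1 + n2, n1)
    rall <- rank(c(x, y))
    ws <- colSums(matrix(rall[cmb], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(ws <= w), mean(ws >= w)))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 *
      ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
    z <- (w - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(statistic = w, p = p, method = method)
}

#' Size-matched Wilcoxon comparison
#'
#' When the control group is larger than the test group, the control is
#' reduced to the `length(test)` members with fold-change closest to 1
#' (smallest `|log2 fc|`, ties broken by id) before the rank-sum test, so the
#' p-value is not inflated by sample size. A smaller control is used as is.
#'
#' @param test Named numeric vector (the tested values, e.g. d3'UTR ratios of
#'   sensitive genes).
#' @param control Named numeric vector of control values.
#' @param control_fc Named fold-changes of the control candidates (same names
#'   as `control`).
#' @return List: `test`, `control` (the matched subset), `statistic`, `p`,
#'   `method`, `matched_ids`.
#' @export
size_matched_wilcoxon <- function(test, control, control_fc) {
  if (length(control) > length(test)) {
    stopifnot(all(names(control) %in% names(control_fc)))
    fc <- control_fc[names(control)]
    ord <- order(abs(log2(fc)), names(control), method = "radix")
    keep <- names(control)[ord][seq_along(test)]
    control <- control[keep]
  }
  ht <- rank_sum_test(test, control)
  list(test = test, control = control, statistic = ht$statistic, p = ht$p,
       method = ht$method, matched_ids = names(control))
}

#' Percentile bootstrap confidence interval of the median
#'
#' @param values Numeric vector.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Optional integer seed.
#' @param conf Confidence level (default 0.95).
#' @return List: `median`, `lo`, `hi` (both `NA` when `length(values) < 5`),
#'   `n`.
#' @export
bootstrap_median_ci <- function(values, n_boot = 2000, seed = NULL,
                                conf = 0.95) {
  values <- values[!is.na(values)]
  med <- stats::median(values)
  if (length(values) < 5)
    return(list(median = med, lo = NA_real_, hi = NA_real_,
                n = length(values)))
  if (!is.null(seed)) set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i)
    stats::median(sample(values, length(values), replace = TRUE)),
    numeric(1))
  alpha <- (1 - conf) / 2
  qs <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE)
  list(median = med, lo = qs[1], hi = qs[2], n = length(values))
}
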