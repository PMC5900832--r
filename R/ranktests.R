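#' Mann-Whitney test with Hodges-Lehmann shift estimate
#'
#' Reports both U conventions (`u_min`, `u_max`, which sum to `n1 * n2`)
#' and the rank-sum statistic `ranksum_w` (sum of the pooled ranks of
#' `x`), since published reports sometimes print the rank sum under the
#' name U. The p value is exact when `n1 * n2 <= 64` and the data are
#' tie-free, otherwise a tie-corrected normal approximation with
#' continuity correction. The Hodges-Lehmann shift is the median of all
#' `n1 * n2` pairwise differences `y - x`, with an order-statistic
#' (Moses-type) confidence interval at nominal 95%.
#'
#' @param x,y Numeric samples (both non-empty).
#' @param conf_level Nominal confidence level for the shift CI.
#' @return One-row tibble: `u_min`, `u_max`, `ranksum_w`, `p_value`,
#'   `hl_shift`, `conf_low`, `conf_high`, `n1`, `n2`, `method`.
#' @export
mann_whitney_hl <- function(x, y, conf_level = 0.95) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) stop("missing values", call. = FALSE)
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_x <- sum(r[seq_len(n1)])
  u_x <- w_x - n1 * (n1 + 1) / 2   # pairs with x > y (ties half)
  u_y <- n1 * n2 - u_x
  ties <- anyDuplicated(pooled) > 0
  exact <- (n1 * n2 <= 64) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(y, x, exact = exact, correct = TRUE,
                       conf.int = TRUE, conf.level = conf_level)
  )
  diffs <- as.vector(outer(y, x, "-"))
  tibble::tibble(
    u_min = min(u_x, u_y), u_max = max(u_x, u_y), ranksum_w = w_x,
    p_value = wt$p.value,
    hl_shift = median(diffs),
    conf_low = wt$conf.int[1], conf_high = wt$conf.int[2],
    n1 = n1, n2 = n2,
    method = if (exact) "exact" else "normal approximation (tie-corrected)"
  )
}

#' Lilliefors-style normality check
#'
#' One-sample Kolmogorov-Smirnov statistic against a normal distribution
#' with the sample mean and SD, with the p value obtained by Monte Carlo
#' simulation of the same statistic under normality (the parameter
#' estimation makes the textbook KS p anti-conservative, so it is
#' simulated instead).
#'
#' @param x Numeric sample (n >= 5, non-constant).
#' @param n_sim Monte Carlo replicates for the p value (default 1999).
#' @param alpha Rejection threshold for the `reject` flag.
#' @return One-row tibble: `statistic`, `p_value`, `reject`, `n`.
#' @export
ks_normality <- function(x, n_sim = 1999, alpha = 0.05) {
  stopifnot(is.numeric(x))
  if (anyNA(x)) stop("missing values", call. = FALSE)
  n <- length(x)
  if (n < 5) stop("need n >= 5", call. = FALSE)
  if (sd(x) < 1e-12) stop("constant input", call. = FALSE)
  d <- lilliefors_stat(x)
  d_sim <- vapply(seq_len(n_sim), function(b) lilliefors_stat(rnorm(n)),
                  numeric(1))
  p <- (1 + sum(d_sim >= d)) / (1 + n_sim)
  tibble::tibble(statistic = d, p_value = p, reject = p < alpha, n = n)
}

# sup |ECDF - fitted normal CDF|, evaluated at the jump points
lilliefors_stat <- function(x) {
  n <- length(x)
  u <- pnorm(sort(x), mean(x), sd(x))
  i <- seq_len(n)
  max(i / n - u, u - (i - 1) / n)
}
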