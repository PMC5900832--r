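#' Spearman correlation with confidence interval
#'
#' Rank correlation on average-tie ranks, p value from the t
#' approximation, and a confidence interval from the Fisher z transform
#' (`1.96/sqrt(n - 3)` half-width on the z scale) or, optionally, a
#' percentile bootstrap.
#'
#' @param x,y Numeric vectors (n >= 4).
#' @param ci `"fisher"` (default) or `"bootstrap"`.
#' @param n_boot Bootstrap resamples when `ci = "bootstrap"`.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `rho`, `p_value`, `conf_low`, `conf_high`, `n`,
#'   `kind`.
#' @export
spearman_ci <- function(x, y, ci = c("fisher", "bootstrap"),
                        n_boot = 2000, conf_level = 0.95) {
  ci <- match.arg(ci)
  check_corr_input(x, y, min_n = 4)
  n <- length(x)
  rho <- cor(rank(x), rank(y))
  out <- tibble::tibble(
    rho = rho, p_value = spearman_p(rho, n),
    conf_low = NA_real_, conf_high = NA_real_, n = n, kind = "spearman"
  )
  if (ci == "fisher") {
    half <- qnorm(1 - (1 - conf_level) / 2) / sqrt(n - 3)
    out$conf_low <- tanh(atanh(clamp_r(rho)) - half)
    out$conf_high <- tanh(atanh(clamp_r(rho)) + half)
  } else {
    boots <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      if (sd(x[idx]) < 1e-12 || sd(y[idx]) < 1e-12) return(NA_real_)
      cor(rank(x[idx]), rank(y[idx]))
    }, numeric(1))
    qs <- stats::quantile(boots, c((1 - conf_level) / 2,
                                   1 - (1 - conf_level) / 2), na.rm = TRUE)
    out$conf_low <- unname(qs[1])
    out$conf_high <- unname(qs[2])
  }
  out
}

#' Partial Spearman correlation controlling for one covariate
#'
#' Correlation of the rank residuals of `x` and `y` after regressing each
#' on the ranked covariate; p from the t approximation on n - 3 degrees of
#' freedom, CI by Fisher z with `sqrt(n - 4)`.
#'
#' @param x,y Numeric vectors (n >= 5).
#' @param covariate Numeric covariate to partial out.
#' @param conf_level Confidence level.
#' @return One-row tibble as in [spearman_ci()], `kind =
#'   "partial_spearman"`.
#' @export
partial_spearman <- function(x, y, covariate, conf_level = 0.95) {
  check_corr_input(x, y, min_n = 5)
  stopifnot(length(covariate) == length(x))
  if (sd(covariate) < 1e-12) stop("constant covariate", call. = FALSE)
  n <- length(x)
  rz <- rank(covariate)
  ex <- stats::resid(stats::lm(rank(x) ~ rz))
  ey <- stats::resid(stats::lm(rank(y) ~ rz))
  rho <- cor(ex, ey)
  tstat <- rho * sqrt((n - 3) / (1 - rho^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 3)
  half <- qnorm(1 - (1 - conf_level) / 2) / sqrt(n - 4)
  tibble::tibble(
    rho = rho, p_value = p,
    conf_low = tanh(atanh(clamp_r(rho)) - half),
    conf_high = tanh(atanh(clamp_r(rho)) + half),
    n = n, kind = "partial_spearman"
  )
}

#' Steiger z test for two dependent correlations sharing one variable
#'
#' Compares the magnitudes `|r_xy|` versus `|r_xz|` (the correlations of
#' two predictors with a shared variable x), accounting for the
#' predictor-predictor correlation `r_yz` (Steiger's Z1* with the average
#' correlation). Signs are absorbed by reflecting y and z to make both
#' focal correlations positive, which also reflects `r_yz` accordingly.
#'
#' @param r_xy,r_xz,r_yz Sample correlations, all in (-1, 1), forming a
#'   positive semi-definite 3x3 correlation matrix.
#' @param n Sample size (>= 4).
#' @return One-row tibble with `z` and two-tailed `p_value`.
#' @export
steiger_z <- function(r_xy, r_xz, r_yz, n) {
  stopifnot(n >= 4)
  if (any(abs(c(r_xy, r_xz, r_yz)) >= 1)) {
    stop("correlations must lie strictly inside (-1, 1)", call. = FALSE)
  }
  R <- matrix(c(1, r_xy, r_xz,
                r_xy, 1, r_yz,
                r_xz, r_yz, 1), 3, 3)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
    stop("implied correlation matrix is not positive semi-definite",
         call. = FALSE)
  }
  sy <- ifelse(r_xy < 0, -1, 1)
  sz <- ifelse(r_xz < 0, -1, 1)
  a <- abs(r_xy)
  b <- abs(r_xz)
  ryz <- r_yz * sy * sz
  z1 <- atanh(a)
  z2 <- atanh(b)
  rbar <- (a + b) / 2
  cov_term <- (ryz * (1 - 2 * rbar^2) -
                 0.5 * rbar^2 * (1 - 2 * rbar^2 - ryz^2)) / (1 - rbar^2)^2
  z <- (z1 - z2) * sqrt(n - 3) / sqrt(2 - 2 * cov_term)
  tibble::tibble(z = z, p_value = 2 * pnorm(-abs(z)))
}

spearman_p <- function(rho, n) {
  if (abs(rho) >= 1) return(0)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

clamp_r <- function(r) pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)

check_corr_input <- function(x, y, min_n) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (anyNA(x) || anyNA(y)) stop("missing values", call. = FALSE)
  if (length(x) < min_n) stop("need n >= ", min_n, call. = FALSE)
  if (sd(x) < 1e-12 || sd(y) < 1e-12) {
    stop("constant input: correlation undefined", call. = FALSE)
  }
  invisible(TRUE)
}
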