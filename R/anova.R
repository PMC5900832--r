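#' Mixed-design (repeated-measures) ANOVA with generalized eta-squared
#'
#' Univariate mixed-design ANOVA for a balanced within-subject factor, one
#' between-subject factor and up to one continuous covariate. Sums of
#' squares are Type III with sum-to-zero contrasts and a centered
#' covariate; degrees of freedom are the uncorrected (sphericity-unadjusted)
#' ones, e.g. a 171-level within factor with 2 groups of 40 subjects gives
#' the within effect df (170, 6460), and adding a covariate to a 6-level
#' design gives (5, 185). Generalized eta-squared treats every factor as
#' manipulated except the covariate, which is observed.
#'
#' @param data Long-format data frame.
#' @param value,subject,within,between Column names (unquoted or strings)
#'   of the response, subject id, within-factor level and group.
#' @param covariate Optional column name of a continuous covariate.
#' @param sphericity Also report Greenhouse-Geisser corrected p values
#'   (default `FALSE`; uncorrected dfs are always the primary output).
#' @return An `hd_anova` object; `tidy()` gives one row per effect with
#'   `df_num`, `df_den`, `statistic`, `p_value`, `ges`.
#' @export
rm_anova <- function(data, value, subject, within, between,
                     covariate = NULL, sphericity = FALSE) {
  value <- as_colname(rlang::enexpr(value))
  subject <- as_colname(rlang::enexpr(subject))
  within <- as_colname(rlang::enexpr(within))
  between <- as_colname(rlang::enexpr(between))
  covariate <- rlang::enexpr(covariate)
  covariate <- if (is.null(covariate)) NULL else as_colname(covariate)
  stopifnot(all(c(value, subject, within, between) %in% names(data)))

  df <- data.frame(
    y = as.numeric(data[[value]]),
    s = factor(data[[subject]]),
    w = factor(data[[within]]),
    g = factor(data[[between]])
  )
  if (!is.null(covariate)) df$x <- as.numeric(data[[covariate]])
  if (anyNA(df)) stop("missing values in the ANOVA table", call. = FALSE)

  counts <- table(df$s, df$w)
  if (any(counts != 1)) {
    bad <- rownames(counts)[rowSums(counts != 1) > 0]
    stop("unbalanced within-design; offending subject(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sub_rows <- !duplicated(df$s)
  sub <- df[sub_rows, , drop = FALSE]
  if (any(tapply(as.character(df$g), df$s,
                 function(v) length(unique(v))) != 1)) {
    stop("each subject must belong to exactly one group", call. = FALSE)
  }
  if (!is.null(covariate)) {
    if (any(tapply(df$x, df$s, function(v) length(unique(v))) != 1)) {
      stop("covariate must be constant within subject", call. = FALSE)
    }
    if (sd(sub$x) < 1e-12) stop("covariate is constant", call. = FALSE)
  }

  wl <- levels(df$w)
  ord <- order(df$s, df$w)
  Y <- matrix(df$y[ord], nrow = nlevels(df$s), ncol = length(wl),
              byrow = TRUE,
              dimnames = list(levels(df$s), wl))
  sub <- sub[order(sub$s), , drop = FALSE]

  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  if (is.null(covariate)) {
    mlm <- stats::lm(Y ~ g, data = sub)
  } else {
    sub$x_c <- sub$x - mean(sub$x)
    mlm <- stats::lm(Y ~ g + x_c, data = sub)
  }
  idata <- data.frame(w = factor(wl, levels = wl))
  av <- car::Anova(mlm, idata = idata, idesign = ~w, type = 3)
  # with more within levels than subjects the error SSP is singular and
  # sphericity corrections are unavailable; the univariate table is fine
  s <- withCallingHandlers(
    summary(av, multivariate = FALSE),
    warning = function(w) {
      if (grepl("non-sphericity|HF eps", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  ut <- s$univariate.tests

  rn <- rownames(ut)
  pretty <- function(r) {
    r <- gsub("\\bg\\b", between, r)
    r <- gsub("\\bw\\b", within, r)
    gsub("\\bx_c\\b", covariate %||% "", r)
  }
  eff_rows <- setdiff(rn, "(Intercept)")
  ss <- ut[, "Sum Sq"]
  err_between <- ut["g", "Error SS"]
  w_row <- rn[rn == "w"]
  err_within <- ut[w_row, "Error SS"]
  measured <- if (is.null(covariate)) character(0) else c("x_c", "x_c:w")
  ss_meas <- sum(ss[intersect(measured, rn)])
  ges <- vapply(eff_rows, function(r) {
    delta <- if (r %in% measured) 0 else 1
    unname(ss[r] / (delta * ss[r] + ss_meas + err_between + err_within))
  }, numeric(1))

  effects <- tibble::tibble(
    effect = pretty(eff_rows),
    df_num = as.integer(ut[eff_rows, "num Df"]),
    df_den = as.integer(ut[eff_rows, "den Df"]),
    sum_sq = unname(ss[eff_rows]),
    statistic = unname(ut[eff_rows, "F value"]),
    p_value = unname(ut[eff_rows, "Pr(>F)"]),
    ges = unname(ges)
  )
  gg <- NULL
  if (sphericity && !is.null(s$pval.adjustments) &&
      nrow(s$pval.adjustments) > 0) {
    pa <- s$pval.adjustments
    gg <- tibble::tibble(effect = pretty(rownames(pa)),
                         gg_epsilon = unname(pa[, "GG eps"]),
                         p_gg = unname(pa[, "Pr(>F[GG])"]))
  }
  design <- sprintf(
    "within: %s (%d levels); between: %s (%d groups); %s; n = %d subjects",
    within, length(wl), between, nlevels(sub$g),
    if (is.null(covariate)) "no covariate" else paste("covariate:", covariate),
    nrow(sub))
  new_hd_anova(effects, design, type = "mixed", gg = gg)
}

#' One-way ANOVA with eta-squared
#'
#' @param data Data frame.
#' @param value,group Column names of the response and the grouping factor.
#' @return An `hd_anova` with the group effect and classical eta-squared.
#' @export
oneway_anova <- function(data, value, group) {
  value <- as_colname(rlang::enexpr(value))
  group <- as_colname(rlang::enexpr(group))
  y <- as.numeric(data[[value]])
  g <- factor(data[[group]])
  if (anyNA(y) || anyNA(g)) stop("missing values", call. = FALSE)
  if (nlevels(g) < 2 || any(table(g) < 2)) {
    stop("need >= 2 groups with >= 2 values each", call. = FALSE)
  }
  fit <- stats::aov(y ~ g)
  sm <- summary(fit)[[1]]
  ss_g <- sm["g", "Sum Sq"]
  ss_e <- sm["Residuals", "Sum Sq"]
  effects <- tibble::tibble(
    effect = group,
    df_num = as.integer(sm["g", "Df"]),
    df_den = as.integer(sm["Residuals", "Df"]),
    sum_sq = ss_g,
    statistic = sm["g", "F value"],
    p_value = sm["g", "Pr(>F)"],
    ges = ss_g / (ss_g + ss_e)
  )
  design <- sprintf("one-way: %s (%d groups); n = %d", group, nlevels(g),
                    length(y))
  new_hd_anova(effects, design, type = "oneway")
}

#' Tukey honestly-significant-difference post-hocs
#'
#' All pairwise group comparisons with studentized-range adjusted p values
#' and simultaneous 95% confidence intervals.
#'
#' @inheritParams oneway_anova
#' @param conf_level Simultaneous confidence level (default 0.95).
#' @return Tibble with `group_a`, `group_b`, `estimate` (mean of `group_a`
#'   minus mean of `group_b`), `conf_low`, `conf_high`, `p_adj`.
#' @export
tukey_hsd <- function(data, value, group, conf_level = 0.95) {
  value <- as_colname(rlang::enexpr(value))
  group <- as_colname(rlang::enexpr(group))
  y <- as.numeric(data[[value]])
  g <- factor(data[[group]])
  if (nlevels(g) < 2 || any(table(g) < 2)) {
    stop("need >= 2 groups with >= 2 values each", call. = FALSE)
  }
  fit <- stats::aov(y ~ g)
  tk <- stats::TukeyHSD(fit, conf.level = conf_level)$g
  cmp <- strsplit(rownames(tk), "-", fixed = TRUE)
  tibble::tibble(
    group_a = vapply(cmp, `[`, character(1), 1),
    group_b = vapply(cmp, `[`, character(1), 2),
    estimate = unname(tk[, "diff"]),
    conf_low = unname(tk[, "lwr"]),
    conf_high = unname(tk[, "upr"]),
    p_adj = unname(tk[, "p adj"])
  )
}

new_hd_anova <- function(effects, design, type, gg = NULL) {
  structure(list(effects = effects, design = design, type = type, gg = gg),
            class = "hd_anova")
}

#' @export
print.hd_anova <- function(x, ...) {
  cat("ANOVA (", x$type, "): ", x$design, "\n", sep = "")
  print(as.data.frame(x$effects), digits = 4)
  if (!is.null(x$gg)) {
    cat("Greenhouse-Geisser adjustments:\n")
    print(as.data.frame(x$gg), digits = 4)
  }
  invisible(x)
}

#' @export
tidy.hd_anova <- function(x, ...) x$effects

#' @export
glance.hd_anova <- function(x, ...) {
  tibble::tibble(type = x$type, design = x$design,
                 n_effects = nrow(x$effects))
}

as_colname <- function(expr) {
  if (is.character(expr)) return(expr)
  rlang::as_name(expr)
}
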