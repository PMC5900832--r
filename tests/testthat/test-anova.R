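make_rm_table <- function(n_subj, n_levels, n_groups, covariate = FALSE,
                          seed = 1, group_shift = 0) {
  withr::with_seed(seed, {
    subj <- paste0("s", sprintf("%03d", seq_len(n_subj)))
    grp <- rep(paste0("g", seq_len(n_groups)), length.out = n_subj)
    age <- rnorm(n_subj, 45, 10)
    df <- tidyr::expand_grid(subject = subj, level = paste0("w", seq_len(n_levels)))
    df$group <- grp[match(df$subject, subj)]
    df$age <- age[match(df$subject, subj)]
    lvl_eff <- rnorm(n_levels)
    df$value <- lvl_eff[match(df$level, paste0("w", seq_len(n_levels)))] +
      group_shift * (df$group == "g2") + rnorm(nrow(df))
    df
  })
}

test_that("mixed ANOVA reproduces the classical df accounting", {
  # 171 within levels, 2 groups, 40 subjects -> (170, 6460)
  d1 <- make_rm_table(40, 171, 2, seed = 2)
  a1 <- tidy(rm_anova(d1, value, subject, level, group))
  w1 <- a1[a1$effect == "level", ]
  expect_equal(c(w1$df_num, w1$df_den), c(170, 6460))
  # 6 levels, 2 groups, covariate -> (5, 185)
  d2 <- make_rm_table(40, 6, 2, seed = 3)
  a2 <- tidy(rm_anova(d2, value, subject, level, group, covariate = age))
  w2 <- a2[a2$effect == "level", ]
  expect_equal(c(w2$df_num, w2$df_den), c(5, 185))
  # interaction df over a small grid
  for (par in list(c(12, 4, 2), c(15, 5, 3), c(12, 3, 2))) {
    d <- make_rm_table(par[1], par[2], par[3], seed = sum(par))
    a <- tidy(rm_anova(d, value, subject, level, group, covariate = age))
    W <- par[2]; G <- par[3]; n <- par[1]
    ia <- a[a$effect == "group:level", ]
    expect_equal(ia$df_num, (W - 1) * (G - 1))
    expect_equal(ia$df_den, (W - 1) * (n - G - 1))
  }
})

test_that("identical groups give a null group effect", {
  d <- make_rm_table(20, 5, 2, seed = 4)
  # make the two groups exact copies of each other
  ref <- d$value[d$group == "g1"]
  d$value[d$group == "g2"] <- ref
  a <- tidy(rm_anova(d, value, subject, level, group))
  expect_lt(a$statistic[a$effect == "group"], 1e-20)
})

test_that("mixed ANOVA matches a hand sums-of-squares oracle", {
  # 4 subjects (2 per group) x 3 levels, solved by direct decomposition
  df <- tidyr::expand_grid(subject = c("a", "b", "c", "d"),
                           level = c("w1", "w2", "w3"))
  df$group <- ifelse(df$subject %in% c("a", "b"), "g1", "g2")
  df$value <- c(1, 2, 4,   2, 4, 5,   3, 5, 9,   4, 6, 8)
  Y <- matrix(df$value, 4, 3, byrow = TRUE)
  grand <- mean(Y)
  subj_m <- rowMeans(Y)
  grp_m <- c(rep(mean(subj_m[1:2]), 2), rep(mean(subj_m[3:4]), 2))
  W <- 3
  ss_group <- W * sum((grp_m - grand)^2)
  ss_err_b <- W * sum((subj_m - grp_m)^2)
  lvl_m <- colMeans(Y)
  ss_level <- 4 * sum((lvl_m - grand)^2)
  cell_m <- rbind(colMeans(Y[1:2, ]), colMeans(Y[3:4, ]))
  ss_inter <- 2 * sum((cell_m - outer(c(mean(subj_m[1:2]), mean(subj_m[3:4])),
                                      lvl_m - grand, "+"))^2)
  ss_total_w <- sum((Y - subj_m)^2)
  ss_err_w <- ss_total_w - ss_level - ss_inter
  f_level <- (ss_level / 2) / (ss_err_w / 4)
  f_group <- ss_group / (ss_err_b / 2)
  ges_level <- ss_level / (ss_level + ss_err_b + ss_err_w)

  a <- tidy(rm_anova(df, value, subject, level, group))
  expect_equal(a$statistic[a$effect == "level"], f_level, tolerance = 1e-10)
  expect_equal(a$statistic[a$effect == "group"], f_group, tolerance = 1e-10)
  expect_equal(a$ges[a$effect == "level"], ges_level, tolerance = 1e-10)
  expect_equal(a$df_den[a$effect == "level"], 4)
})

test_that("generalized eta squared is invariant to affine response rescaling", {
  d <- make_rm_table(16, 4, 2, seed = 5, group_shift = 0.6)
  a1 <- tidy(rm_anova(d, value, subject, level, group))
  d$value <- 3.7 * d$value - 11
  a2 <- tidy(rm_anova(d, value, subject, level, group))
  expect_equal(a1$ges, a2$ges, tolerance = 1e-10)
  expect_equal(a1$statistic, a2$statistic, tolerance = 1e-10)
  expect_true(all(a1$ges >= 0 & a1$ges <= 1))
})

test_that("mixed ANOVA rejects malformed tables", {
  d <- make_rm_table(10, 3, 2, seed = 6)
  expect_error(rm_anova(d[-1, ], value, subject, level, group),
               "unbalanced")
  d2 <- make_rm_table(10, 3, 2, seed = 7)
  d2$age <- 50
  expect_error(rm_anova(d2, value, subject, level, group, covariate = age),
               "constant")
})

test_that("one-way ANOVA reports classical df and eta squared", {
  withr::local_seed(8)
  df <- data.frame(
    g = rep(c("control", "near", "far"), times = c(21, 10, 9)),
    y = rnorm(40))
  a <- tidy(oneway_anova(df, y, g))
  expect_equal(c(a$df_num, a$df_den), c(2, 37))
  # equal values across groups -> F = 0
  df0 <- data.frame(g = rep(c("a", "b"), each = 4), y = rep(c(1, 2, 3, 4), 2))
  a0 <- tidy(oneway_anova(df0, y, g))
  expect_equal(a0$statistic, 0)
  # oracle check of F and eta^2 on a tiny table
  df1 <- data.frame(g = rep(c("a", "b"), each = 3),
                    y = c(1, 2, 3, 4, 6, 8))
  m <- tapply(df1$y, df1$g, mean)
  ssb <- 3 * sum((m - mean(df1$y))^2)
  ssw <- sum((df1$y - m[df1$g])^2)
  a1 <- tidy(oneway_anova(df1, y, g))
  expect_equal(a1$statistic, (ssb / 1) / (ssw / 4), tolerance = 1e-12)
  expect_equal(a1$ges, ssb / (ssb + ssw), tolerance = 1e-12)
})

test_that("Tukey HSD matches the studentized-range oracle", {
  withr::local_seed(9)
  df <- data.frame(g = rep(c("a", "b", "c"), each = 8),
                   y = rnorm(24) + rep(c(0, 0.8, 1.6), each = 8))
  tk <- tukey_hsd(df, y, g)
  fit <- aov(y ~ g, df)
  mse <- summary(fit)[[1]]["Residuals", "Mean Sq"]
  m <- tapply(df$y, df$g, mean)
  q_ba <- as.numeric(abs(m["b"] - m["a"])) / sqrt(mse / 8)
  p_oracle <- ptukey(q_ba, nmeans = 3, df = 21, lower.tail = FALSE)
  row <- tk[tk$group_a == "b" & tk$group_b == "a", ]
  expect_equal(row$p_adj, p_oracle, tolerance = 1e-10)
  expect_true(all(tk$conf_low <= tk$estimate & tk$estimate <= tk$conf_high))
})

test_that("Tukey p values behave sensibly", {
  withr::local_seed(10)
  base <- rnorm(10)
  df_same <- data.frame(g = rep(c("a", "b"), each = 10), y = c(base, base))
  tk0 <- tukey_hsd(df_same, y, g)
  expect_gt(tk0$p_adj, 0.999)
  expect_true(tk0$conf_low < 0 && tk0$conf_high > 0)
  # adjusted p is never smaller than the unadjusted pairwise t p
  df <- data.frame(g = rep(c("a", "b", "c"), each = 6),
                   y = rnorm(18) + rep(c(0, 0.5, 2), each = 6))
  tk <- tukey_hsd(df, y, g)
  for (k in seq_len(nrow(tk))) {
    t_p <- t.test(df$y[df$g == tk$group_a[k]],
                  df$y[df$g == tk$group_b[k]], var.equal = TRUE)$p.value
    expect_gte(tk$p_adj[k] + 1e-12, t_p * 0.999)
  }
})
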