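test_that("rank-based inverse normal transform gives Blom scores", {
  expect_equal(rank_inverse_normal(c(1, 5, 9)),
               c(-0.8694237733, 0, 0.8694237733), tolerance = 1e-8)
  # middle value of an odd-length tie-free vector maps to zero
  withr::local_seed(1)
  x <- rnorm(11)
  sc <- rank_inverse_normal(x)
  expect_equal(sc[which(rank(x) == 6)], 0)
  # strictly monotone, ties share scores
  expect_true(all(diff(sc[order(x)]) > 0))
  xt <- c(1, 2, 2, 3)
  st <- rank_inverse_normal(xt)
  expect_equal(st[2], st[3])
  expect_error(rank_inverse_normal(rep(1, 5)), "distinct")
})

test_that("inverse-normal output looks normal for uniform input", {
  withr::local_seed(2)
  sc <- rank_inverse_normal(runif(500))
  res <- ks_normality(sc, n_sim = 499)
  expect_false(res$reject)
})

test_that("residualization removes covariates exactly on the fit population", {
  withr::local_seed(3)
  n <- 40
  X <- noise_features(n, 6, seed = 3)
  cov <- toy_covariates(n, n_sites = 2, seed = 4)
  X[, 1] <- X[, 1] + 0.05 * cov$age
  pm <- fit_preprocess(X, cov)
  Xr <- apply_preprocess(pm, X, cov, rin = FALSE)
  expect_lt(max(abs(cor(Xr, cov$age))), 1e-8)
  expect_lt(max(abs(colMeans(Xr))), 1e-10)
  site_dummy <- as.numeric(cov$site == "site2")
  expect_lt(max(abs(cor(Xr, site_dummy))), 1e-8)
  # the full pipeline (with the monotone normal-score step) stays close
  Xfull <- apply_preprocess(pm, X, cov, rin = TRUE)
  expect_lt(max(abs(cor(Xfull, cov$age))), 0.25)
})

test_that("features orthogonal to the covariates pass through unchanged", {
  withr::local_seed(5)
  n <- 30
  cov <- toy_covariates(n, n_sites = 1, seed = 5)
  raw <- rnorm(n)
  Z <- cbind(1, cov$age)
  orth <- qr.resid(qr(Z), raw)
  orth <- (orth - mean(orth)) / sd(orth)
  X <- cbind(f1 = orth)
  pm <- fit_preprocess(X, cov)
  Xr <- apply_preprocess(pm, X, cov, rin = FALSE)
  expect_equal(unname(Xr[, 1]), unname(orth), tolerance = 1e-8)
})

test_that("fit-population subjects recover their exact Blom scores", {
  withr::local_seed(6)
  X <- noise_features(25, 4, seed = 6)
  pm <- fit_preprocess(X, NULL)
  Xp <- apply_preprocess(pm, X, NULL)
  for (j in 1:4) {
    expect_equal(unname(Xp[, j]),
                 unname(rank_inverse_normal(scale(X[, j])[, 1])),
                 tolerance = 1e-10)
  }
})

test_that("held-out subjects get interpolated, clamped normal scores", {
  X <- cbind(f1 = c(1, 2, 3, 4, 5))
  pm <- fit_preprocess(X, NULL)
  out <- apply_preprocess(pm, cbind(f1 = c(-100, 2.5, 100)), NULL)
  expect_equal(as.numeric(out[1, 1]), min(rank_inverse_normal(1:5))) # clamped
  expect_equal(as.numeric(out[3, 1]), max(rank_inverse_normal(1:5)))
  sc <- rank_inverse_normal(1:5)
  z <- scale(1:5)[, 1]
  mid <- approx(z, sc, xout = (2.5 - 3) / sd(1:5))$y
  expect_equal(as.numeric(out[2, 1]), mid, tolerance = 1e-10)
})

test_that("unseen sites and schema mismatches are refused", {
  X <- noise_features(20, 3, seed = 7)
  cov <- toy_covariates(20, n_sites = 2, seed = 7)
  pm <- fit_preprocess(X, cov)
  cov_new <- data.frame(age = 50, site = "siteZ")
  expect_error(apply_preprocess(pm, X[1, , drop = FALSE], cov_new),
               "unseen site")
  expect_error(apply_preprocess(pm, X[, 1:2, drop = FALSE], cov),
               "missing")
  expect_error(fit_preprocess(cbind(f1 = rep(1, 10)), NULL), "constant")
})

test_that("the C++ fold preprocessing matches the R reference exactly", {
  withr::local_seed(8)
  n <- 18
  X <- noise_features(n, 5, seed = 8)
  cov <- toy_covariates(n, n_sites = 2, seed = 9)
  Z <- hdpolymarker:::covariate_design(cov, levels(factor(cov$site)))
  for (hold in c(1, 7, n)) {
    cpp <- hdpolymarker:::cpp_preprocess_loo(X, Z, hold - 1, TRUE)
    tr <- setdiff(seq_len(n), hold)
    pm <- fit_preprocess(X[tr, ], cov[tr, ])
    r_train <- apply_preprocess(pm, X[tr, ], cov[tr, ])
    r_ho <- apply_preprocess(pm, X[hold, , drop = FALSE],
                             cov[hold, , drop = FALSE])
    expect_equal(unname(cpp$train), unname(r_train), tolerance = 1e-10)
    expect_equal(as.numeric(cpp$holdout), as.numeric(r_ho),
                 tolerance = 1e-10)
  }
})
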