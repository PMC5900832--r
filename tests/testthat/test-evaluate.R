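test_that("F1 handles the undefined-precision case as zero", {
  truth <- c("p", "p", "c", "c")
  all_neg <- rep("c", 4)
  expect_equal(f1_score(truth, all_neg, "p")$f1, 0)
  perfect <- f1_score(truth, truth, "p")
  expect_equal(perfect$f1, 1)
  mixed <- f1_score(truth, c("p", "c", "p", "c"), "p")
  expect_equal(mixed$sensitivity, 0.5)
  expect_equal(mixed$precision, 0.5)
  expect_equal(mixed$f1, 0.5)
  expect_equal(sum(mixed$confusion), 4)
})

test_that("leave-one-out recovers well-separated clusters", {
  X <- separated_features(n_per = 8, delta = 6, seed = 1)
  lab <- balanced_labels(16)
  rep1 <- loo_f1(X, lab)
  expect_equal(rep1$f1, 1)
  expect_equal(sum(rep1$confusion), 16)
  expect_equal(nrow(tidy(rep1)), 16)
  expect_equal(glance(rep1)$f1, 1)
})

test_that("both evaluation engines agree to numerical precision", {
  withr::local_seed(2)
  X <- noise_features(20, 6, seed = 2)
  lab <- balanced_labels(20)
  cov <- toy_covariates(20, n_sites = 2, seed = 3)
  for (pm in c(FALSE, TRUE)) {
    r_cpp <- loo_f1(X, lab, cov, engine = "cpp", paper_mode = pm)
    r_r <- loo_f1(X, lab, cov, engine = "r", paper_mode = pm)
    expect_equal(r_cpp$subjects$decision, r_r$subjects$decision,
                 tolerance = 1e-8)
    expect_equal(r_cpp$f1, r_r$f1)
  }
})

test_that("evaluation guards its preconditions", {
  X <- noise_features(8, 3, seed = 4)
  expect_error(loo_f1(X[1:5, ], balanced_labels(8)[1:5]), "n >= 6")
  lab_bad <- factor(c(rep("a", 6), "b", "b"))
  expect_error(loo_f1(X, lab_bad), "3 subjects")
  cov1 <- data.frame(age = rnorm(8), site = c("A", rep("B", 7)))
  expect_error(loo_f1(X, balanced_labels(8), cov1), "2 subjects")
  expect_error(permutation_test(X, balanced_labels(8), n_perm = 10),
               "at least 20")
  expect_warning(
    permutation_test(noise_features(8, 2, seed = 5), balanced_labels(8),
                     n_perm = 50, seed = 1),
    "coarse")
})

test_that("the add-one empirical p is exact when the observed F1 tops the null", {
  X <- separated_features(n_per = 10, delta = 6, seed = 6)
  lab <- balanced_labels(20)
  rep1 <- permutation_test(X, lab, n_perm = 199, seed = 7)
  expect_equal(rep1$f1, 1)
  expect_equal(rep1$p_value, 1 / 200)
  expect_equal(length(rep1$null_f1), 199)
  expect_true(all(rep1$null_f1 >= 0 & rep1$null_f1 <= 1))
})

test_that("permutation runs are deterministic given a seed", {
  X <- noise_features(16, 4, seed = 8)
  lab <- balanced_labels(16)
  r1 <- suppressWarnings(permutation_test(X, lab, n_perm = 99, seed = 11))
  r2 <- suppressWarnings(permutation_test(X, lab, n_perm = 99, seed = 11))
  expect_identical(r1$null_f1, r2$null_f1)
  expect_identical(r1$p_value, r2$p_value)
  r3 <- suppressWarnings(permutation_test(X, lab, n_perm = 99, seed = 12))
  expect_false(identical(r1$null_f1, r3$null_f1))
})

test_that("the null distribution of balanced noise centres near one half", {
  X <- noise_features(40, 10, seed = 9)
  lab <- balanced_labels(40)
  rep1 <- permutation_test(X, lab, n_perm = 199, seed = 13)
  expect_gt(mean(rep1$null_f1), 0.42)
  expect_lt(mean(rep1$null_f1), 0.58)
  expect_gt(rep1$p_value, 0.05) # noise should not classify
})

test_that("external validation detects a shared strong effect", {
  withr::local_seed(10)
  make <- function(seed) {
    X <- separated_features(n_per = 15, delta = 2.5, seed = seed)
    list(X = X, lab = balanced_labels(30))
  }
  tr <- make(14); te <- make(15)
  rep1 <- external_validate(tr$X, tr$lab, NULL, te$X, te$lab, NULL,
                            n_perm = 199, seed = 16)
  expect_gt(rep1$f1, 0.9)
  expect_lt(rep1$p_value, 0.05)
  # shuffled test labels stay inside the null
  lab_shuf <- withr::with_seed(17, sample(te$lab))
  rep0 <- external_validate(tr$X, tr$lab, NULL, te$X, lab_shuf, NULL,
                            n_perm = 199, seed = 18)
  expect_gt(rep0$p_value, 0.05)
})

test_that("site centering absorbs a wholesale test-cohort shift", {
  withr::local_seed(11)
  tr_X <- separated_features(n_per = 15, delta = 2.5, seed = 19)
  tr_lab <- balanced_labels(30)
  tr_cov <- toy_covariates(30, n_sites = 2, seed = 20)
  te_X <- separated_features(n_per = 12, delta = 2.5, seed = 21)
  te_lab <- balanced_labels(24)
  te_cov <- toy_covariates(24, n_sites = 1, seed = 22)
  te_cov$site <- "siteX"
  r_base <- external_validate(tr_X, tr_lab, tr_cov, te_X, te_lab, te_cov,
                              n_perm = 99, seed = 23)
  r_shift <- external_validate(tr_X, tr_lab, tr_cov, te_X + 5, te_lab,
                               te_cov, n_perm = 99, seed = 23)
  expect_lt(abs(r_base$f1 - r_shift$f1), 0.05)
})

test_that("schema mismatches across cohorts are refused", {
  tr_X <- separated_features(n_per = 5, seed = 24)
  te_X <- tr_X[, 1:2]
  expect_error(
    external_validate(tr_X, balanced_labels(10), NULL, te_X,
                      balanced_labels(10), NULL, n_perm = 99),
    "missing feature")
})
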