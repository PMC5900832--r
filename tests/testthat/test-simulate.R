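test_that("the same config and seed reproduce the bundle bit-exactly", {
  cfg <- small_cohort_config(seed = 21)
  b1 <- simulate_cohort(cfg)
  b2 <- simulate_cohort(cfg)
  expect_identical(b1$subjects, b2$subjects)
  expect_identical(b1$scv, b2$scv)
  expect_identical(b1$ct, b2$ct)
  expect_identical(b1$timecourses[[1]]$signals, b2$timecourses[[1]]$signals)
  b3 <- simulate_cohort(small_cohort_config(seed = 22))
  expect_false(identical(b1$scv, b3$scv))
})

test_that("subject records satisfy the genetic-clock invariants", {
  b <- simulate_cohort(sim_config(seed = 3, include_timecourses = FALSE))
  s <- b$subjects
  ctrl <- s$group == "control"
  expect_true(all(is.na(s$cag[ctrl])))
  expect_true(all(is.na(s$subgroup[ctrl])))
  expect_true(all(is.na(s$converted_within_followup[ctrl])))
  pre <- !ctrl
  expect_true(all(s$cag[pre] >= 36))
  expect_true(all(s$age > 0))
  expect_equal(s$dbs[pre], s$age[pre] * (s$cag[pre] - 35.5))
  expect_equal(sum(s$subgroup[pre] == "near"), 10)
  expect_equal(sum(s$subgroup[pre] == "far"), 9)
  expect_gte(sum(s$converted_within_followup[pre]), 3) # min_converters
})

test_that("simulated timecourses converge to the target coupling", {
  target <- diag(4)
  target[1, 2] <- target[2, 1] <- 0.6
  tc <- simulate_timecourses(4, 3000, target, nuisance_scale = 0.4,
                             seed = 31)
  cv <- coupling_vector(tc)
  expect_lt(abs(cv$coupling[cv$pair == "net01__net02"] - 0.6), 0.05)
  # identity target, no nuisance: couplings at sampling-noise level
  tc0 <- simulate_timecourses(6, 2000, diag(6), nuisance_scale = 0,
                              seed = 32)
  expect_lt(max(abs(coupling_vector(tc0)$coupling)), 0.1)
})

test_that("invalid coupling targets are rejected", {
  bad <- matrix(0.9, 3, 3); diag(bad) <- 1; bad[1, 2] <- -0.9
  expect_error(simulate_timecourses(3, 50, bad), "symmetric")
  neg <- diag(3); neg[1, 2] <- neg[2, 1] <- 1.2
  expect_error(simulate_timecourses(3, 50, neg), "positive definite")
})

test_that("a null configuration carries no group signal", {
  withr::local_seed(41)
  # zero effect sizes: screening finds ~ alpha * n_edges false positives
  cfg0 <- function(seed) {
    sim_config(n_control = 8, n_prehd = 8, n_timepoints = 120,
               coupling_hypo_deficit = 0, coupling_hyper_excess = 0,
               scv_slope = stats::setNames(rep(0, 6),
                                           names(sim_config()$scv_baseline)),
               ct_thinning = 0, min_converters = 0, seed = seed)
  }
  counts <- vapply(1:40, function(k) {
    b <- simulate_cohort(cfg0(4100 + k))
    cp <- cohort_couplings(b$timecourses)
    nrow(edge_group_screen(cp[, -1], b$subjects$group, alpha = 0.02))
  }, numeric(1))
  # total screened edges ~ Binomial(40 * 171, 0.02); generous 99.9% band
  total <- sum(counts)
  band <- qbinom(c(5e-4, 1 - 5e-4), 40 * 171, 0.02)
  expect_gte(total, band[1])
  expect_lte(total, band[2])
})

test_that("the configured caudate slope is recovered by regression", {
  cfg <- sim_config(n_control = 2, n_prehd = 200, min_converters = 0,
                    include_timecourses = FALSE, seed = 51)
  b <- simulate_cohort(cfg)
  s <- b$subjects
  pre <- s$group == "preHD"
  g <- pmin(pmax(1 - s$latent_years_to_onset[pre] / cfg$proximity_scale,
                 0)^cfg$proximity_power, 1.5)
  fit <- lm(b$scv$caudate[pre] ~ g + s$age[pre])
  slope_hat <- -coef(fit)[["g"]]
  expect_equal(slope_hat, cfg$scv_slope[["caudate"]], tolerance = 0.15)
})

test_that("unexpected converters become more frequent as onset error grows", {
  withr::local_seed(61)
  frac_unexpected <- vapply(c(0.05, 0.4, 1.2), function(sc) {
    mean(vapply(1:100, function(k) {
      b <- simulate_cohort(sim_config(onset_dev_scale = sc,
                                      min_converters = 0,
                                      include_timecourses = FALSE,
                                      seed = 6100 + 1000 * sc * 10 + k))
      s <- b$subjects
      sum(s$converted_within_followup & s$est_years_to_dx > 5, na.rm = TRUE)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(frac_unexpected) > 0))
})

test_that("near carriers lose caudate volume while far carriers track controls", {
  b <- simulate_cohort(sim_config(seed = 71, include_timecourses = FALSE))
  s <- b$subjects
  grp <- ifelse(s$group == "control", "control", s$subgroup)
  m <- tapply(b$scv$caudate, grp, mean)
  expect_lt(m[["near"]], m[["control"]])
  expect_lt(abs(m[["far"]] - m[["control"]]),
            m[["control"]] - m[["near"]])
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(n_control = 1), ">= 2")
  expect_error(sim_config(ct_noise = -1), ">= 0")
  expect_error(sim_config(min_converters = 25), "min_converters")
})
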