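test_that("pair index enumerates unordered pairs canonically", {
  pi19 <- pair_index(paste0("n", 1:19))
  expect_equal(nrow(pi19), 171)
  expect_equal(pi19$pair[1], "n1__n2")
  expect_equal(pi19$pair[171], "n18__n19")
  expect_equal(nrow(pair_index(c("a", "b", "c"))), 3)
  expect_false(anyDuplicated(pi19$pair) > 0)
})

test_that("coupling of a series with itself is +/-1", {
  x <- sin(seq_len(60)) + rnorm(60, sd = 0.1)
  expect_equal(estimate_pair_coupling(x, x), 1)
  expect_equal(estimate_pair_coupling(x, -x), -1)
})

test_that("coupling with nuisance matches the normal-equations oracle", {
  # 6-timepoint toy solved by explicit least squares
  x <- c(0.2, -1.1, 0.7, 1.9, -0.6, 0.3)
  y <- c(1.0, -0.4, 0.2, 2.2, -1.3, 0.8)
  nuis <- matrix(c(0.5, 0.1, -0.3, 0.9, 0.4, -0.7), ncol = 1)
  zx <- (x - mean(x)) / sd(x)
  zy <- (y - mean(y)) / sd(y)
  beta_of <- function(dep, ind) {
    D <- cbind(1, nuis, ind)
    solve(t(D) %*% D, t(D) %*% dep)[3]
  }
  oracle <- (beta_of(zy, zx) + beta_of(zx, zy)) / 2
  expect_equal(estimate_pair_coupling(x, y, nuis), oracle, tolerance = 1e-12)
})

test_that("with no nuisance the coupling equals the Pearson correlation", {
  withr::local_seed(7)
  for (k in 1:20) {
    x <- rnorm(50)
    y <- 0.4 * x + rnorm(50)
    expect_equal(estimate_pair_coupling(x, y), cor(x, y), tolerance = 1e-10)
  }
})

test_that("coupling is symmetric and unchanged by orthogonal nuisance", {
  withr::local_seed(8)
  x <- rnorm(80)
  y <- 0.5 * x + rnorm(80)
  expect_identical(estimate_pair_coupling(x, y),
                   estimate_pair_coupling(y, x))
  # build a regressor orthogonal to [1, x, y]
  raw <- rnorm(80)
  orth <- qr.resid(qr(cbind(1, x, y)), raw)
  expect_equal(estimate_pair_coupling(x, y, matrix(orth)),
               estimate_pair_coupling(x, y), tolerance = 1e-8)
})

test_that("degenerate coupling inputs raise informative errors", {
  x <- rnorm(30)
  expect_error(estimate_pair_coupling(x, rep(1, 30)), "constant")
  nuis <- cbind(a = x, b = 2 * x)
  expect_error(estimate_pair_coupling(x, rnorm(30), nuis), "collinear")
  expect_error(estimate_pair_coupling(x[1:3], rnorm(3), cbind(rnorm(3))),
               "timepoints")
})

test_that("coupling vector covers all pairs and respects relabelling", {
  withr::local_seed(9)
  sig <- matrix(rnorm(3 * 100), 3, 100)
  tc <- list(signals = sig, nuisance = NULL,
             network_labels = c("A", "B", "C"))
  cv <- coupling_vector(tc)
  expect_equal(nrow(cv), 3)
  # permuting the network order only re-indexes the canonical pairs
  perm <- c(3, 1, 2)
  tc2 <- list(signals = sig[perm, ], nuisance = NULL,
              network_labels = c("A", "B", "C")[perm])
  cv2 <- coupling_vector(tc2)
  key <- function(df) {
    sorted <- t(apply(df[, c("net_a", "net_b")], 1, sort))
    stats::setNames(df$coupling, paste(sorted[, 1], sorted[, 2], sep = "_"))
  }
  k1 <- key(cv)
  k2 <- key(cv2)
  expect_equal(k1, k2[names(k1)], tolerance = 1e-12)
})

test_that("19 simulated networks give 171 couplings", {
  tc <- simulate_timecourses(19, 120, diag(19), nuisance_scale = 0.3,
                             seed = 11)
  expect_equal(nrow(coupling_vector(tc)), 171)
})

test_that("edge screen splits directions by the sign of the group difference", {
  withr::local_seed(10)
  n <- 20
  mat <- matrix(rnorm(2 * n * 12), 2 * n, 12,
                dimnames = list(NULL, paste0("e", 1:12)))
  labels <- rep(c("control", "preHD"), each = n)
  shifted <- mat
  shifted[labels == "preHD", ] <- shifted[labels == "preHD", ] + 2
  es <- edge_group_screen(shifted, labels, alpha = 0.02)
  expect_true(all(es$direction == "hyper"))
  expect_true(all(es$p < 0.02))
  expect_error(edge_group_screen(mat[1:3, ], c("a", "b", "b")), "2 subjects")
})

test_that("edge sets are nested across screening thresholds", {
  withr::local_seed(11)
  mat <- matrix(rnorm(40 * 50), 40, 50,
                dimnames = list(NULL, paste0("e", 1:50)))
  mat[21:40, 1:5] <- mat[21:40, 1:5] - 1
  labels <- rep(c("control", "preHD"), each = 20)
  sets <- lapply(c(0.01, 0.02, 0.05), function(a) {
    edge_group_screen(mat, labels, alpha = a)$pair
  })
  expect_true(all(sets[[1]] %in% sets[[2]]))
  expect_true(all(sets[[2]] %in% sets[[3]]))
})

test_that("planted 1.5-SD deficits are recovered as hypo edges", {
  # per-edge power at alpha = 0.02, n = 20/20, d = 1.5 is
  # pt(qt(.99, 38), 38, ncp = 1.5/sqrt(0.1), lower = FALSE) ~ 0.988,
  # so ~98.8% of planted edges screen out and ~89% of replicates recover
  # all ten at once
  withr::local_seed(12)
  per_edge <- 0L
  all_ten <- 0L
  for (r in 1:20) {
    mat <- matrix(rnorm(40 * 30), 40, 30,
                  dimnames = list(NULL, paste0("e", 1:30)))
    mat[21:40, 1:10] <- mat[21:40, 1:10] - 1.5
    es <- edge_group_screen(mat, rep(c("control", "preHD"), each = 20),
                            alpha = 0.02)
    hypo <- es$pair[es$direction == "hypo"]
    found <- sum(paste0("e", 1:10) %in% hypo)
    per_edge <- per_edge + found
    all_ten <- all_ten + (found == 10L)
  }
  expect_gte(per_edge, 188) # 200 planted edge-replicates, 98.8% power
  expect_gte(all_ten, 13)
})

test_that("composite scores average the screened edges", {
  couplings <- tibble::tibble(subject_id = c("a", "b"),
                              e1 = c(0.2, 0.5), e2 = c(0.4, 0.1),
                              e3 = c(0.9, 0.8))
  edges <- tibble::tibble(pair = c("e1", "e2", "e3"),
                          direction = c("hypo", "hypo", "hyper"),
                          t = c(-3, -2.5, 2.6), p = c(0.01, 0.01, 0.01))
  hypo <- composite_score(couplings, edges, "hypo")
  expect_equal(hypo$composite, c(0.3, 0.3))
  hyper <- composite_score(couplings, edges, "hyper")
  expect_equal(hyper$composite, c(0.9, 0.8))
  # single-edge composite equals that edge
  single <- composite_score(couplings, edges[2, ], "hypo")
  expect_equal(single$composite, couplings$e2)
})

test_that("an empty direction yields an explicit no-composite result", {
  couplings <- tibble::tibble(subject_id = "a", e1 = 0.2)
  edges <- tibble::tibble(pair = "e1", direction = "hypo",
                          t = -3, p = 0.01)
  expect_message(out <- composite_score(couplings, edges, "hyper"),
                 "no composite defined")
  expect_equal(nrow(out), 0)
})
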