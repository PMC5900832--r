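# shared fixture builders (all data generated in code, seeded per test)

noise_features <- function(n, p, seed = 1) {
  withr::with_seed(seed, {
    matrix(rnorm(n * p), n, p,
           dimnames = list(paste0("s", seq_len(n)), paste0("f", seq_len(p))))
  })
}

balanced_labels <- function(n, levels = c("control", "patient")) {
  factor(rep(levels, each = n / 2), levels = levels)
}

toy_covariates <- function(n, n_sites = 2, seed = 1) {
  withr::with_seed(seed, {
    data.frame(age = rnorm(n, 45, 10),
               site = rep(paste0("site", seq_len(n_sites)), length.out = n))
  })
}

# two well-separated Gaussian classes
separated_features <- function(n_per = 10, p = 3, delta = 3, seed = 1) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n_per * p, -delta / 2), n_per, p),
               matrix(rnorm(n_per * p, delta / 2), n_per, p))
    colnames(X) <- paste0("f", seq_len(p))
    X
  })
}

small_cohort_config <- function(seed = 1, ...) {
  sim_config(n_control = 8, n_prehd = 8, n_timepoints = 120,
             min_converters = 0, seed = seed, ...)
}
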