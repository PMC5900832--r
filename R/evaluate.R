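#' F1 score with the patient class positive
#'
#' Harmonic mean of sensitivity (recall of the positive class) and
#' precision. Defined as 0 when there are no positive predictions or when
#' sensitivity and precision are both zero.
#'
#' @param truth,predicted Vectors of class labels.
#' @param positive The positive-class label.
#' @return List with `sensitivity`, `precision`, `f1` and the 2x2
#'   `confusion` table (truth in rows).
#' @export
f1_score <- function(truth, predicted, positive) {
  truth_pos <- truth == positive
  pred_pos <- predicted == positive
  tp <- sum(truth_pos & pred_pos)
  fp <- sum(!truth_pos & pred_pos)
  fn <- sum(truth_pos & !pred_pos)
  tn <- sum(!truth_pos & !pred_pos)
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (sens + prec > 0) 2 * sens * prec / (sens + prec) else 0
  confusion <- matrix(c(tn, fn, fp, tp), 2, 2,
                      dimnames = list(truth = c("negative", "positive"),
                                      predicted = c("negative", "positive")))
  list(sensitivity = sens, precision = prec, f1 = f1, confusion = confusion)
}

fast_f1 <- function(y, dec) {
  # y in {-1, 1}; predictions from the sign of the decision value
  tp <- sum(y > 0 & dec > 0)
  fp <- sum(y < 0 & dec > 0)
  fn <- sum(y > 0 & dec <= 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  if (sens + prec > 0) 2 * sens * prec / (sens + prec) else 0
}

#' Leave-one-out classification with in-fold preprocessing
#'
#' For each subject in turn, the preprocessing model
#' (standardize/residualize/inverse-normal) and the weighted linear SVM are
#' fitted on the remaining subjects and the held-out subject is predicted.
#' All held-out predictions are pooled into a single confusion matrix and
#' summarized by the F1 score with the patient class positive.
#'
#' @param features Subjects x features table (raw; preprocessing is fitted
#'   inside every fold).
#' @param labels Two-class factor or vector.
#' @param covariates Optional data frame with `age` and `site` columns for
#'   residualization (each site needs at least two subjects).
#' @param C Soft-margin cost.
#' @param positive Positive (patient) class; default second factor level.
#' @param rin Apply the rank-based inverse normal step (default `TRUE`).
#' @param paper_mode If `TRUE`, fit the preprocessing once on the full
#'   sample instead of inside each fold (the leakier convention some
#'   published analyses used); default `FALSE`.
#' @param engine `"cpp"` (cached fast path) or `"r"` (reference
#'   implementation built from [fit_preprocess()] and
#'   [train_weighted_svm()]); both give identical results.
#' @return A `classification_report`.
#' @export
loo_f1 <- function(features, labels, covariates = NULL, C = 1,
                   positive = NULL, rin = TRUE, paper_mode = FALSE,
                   engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  prep <- check_eval_inputs(features, labels, covariates, positive)
  n <- nrow(prep$X)
  if (n < 6) stop("leave-one-out evaluation needs n >= 6", call. = FALSE)
  if (min(table(prep$labels)) < 3) {
    stop("each class needs at least 3 subjects", call. = FALSE)
  }

  if (engine == "cpp") {
    dec <- cpp_loo_decisions(prep$X, prep$Z, matrix(prep$y, ncol = 1), C,
                             rin, paper_mode)[, 1]
  } else {
    dec <- loo_decisions_r(prep$X, prep$labels, covariates, C, prep$positive,
                           rin, paper_mode)
  }
  build_report(prep, dec, C)
}

loo_decisions_r <- function(X, labels, covariates, C, positive, rin,
                            paper_mode) {
  n <- nrow(X)
  dec <- numeric(n)
  if (paper_mode) {
    pm <- fit_preprocess(X, covariates)
    Xp <- apply_preprocess(pm, X, covariates, rin = rin)
  }
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    if (length(unique(labels[tr])) < 2) {
      stop("single-class training set in a leave-one-out fold", call. = FALSE)
    }
    if (paper_mode) {
      Xtr <- Xp[tr, , drop = FALSE]
      xho <- Xp[i, , drop = FALSE]
    } else {
      cv_tr <- if (is.null(covariates)) NULL else covariates[tr, , drop = FALSE]
      cv_ho <- if (is.null(covariates)) NULL else covariates[i, , drop = FALSE]
      pmod <- fit_preprocess(X[tr, , drop = FALSE], cv_tr)
      Xtr <- apply_preprocess(pmod, X[tr, , drop = FALSE], cv_tr, rin = rin)
      xho <- apply_preprocess(pmod, X[i, , drop = FALSE], cv_ho, rin = rin)
    }
    fit <- train_weighted_svm(Xtr, droplevels(labels[tr]), C = C,
                              positive = positive)
    dec[i] <- predict(fit, xho, type = "decision")
  }
  dec
}

#' Permutation test of leave-one-out classification
#'
#' Recomputes the full leave-one-out F1 under `n_perm` random relabelings
#' of the subjects (class counts preserved exactly; preprocessing refit
#' inside every fold of every permutation) and reports the add-one
#' empirical p value, `(1 + #\{null F1 >= observed F1\}) / (1 + n_perm)`.
#'
#' @inheritParams loo_f1
#' @param n_perm Number of permutations (default 1000; fewer than 100
#'   warns, fewer than 20 is an error).
#' @param seed Integer seed for the permutation draws; all permutations are
#'   drawn up front from this one seed so results do not depend on
#'   execution order.
#' @return A `classification_report` with the null F1 vector and empirical
#'   p value attached.
#' @export
permutation_test <- function(features, labels, covariates = NULL,
                             n_perm = 1000, seed = NULL, C = 1,
                             positive = NULL, rin = TRUE,
                             paper_mode = FALSE) {
  if (n_perm < 20) stop("`n_perm` must be at least 20", call. = FALSE)
  if (n_perm < 100) warning("`n_perm` < 100 gives a coarse null", call. = FALSE)
  prep <- check_eval_inputs(features, labels, covariates, positive)
  n <- nrow(prep$X)
  if (n < 6) stop("leave-one-out evaluation needs n >= 6", call. = FALSE)
  if (min(table(prep$labels)) < 3) {
    stop("each class needs at least 3 subjects", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(b) sample(prep$y),
                 integer(n))
  lab_mat <- cbind(prep$y, perm)
  dec <- cpp_loo_decisions(prep$X, prep$Z, lab_mat, C, rin, paper_mode)
  f1s <- vapply(seq_len(ncol(lab_mat)),
                function(b) fast_f1(lab_mat[, b], dec[, b]), numeric(1))
  obs <- f1s[1]
  null_f1 <- f1s[-1]
  report <- build_report(prep, dec[, 1], C)
  report$null_f1 <- null_f1
  report$n_perm <- n_perm
  report$p_value <- (1 + sum(null_f1 >= obs)) / (1 + n_perm)
  report$seed <- seed
  report
}

#' Cross-cohort validation of an SCV (or any feature-set) classifier
#'
#' Fits the preprocessing and the weighted linear SVM on one cohort and
#' scores a second cohort once. The null distribution is built by shuffling
#' the *test* cohort's labels and re-scoring the fixed predictions; the
#' trained model is never refitted.
#'
#' Site effects are removed within each cohort separately: the training
#' cohort through the fitted preprocessing model, the test cohort by
#' site-wise centering of its standardized, age-adjusted features (cohorts
#' have disjoint site sets, so the training site coefficients cannot be
#' transported).
#'
#' @param train_features,train_labels,train_covariates Training cohort.
#' @param test_features,test_labels,test_covariates Test cohort with the
#'   identical feature schema.
#' @inheritParams permutation_test
#' @return A `classification_report` for the test cohort.
#' @export
external_validate <- function(train_features, train_labels,
                              train_covariates = NULL,
                              test_features, test_labels,
                              test_covariates = NULL,
                              n_perm = 1000, seed = NULL, C = 1,
                              positive = NULL, rin = TRUE) {
  if (n_perm < 20) stop("`n_perm` must be at least 20", call. = FALSE)
  tr_names <- colnames(as.matrix(train_features))
  te_names <- colnames(as.matrix(test_features))
  missing <- setdiff(tr_names, te_names)
  if (length(missing) > 0) {
    stop("test cohort is missing feature(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  prep_tr <- check_eval_inputs(train_features, train_labels,
                               train_covariates, positive)
  pmod <- fit_preprocess(train_features, train_covariates)
  Xtr <- apply_preprocess(pmod, train_features, train_covariates, rin = rin)
  fit <- train_weighted_svm(Xtr, prep_tr$labels, C = C,
                            positive = prep_tr$positive)

  Xte <- transform_external(pmod, test_features, test_covariates, rin = rin)
  test_labels <- factor(test_labels, levels = levels(prep_tr$labels))
  if (anyNA(test_labels)) {
    stop("test labels contain classes unseen in training", call. = FALSE)
  }
  dec <- predict(fit, Xte, type = "decision")
  y_te <- ifelse(test_labels == prep_tr$positive, 1L, -1L)
  obs <- fast_f1(y_te, dec)
  if (!is.null(seed)) set.seed(seed)
  null_f1 <- vapply(seq_len(n_perm),
                    function(b) fast_f1(sample(y_te), dec), numeric(1))

  prep_te <- list(labels = test_labels, y = y_te,
                  positive = prep_tr$positive,
                  negative = prep_tr$negative,
                  subject_id = rownames(as.matrix(test_features)) %||%
                    paste0("s", seq_along(y_te)))
  report <- build_report(prep_te, dec, C)
  report$null_f1 <- null_f1
  report$n_perm <- n_perm
  report$p_value <- (1 + sum(null_f1 >= obs)) / (1 + n_perm)
  report$seed <- seed
  report$model <- fit
  report
}

# standardize + age-adjust with training parameters, then remove site
# offsets within the test cohort, then map through the training reference
# normal scores
transform_external <- function(model, features, covariates, rin = TRUE) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (!is.null(model$feature_names) && !is.null(colnames(X))) {
    X <- X[, model$feature_names, drop = FALSE]
  }
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  if (!is.null(model$beta) && !is.null(covariates)) {
    age_beta <- model$beta[c("(Intercept)", "age"), , drop = FALSE]
    Zage <- cbind(1, as.numeric(covariates$age))
    Xs <- Xs - Zage %*% age_beta
    for (s in unique(as.character(covariates$site))) {
      idx <- which(covariates$site == s)
      if (length(idx) > 1) {
        Xs[idx, ] <- sweep(Xs[idx, , drop = FALSE], 2,
                           colMeans(Xs[idx, , drop = FALSE]))
      }
    }
  }
  if (!rin) return(Xs)
  out <- Xs
  for (j in seq_len(ncol(Xs))) {
    r <- model$reference[[j]]
    out[, j] <- stats::approx(r$values, r$scores, xout = Xs[, j], rule = 2,
                              ties = "ordered")$y
  }
  out
}

check_eval_inputs <- function(features, labels, covariates, positive) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("features must be finite", call. = FALSE)
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("need exactly two classes", call. = FALSE)
  if (length(labels) != nrow(X)) stop("label/feature length mismatch", call. = FALSE)
  positive <- positive %||% levels(labels)[2]
  stopifnot(positive %in% levels(labels))
  negative <- setdiff(levels(labels), positive)
  y <- ifelse(labels == positive, 1L, -1L)
  Z <- matrix(numeric(0), nrow(X), 0)
  if (!is.null(covariates)) {
    stopifnot(is.data.frame(covariates), nrow(covariates) == nrow(X))
    site_tab <- table(covariates$site)
    if (any(site_tab < 2)) {
      stop("each site needs at least 2 subjects for fold-safe residualization",
           call. = FALSE)
    }
    Z <- covariate_design(covariates, levels(factor(covariates$site)))
  }
  list(X = X, labels = labels, y = y, Z = Z, positive = positive,
       negative = negative,
       subject_id = rownames(X) %||% paste0("s", seq_len(nrow(X))))
}

build_report <- function(prep, dec, C) {
  predicted <- factor(ifelse(dec > 0, prep$positive, prep$negative),
                      levels = c(prep$negative, prep$positive))
  metrics <- f1_score(prep$labels, predicted, prep$positive)
  structure(
    list(subjects = tibble::tibble(subject_id = prep$subject_id,
                                   truth = as.character(prep$labels),
                                   predicted = as.character(predicted),
                                   decision = unname(dec)),
         confusion = metrics$confusion,
         sensitivity = metrics$sensitivity,
         precision = metrics$precision,
         f1 = metrics$f1,
         positive = prep$positive, negative = prep$negative, C = C,
         null_f1 = numeric(0), n_perm = NA_integer_, p_value = NA_real_,
         seed = NULL),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat("Classification report (positive class:", x$positive, ")\n")
  cat(sprintf("  F1 = %.3f  sensitivity = %.3f  precision = %.3f\n",
              x$f1, x$sensitivity, x$precision))
  if (!is.na(x$n_perm)) {
    cat(sprintf("  permutation null: %d iterations, mean F1 = %.3f, p = %.4g\n",
                x$n_perm, mean(x$null_f1), x$p_value))
  }
  print(x$confusion)
  invisible(x)
}

#' @export
tidy.classification_report <- function(x, ...) {
  x$subjects
}

#' @export
glance.classification_report <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$subjects), f1 = x$f1, sensitivity = x$sensitivity,
    precision = x$precision,
    null_mean_f1 = if (length(x$null_f1)) mean(x$null_f1) else NA_real_,
    n_perm = x$n_perm, p_value = x$p_value
  )
}
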