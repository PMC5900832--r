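#' Train an imbalance-weighted linear SVM
#'
#' Fits a linear soft-margin support vector machine by sequential minimal
#' optimization on the dual, with per-class misclassification costs
#' proportional to inverse class frequency (normalized to mean 1) so that
#' imbalanced groups contribute equally to the decision boundary.
#'
#' Features are used as supplied; run [fit_preprocess()] /
#' [apply_preprocess()] first for the standard pipeline.
#'
#' @param features Subjects x features numeric matrix or data frame.
#' @param labels Factor (or coercible) with exactly two levels.
#' @param C Soft-margin cost (default 1).
#' @param positive Which level is the positive (patient) class; defaults to
#'   the second factor level.
#' @return An `hd_svm` model with weight vector `w`, offset `b`, class
#'   weights and training metadata. `predict()` returns classes or decision
#'   values (`w . x + b`).
#' @export
train_weighted_svm <- function(features, labels, C = 1,
                               positive = NULL) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("features must be finite", call. = FALSE)
  labels <- factor(labels)
  if (nlevels(labels) != 2) {
    stop("`labels` must contain exactly two classes (got ",
         nlevels(labels), ")", call. = FALSE)
  }
  if (length(labels) != nrow(X)) stop("label/feature length mismatch", call. = FALSE)
  positive <- positive %||% levels(labels)[2]
  stopifnot(positive %in% levels(labels))
  negative <- setdiff(levels(labels), positive)
  y <- ifelse(labels == positive, 1L, -1L)
  counts <- c(sum(y < 0), sum(y > 0))
  if (any(counts == 0)) stop("both classes must be present", call. = FALSE)
  inv <- 1 / counts
  wts <- inv / mean(inv)           # c(negative, positive), mean 1
  Cvec <- C * ifelse(y > 0, wts[2], wts[1])
  fit <- cpp_svm_train(X, y, Cvec)
  structure(
    list(w = stats::setNames(drop(fit$w), colnames(X)), b = fit$b,
         alpha = drop(fit$alpha), C = C,
         class_weights = stats::setNames(wts, c(negative, positive)),
         classes = c(negative = negative, positive = positive),
         feature_names = colnames(X), n_fit = nrow(X)),
    class = "hd_svm"
  )
}

#' @export
predict.hd_svm <- function(object, newdata,
                           type = c("class", "decision"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(X))) {
    X <- X[, object$feature_names, drop = FALSE]
  }
  dec <- drop(X %*% object$w) + object$b
  if (type == "decision") return(dec)
  factor(ifelse(dec > 0, object$classes[["positive"]],
                object$classes[["negative"]]),
         levels = unname(object$classes))
}

#' @export
print.hd_svm <- function(x, ...) {
  cat("Weighted linear SVM (SMO)\n")
  cat("  features:", length(x$w), " cost C:", x$C, "\n")
  cat("  classes:", x$classes[["negative"]], "(-) vs",
      x$classes[["positive"]], "(+)\n")
  cat("  class weights:", paste(sprintf("%s=%.3f", names(x$class_weights),
                                        x$class_weights), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.hd_svm <- function(x, ...) {
  tibble::tibble(
    feature = x$feature_names %||% paste0("V", seq_along(x$w)),
    weight = unname(x$w)
  )
}

#' @export
glance.hd_svm <- function(x, ...) {
  tibble::tibble(
    n = x$n_fit, p = length(x$w), C = x$C,
    norm_w = sqrt(sum(x$w^2)), b = x$b,
    n_support = sum(x$alpha > 1e-8)
  )
}

#' Hyperplane distances, patient ranks and median-split calls
#'
#' Signed distance of each subject to the SVM decision boundary,
#' `(w . x + b) / ||w||`, with larger values lying further on the positive
#' (patient) side. Patients are ranked by distance (rank 1 = deepest on the
#' patient side) and median-split into predicted converters (at or beyond
#' the patient median) and nonconverters.
#'
#' @param model An `hd_svm` model.
#' @param features Preprocessed features on the model's feature space.
#' @param is_patient Logical vector marking the patient subjects over which
#'   the ranks and the median split are computed (default: all subjects).
#' @param subject_id Optional subject identifiers.
#' @return Tibble with `subject_id`, `decision`, `distance`,
#'   `patient_rank`, `median_split` (`"predicted_converter"` /
#'   `"predicted_nonconverter"` / `NA` for non-patients).
#' @export
hyperplane_scores <- function(model, features, is_patient = NULL,
                              subject_id = NULL) {
  stopifnot(inherits(model, "hd_svm"))
  nw <- sqrt(sum(model$w^2))
  if (nw < 1e-12) stop("degenerate model: ||w|| = 0", call. = FALSE)
  dec <- predict(model, features, type = "decision")
  n <- length(dec)
  is_patient <- is_patient %||% rep(TRUE, n)
  subject_id <- subject_id %||% rownames(as.matrix(features)) %||%
    paste0("s", seq_len(n))
  dist <- dec / nw
  rank_pat <- rep(NA_real_, n)
  rank_pat[is_patient] <- rank(-dist[is_patient], ties.method = "average")
  split <- rep(NA_character_, n)
  med <- median(dist[is_patient])
  split[is_patient] <- ifelse(dist[is_patient] >= med,
                              "predicted_converter", "predicted_nonconverter")
  tibble::tibble(subject_id = subject_id, decision = unname(dec),
                 distance = unname(dist), patient_rank = rank_pat,
                 median_split = split)
}
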