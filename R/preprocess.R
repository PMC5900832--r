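#' Rank-based inverse normal transform
#'
#' Maps a numeric vector to normal scores via Blom-offset ranks,
#' `qnorm((r - 3/8) / (n + 1/4))`, with average ranks for ties. The
#' transform is strictly monotone in the input (ties map to equal scores).
#'
#' @param x Numeric vector with at least 3 distinct values.
#' @return Numeric vector of normal scores.
#' @examples
#' rank_inverse_normal(c(1, 5, 9))
#' @export
rank_inverse_normal <- function(x) {
  stopifnot(is.numeric(x))
  if (anyNA(x)) stop("`x` must not contain missing values", call. = FALSE)
  if (length(unique(x)) < 3) {
    stop("rank-based inverse normal transform needs >= 3 distinct values",
         call. = FALSE)
  }
  n <- length(x)
  qnorm((rank(x, ties.method = "average") - 3 / 8) / (n + 1 / 4))
}

#' Fit the feature preprocessing model
#'
#' Fits the classifier preprocessing chain on a training population:
#' features are standardized (center/scale), residualized on age and
#' imaging-site indicators, then mapped to normal scores by the rank-based
#' inverse normal transform. All parameters (means, scales, regression
#' coefficients, reference values/scores for the normal mapping) are taken
#' from the fit population only, so the model can be applied to held-out
#' subjects without touching their labels.
#'
#' @param features Data frame or matrix of subjects x features (numeric).
#' @param covariates Data frame with columns `age` (numeric) and `site`
#'   (categorical), one row per subject, or `NULL` to skip residualization.
#' @return A `preprocess_model` object.
#' @seealso [apply_preprocess()]
#' @export
fit_preprocess <- function(features, covariates = NULL) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("features must be finite", call. = FALSE)
  center <- colMeans(X)
  scale <- apply(X, 2, sd)
  if (any(scale < 1e-12)) {
    stop("constant feature column(s): ",
         paste(colnames(X)[scale < 1e-12], collapse = ", "), call. = FALSE)
  }
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")

  site_levels <- NULL
  beta <- NULL
  if (!is.null(covariates)) {
    stopifnot(is.data.frame(covariates), nrow(covariates) == nrow(X),
              all(c("age", "site") %in% names(covariates)))
    if (sd(covariates$age) < 1e-12) {
      stop("covariate `age` is constant", call. = FALSE)
    }
    site_levels <- levels(factor(covariates$site))
    Z <- covariate_design(covariates, site_levels)
    beta <- qr.coef(qr(Z), Xs)
    beta[is.na(beta)] <- 0
    Xs <- Xs - Z %*% beta
  }

  ref <- lapply(seq_len(ncol(Xs)), function(j) {
    v <- Xs[, j]
    sc <- rank_inverse_normal(v)
    ord <- order(v)
    keep <- !duplicated(v[ord])
    list(values = v[ord][keep], scores = sc[ord][keep])
  })

  structure(
    list(feature_names = colnames(X), center = center, scale = scale,
         site_levels = site_levels, beta = beta, reference = ref,
         n_fit = nrow(X)),
    class = "preprocess_model"
  )
}

#' Apply a fitted preprocessing model
#'
#' Standardizes, residualizes and normal-score-transforms a feature table
#' using only the parameters stored in `model`. Held-out subjects receive
#' interpolated normal scores from the fit population's reference values
#' (clamped at the extremes); subjects from the fit population itself
#' recover their exact Blom scores.
#'
#' @param model A `preprocess_model` from [fit_preprocess()].
#' @param features Subjects x features table with the fit feature schema.
#' @param covariates As in [fit_preprocess()]; required if the model was
#'   fitted with covariates. A site level unseen at fit time is an error.
#' @param rin Apply the final inverse-normal step (default `TRUE`). With
#'   `FALSE` the residualized standardized features are returned, which are
#'   exactly uncorrelated with the fit covariates on the fit population.
#' @return Numeric matrix of preprocessed features.
#' @export
apply_preprocess <- function(model, features, covariates = NULL, rin = TRUE) {
  stopifnot(inherits(model, "preprocess_model"))
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (!is.null(model$feature_names) && !is.null(colnames(X))) {
    missing <- setdiff(model$feature_names, colnames(X))
    if (length(missing) > 0) {
      stop("features missing from input: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    X <- X[, model$feature_names, drop = FALSE]
  }
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  if (!is.null(model$beta)) {
    if (is.null(covariates)) {
      stop("model was fitted with covariates; supply `covariates`", call. = FALSE)
    }
    unseen <- setdiff(unique(as.character(covariates$site)), model$site_levels)
    if (length(unseen) > 0) {
      stop("unseen site level(s) at apply time: ",
           paste(unseen, collapse = ", "), call. = FALSE)
    }
    Z <- covariate_design(covariates, model$site_levels)
    Xs <- Xs - Z %*% model$beta
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

# intercept + age + treatment-coded site indicators (site dropped when the
# fit population had a single site)
covariate_design <- function(covariates, site_levels) {
  n <- nrow(covariates)
  Z <- cbind(`(Intercept)` = rep(1, n), age = as.numeric(covariates$age))
  if (length(site_levels) > 1) {
    site <- factor(as.character(covariates$site), levels = site_levels)
    dummies <- vapply(site_levels[-1], function(s) as.numeric(site == s),
                      numeric(n))
    dummies <- matrix(dummies, nrow = n,
                      dimnames = list(NULL, paste0("site", site_levels[-1])))
    Z <- cbind(Z, dummies)
  }
  Z
}
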