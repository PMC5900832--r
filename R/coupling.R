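#' Canonical unordered network-pair index
#'
#' Pairs are ordered (1,2), (1,3), ..., (1,n), (2,3), ..., (n-1,n); labels
#' are `"<netA>__<netB>"`.
#'
#' @param network_labels Character vector of network names.
#' @return Tibble with `position`, `i`, `j`, `net_a`, `net_b`, `pair`.
#' @export
pair_index <- function(network_labels) {
  n <- length(network_labels)
  stopifnot(n >= 2, !anyDuplicated(network_labels))
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  tibble::tibble(
    position = seq_len(nrow(idx)),
    i = unname(idx[, "row"]), j = unname(idx[, "col"]),
    net_a = network_labels[idx[, "row"]],
    net_b = network_labels[idx[, "col"]],
    pair = paste0(network_labels[idx[, "row"]], "__",
                  network_labels[idx[, "col"]])
  )
}

#' Coupling strength between two network time courses
#'
#' Both series are z-scored, then each is regressed on the other with the
#' nuisance series included; the coupling strength is the mean of the two
#' slope coefficients. With no nuisance regressors this equals the Pearson
#' correlation; it is symmetric in `x` and `y` by construction.
#'
#' @param x,y Numeric time series of equal length.
#' @param nuisance Optional time x k matrix of nuisance regressors.
#' @return Scalar coupling strength.
#' @export
estimate_pair_coupling <- function(x, y, nuisance = NULL) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("time series must be finite", call. = FALSE)
  }
  if (sd(x) < 1e-12 || sd(y) < 1e-12) {
    stop("constant time series: coupling undefined (zero variance)",
         call. = FALSE)
  }
  tt <- length(x)
  D <- cbind(`(Intercept)` = rep(1, tt))
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    stopifnot(nrow(nuisance) == tt)
    if (is.null(colnames(nuisance))) {
      colnames(nuisance) <- paste0("nuisance", seq_len(ncol(nuisance)))
    }
    D <- cbind(D, nuisance)
  }
  if (tt < ncol(D) + 3) {
    stop("need at least 3 more timepoints than regressors", call. = FALSE)
  }
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    bad <- colnames(D)[qrD$pivot[seq(qrD$rank + 1, ncol(D))]]
    stop("rank-deficient design; collinear regressor(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  zx <- (x - mean(x)) / sd(x)
  zy <- (y - mean(y)) / sd(y)
  rx <- qr.resid(qrD, zx)
  ry <- qr.resid(qrD, zy)
  # Frisch-Waugh: slope of y~x given D equals slope between the residuals
  s <- sum(rx * ry)
  0.5 * (s / sum(rx * rx) + s / sum(ry * ry))
}

#' All pairwise coupling strengths for one subject
#'
#' Applies [estimate_pair_coupling()] to every unordered network pair in
#' canonical order; 19 networks yield 171 couplings.
#'
#' @param tc A `timecourse_set` (see [simulate_timecourses()]) or a list
#'   with `signals` (networks x time), `nuisance` (time x k or `NULL`) and
#'   optional `network_labels`.
#' @return Tibble with `position`, `pair`, `net_a`, `net_b`, `coupling`.
#' @export
coupling_vector <- function(tc) {
  sig <- as.matrix(tc$signals)
  labels <- tc$network_labels %||% rownames(sig) %||%
    paste0("net", sprintf("%02d", seq_len(nrow(sig))))
  nuis <- tc$nuisance
  tt <- ncol(sig)
  if (!is.null(nuis)) {
    nuis <- as.matrix(nuis)
    stopifnot(nrow(nuis) == tt)
  }
  if (any(!is.finite(sig))) stop("time series must be finite", call. = FALSE)
  sds <- apply(sig, 1, sd)
  if (any(sds < 1e-12)) {
    stop("constant time series for network(s): ",
         paste(labels[sds < 1e-12], collapse = ", "), call. = FALSE)
  }
  Zs <- t((sig - rowMeans(sig)) / sds) # time x networks, z-scored columns
  D <- cbind(rep(1, tt), nuis)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    stop("rank-deficient nuisance design", call. = FALSE)
  }
  R <- qr.resid(qrD, Zs)
  S <- crossprod(R)
  d <- diag(S)
  pi_tbl <- pair_index(labels)
  s_ij <- S[cbind(pi_tbl$i, pi_tbl$j)]
  pi_tbl$coupling <- 0.5 * s_ij * (1 / d[pi_tbl$i] + 1 / d[pi_tbl$j])
  pi_tbl[, c("position", "pair", "net_a", "net_b", "coupling")]
}

#' Couplings for every subject of a cohort
#'
#' @param timecourses Named list of timecourse sets (one per subject), e.g.
#'   the `timecourses` element of a simulated cohort bundle.
#' @return Wide tibble: `subject_id` plus one column per canonical network
#'   pair.
#' @export
cohort_couplings <- function(timecourses) {
  stopifnot(is.list(timecourses), length(timecourses) > 0)
  ids <- names(timecourses) %||% paste0("s", seq_along(timecourses))
  rows <- purrr::map(timecourses, function(tc) {
    cv <- coupling_vector(tc)
    stats::setNames(cv$coupling, cv$pair)
  })
  mat <- do.call(rbind, rows)
  dplyr::bind_cols(tibble::tibble(subject_id = ids),
                   tibble::as_tibble(mat))
}

#' Screen network pairs for group differences
#'
#' Per-edge two-sample pooled-variance t tests of patients versus controls
#' at an uncorrected threshold (no multiplicity correction, by design).
#' Edges below the threshold are split into `hypo` (patient mean below
#' control mean) and `hyper` (above).
#'
#' @param couplings Wide tibble from [cohort_couplings()] (a `subject_id`
#'   column plus numeric pair columns), or a plain numeric matrix.
#' @param labels Group label per subject (two groups).
#' @param patient Label of the patient group; defaults to the second factor
#'   level.
#' @param alpha Uncorrected two-tailed threshold (default 0.02).
#' @return An `edge_set`: tibble with `pair`, `direction`, `t`, `p`, and
#'   attributes `alpha`, `tail`, `patient`.
#' @export
edge_group_screen <- function(couplings, labels, patient = NULL,
                              alpha = 0.02) {
  mat <- coupling_matrix(couplings)
  labels <- factor(labels)
  stopifnot(length(labels) == nrow(mat), nlevels(labels) == 2)
  patient <- patient %||% levels(labels)[2]
  stopifnot(patient %in% levels(labels))
  pat <- labels == patient
  n1 <- sum(pat); n0 <- sum(!pat)
  if (n1 < 2 || n0 < 2) {
    stop("need at least 2 subjects per group to screen edges", call. = FALSE)
  }
  m1 <- colMeans(mat[pat, , drop = FALSE])
  m0 <- colMeans(mat[!pat, , drop = FALSE])
  v1 <- apply(mat[pat, , drop = FALSE], 2, var)
  v0 <- apply(mat[!pat, , drop = FALSE], 2, var)
  sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
  tstat <- (m1 - m0) / sqrt(sp2 * (1 / n1 + 1 / n0))
  pval <- 2 * stats::pt(-abs(tstat), df = n1 + n0 - 2)
  res <- tibble::tibble(
    pair = colnames(mat),
    direction = ifelse(m1 < m0, "hypo", "hyper"),
    t = unname(tstat), p = unname(pval)
  )
  res <- res[res$p < alpha, , drop = FALSE]
  structure(res, alpha = alpha, tail = "two-tailed", patient = patient,
            class = c("edge_set", class(res)))
}

#' Composite hypo-/hyper-connectivity scores
#'
#' Unweighted mean of each subject's coupling values over the screened
#' edges of one direction. An empty direction yields an explicit zero-row
#' result (with a message), never a zero score.
#'
#' @param couplings Wide couplings table (see [edge_group_screen()]).
#' @param edges An `edge_set`.
#' @param direction `"hypo"` or `"hyper"`.
#' @return Tibble with `subject_id`, `direction`, `composite`.
#' @export
composite_score <- function(couplings, edges, direction = c("hypo", "hyper")) {
  direction <- match.arg(direction)
  sel <- edges$pair[edges$direction == direction]
  ids <- if (is.data.frame(couplings) && "subject_id" %in% names(couplings)) {
    couplings$subject_id
  } else {
    rownames(as.matrix(couplings)) %||% paste0("s", seq_len(nrow(couplings)))
  }
  if (length(sel) == 0) {
    message("no composite defined: no edges screened in direction '",
            direction, "'")
    return(tibble::tibble(subject_id = character(0),
                          direction = character(0),
                          composite = numeric(0)))
  }
  mat <- coupling_matrix(couplings)
  tibble::tibble(subject_id = ids, direction = direction,
                 composite = unname(rowMeans(mat[, sel, drop = FALSE])))
}

#' Both composite scores in wide form
#'
#' @inheritParams composite_score
#' @return Tibble `subject_id`, plus `hypo` and/or `hyper` columns for the
#'   directions with screened edges.
#' @export
composite_scores <- function(couplings, edges) {
  out <- NULL
  for (dir in c("hypo", "hyper")) {
    cs <- suppressMessages(composite_score(couplings, edges, dir))
    if (nrow(cs) == 0) next
    cs <- stats::setNames(cs[, c("subject_id", "composite")],
                          c("subject_id", dir))
    out <- if (is.null(out)) cs else dplyr::left_join(out, cs, by = "subject_id")
  }
  if (is.null(out)) {
    message("no composite defined: edge set is empty")
    return(tibble::tibble(subject_id = character(0)))
  }
  out
}

coupling_matrix <- function(couplings) {
  if (is.data.frame(couplings)) {
    num <- vapply(couplings, is.numeric, logical(1))
    mat <- as.matrix(couplings[, num, drop = FALSE])
    if ("subject_id" %in% names(couplings)) {
      rownames(mat) <- couplings$subject_id
    }
    mat
  } else {
    as.matrix(couplings)
  }
}
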