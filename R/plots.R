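#' @importFrom ggplot2 autoplot ggplot aes geom_histogram geom_vline
#'   geom_point geom_segment geom_boxplot geom_jitter labs theme_minimal
#'   scale_colour_manual
NULL

#' @export
ggplot2::autoplot

#' Plot a permutation null distribution with the observed F1
#'
#' @param object A `classification_report` with a permutation null.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.classification_report <- function(object, ...) {
  if (length(object$null_f1) == 0) {
    stop("report has no permutation null; run permutation_test()", call. = FALSE)
  }
  df <- tibble::tibble(null_f1 = object$null_f1)
  ggplot(df, aes(x = .data$null_f1)) +
    geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    geom_vline(xintercept = object$f1, colour = "#c0392b", linewidth = 1) +
    labs(x = "null F1 (shuffled labels)", y = "count",
         title = sprintf("Observed F1 = %.2f, empirical p = %.3g",
                         object$f1, object$p_value)) +
    theme_minimal()
}

#' Plot screened edges as a coupling-difference map
#'
#' One point per screened network pair, coloured by direction (hypo- vs
#' hyper-connectivity in patients), sized by |t|; a text-free analogue of
#' the connectivity "schema ball".
#'
#' @param object An `edge_set`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.edge_set <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot(df, aes(x = .data$pair, y = .data$t, colour = .data$direction)) +
    geom_segment(aes(xend = .data$pair, yend = 0), linewidth = 0.6) +
    geom_point(size = 2) +
    scale_colour_manual(values = c(hypo = "#2c6fbb", hyper = "#c0392b")) +
    labs(x = NULL, y = "t statistic (patient - control)",
         title = sprintf("Screened edges (two-tailed p < %g, uncorrected)",
                         attr(object, "alpha"))) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}

#' Composite connectivity scores by group
#'
#' @param composites Output of [composite_scores()].
#' @param groups Group label per subject (aligned with the composites
#'   rows), e.g. control/preHD-far/preHD-near.
#' @return A ggplot.
#' @export
plot_composites <- function(composites, groups) {
  stopifnot(nrow(composites) == length(groups))
  long <- tidyr::pivot_longer(
    dplyr::mutate(composites, group = as.character(groups)),
    cols = -c("subject_id", "group"),
    names_to = "direction", values_to = "composite")
  ggplot(long, aes(x = .data$group, y = .data$composite)) +
    geom_boxplot(outlier.shape = NA, fill = "grey90") +
    geom_jitter(width = 0.12, alpha = 0.6, size = 1.2) +
    ggplot2::facet_wrap(~direction, scales = "free_y") +
    labs(x = NULL, y = "mean coupling over screened edges") +
    theme_minimal()
}

#' Hyperplane distances with conversion outcome
#'
#' @param scores Output of [hyperplane_scores()].
#' @param converted Logical conversion outcome per subject (NA for
#'   controls/non-patients).
#' @return A ggplot.
#' @export
plot_hyperplane <- function(scores, converted) {
  df <- dplyr::mutate(scores, converted = converted)
  df <- df[!is.na(df$patient_rank), ]
  ggplot(df, aes(x = .data$patient_rank, y = .data$distance,
                 colour = .data$converted)) +
    geom_point(size = 2.5) +
    scale_colour_manual(values = c(`TRUE` = "#c0392b", `FALSE` = "#2c6fbb"),
                        name = "converted") +
    labs(x = "rank among patients (1 = deepest on patient side)",
         y = "signed distance to hyperplane") +
    theme_minimal()
}
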