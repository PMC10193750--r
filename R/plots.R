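#' Plot an ROC curve
#'
#' @param object An ROC tibble from [roc_points()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.orfvec_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate (1 - specificity)",
                  y = "True positive rate (sensitivity)",
                  title = "ROC of the coding-potential classifier") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the ROC for scored predictions
#'
#' Convenience wrapper: computes [roc_points()] and draws the curve with
#' the trapezoidal AUC in the subtitle.
#'
#' @param truth Character vector over `{"coding", "noncoding"}`.
#' @param coding_prob Numeric scores.
#' @return A ggplot object.
#' @export
plot_roc <- function(truth, coding_prob) {
  r <- roc_points(truth, coding_prob)
  autoplot(r) +
    ggplot2::labs(subtitle = sprintf("AUC (trapezoid) = %.4f",
                                     auc_trapezoid(truth, coding_prob)))
}

#' Plot document vectors in two principal components
#'
#' Projects the trained paragraph vectors of a PV-DM model onto their first
#' two principal components, optionally coloured by class label -- a quick
#' look at whether the embedding separates coding from noncoding documents.
#'
#' @param model A `pvdm` model.
#' @param labels Optional tibble with columns `id` and `label`.
#' @return A ggplot object.
#' @export
plot_embedding <- function(model, labels = NULL) {
  stopifnot(inherits(model, "pvdm"))
  pc <- stats::prcomp(model$doc_matrix, rank. = 2L)
  df <- tibble(id = rownames(model$doc_matrix),
               PC1 = pc$x[, 1L], PC2 = pc$x[, 2L])
  if (!is.null(labels)) {
    df <- dplyr::left_join(df, labels[, c("id", "label")], by = "id")
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                          colour = .data$label))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  }
  p + ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(title = "PV-DM document vectors, first two principal components") +
    ggplot2::theme_minimal()
}
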