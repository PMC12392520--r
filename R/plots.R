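# ggplot2 displays for cross-validation reports, adaptive fits and
# interpretation tables.

#' Plot a cross-validation report
#'
#' One panel per metric with per-fold points and the fold mean.
#'
#' @param object A `topreg_cv` tibble from [cross_validate()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.topreg_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("nrmse", "spearman_rho", "pcc", "bias"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$model, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 3,
                          size = 3, colour = "red") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Cross-validation metrics by fold")
}

#' Plot the anchor-set growth of an adaptive fit
#'
#' Anchor-set size per adaptive step, with the validation NRMSE trace when
#' early stopping was monitored.
#'
#' @param object An `adaptor_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.adaptor_model <- function(object, ...) {
  df <- tibble::tibble(
    step = seq_along(object$anchor_sets),
    anchors = vapply(object$anchor_sets, length, integer(1))
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$anchors)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "adaptive step", y = "structure anchors",
                  title = "Adaptive structure-anchor accumulation")
  if (length(object$val_history) > 0) {
    vh <- tibble::tibble(step = seq_along(object$val_history),
                         nrmse = object$val_history)
    p <- p + ggplot2::geom_line(
      data = vh,
      ggplot2::aes(x = .data$step,
                   y = .data$nrmse * max(df$anchors) / max(vh$nrmse)),
      colour = "red")
  }
  p
}

#' Plot adjusted-weight-sum interpretation scores
#'
#' Diverging bar chart of the top positive and negative critical structure
#' anchors.
#'
#' @param model A fitted model.
#' @param k Anchors per direction; default 5.
#' @param low_response_threshold Passed to [adjusted_weight_sums()].
#' @return A ggplot.
#' @export
plot_adjusted_weights <- function(model, k = 5, low_response_threshold = 5.0) {
  s <- adjusted_weight_sums(model, low_response_threshold)
  top <- dplyr::bind_rows(utils::head(s, k), utils::head(s[rev(seq_len(nrow(s))), ], k))
  top$anchor_id <- factor(top$anchor_id, levels = rev(unique(top$anchor_id)))
  ggplot2::ggplot(top, ggplot2::aes(x = .data$score, y = .data$anchor_id,
                                    fill = .data$score > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "adjusted weight sum", y = "structure anchor",
                  title = "Critical structure anchors")
}
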