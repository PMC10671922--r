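#' Plot the C-search objective curve
#'
#' Mean fused F-beta score across folds against the sharpening exponent,
#' with the selected C marked.
#'
#' @param object A `caw_search` object from [search_c()].
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @method autoplot caw_search
#' @export
autoplot.caw_search <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$c,
                                             y = .data$objective)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$best_c, linetype = "dashed") +
    ggplot2::labs(x = "sharpening exponent C",
                  y = "mean fused score across folds",
                  title = sprintf("Exhaustive C search (best C = %g)",
                                  object$best_c)) +
    ggplot2::theme_minimal()
}

#' Plot cross-validated method scores
#'
#' Mean F2 per method with ± one standard-deviation error bars across
#' folds; fusion methods are highlighted.
#'
#' @param object A `caw_cv` object from [run_cv()].
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @method autoplot caw_cv
#' @export
autoplot.caw_cv <- function(object, ...) {
  d <- object$per_method |>
    dplyr::mutate(
      method = factor(.data$method, levels = .data$method),
      kind = ifelse(.data$method %in%
                      c("majority_vote", "caw_v1", "caw_v2"),
                    "fusion", "base model"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$method, y = .data$mean,
                                  fill = .data$kind)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.25) +
    ggplot2::scale_fill_manual(values = c(`base model` = "grey65",
                                          fusion = "steelblue")) +
    ggplot2::coord_cartesian(
      ylim = c(max(0, min(d$mean) - 5), min(100, max(d$mean) + 2))) +
    ggplot2::labs(x = NULL, y = "F2 score (%, mean ± sd across folds)",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot a fusion weight vector
#'
#' @param weights A data frame with columns `model` and `weight`.
#'
#' @return A ggplot object.
#' @export
plot_weights <- function(weights) {
  w <- align_weights(weights, weights$model)
  d <- tibble::tibble(model = factor(weights$model,
                                     levels = weights$model),
                      weight = w)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$model, y = .data$weight)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1 / nrow(d), linetype = "dotted") +
    ggplot2::labs(x = NULL, y = "fusion weight") +
    ggplot2::theme_minimal()
}
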