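#' Plot training curves of a fitted pair transformer
#'
#' @param object A `tspe_fit`.
#' @param ... Unused.
#' @return A ggplot of train/validation loss per epoch with the selected
#'   checkpoint marked.
#' @export
autoplot.tspe_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_loss", "valid_loss"),
                           names_to = "series", values_to = "loss")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed") +
    ggplot2::labs(x = "epoch", y = "binary cross-entropy",
                  colour = NULL,
                  title = "Training history",
                  subtitle = sprintf("best checkpoint at epoch %d",
                                     object$best_epoch)) +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validation metrics
#'
#' @param object A `tspe_cv`.
#' @param ... Unused.
#' @return A ggplot with one panel per metric, folds on the x axis and the
#'   across-fold mean as a horizontal line.
#' @export
autoplot.tspe_cv <- function(object, ...) {
  pf <- tidyr::pivot_longer(object$per_fold,
                            dplyr::all_of(metric_cols),
                            names_to = "metric")
  means <- object$aggregate
  ggplot2::ggplot(pf, ggplot2::aes(x = factor(.data$fold), y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(data = means,
                        ggplot2::aes(yintercept = .data$mean),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "fold", y = NULL,
                  title = sprintf("Cross-validation metrics (%s)",
                                  object$variant)) +
    ggplot2::theme_minimal()
}

#' Plot a positional-encoding ablation
#'
#' @param object A `tspe_ablation`.
#' @param metric Metric column of the per-fold tables to display.
#' @param ... Unused.
#' @return A ggplot of per-fold metric distributions by encoding variant.
#' @export
autoplot.tspe_ablation <- function(object, metric = "roc_auc", ...) {
  pf <- purrr::imap(object$runs, function(cv, id) {
    parts <- strsplit(id, "/")[[1]]
    dplyr::mutate(cv$per_fold, variant = parts[1], seed = parts[2])
  }) |> dplyr::bind_rows()
  pf$variant <- factor(pf$variant, levels = object$variants)
  ggplot2::ggplot(pf, ggplot2::aes(x = .data$variant, y = .data[[metric]])) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$seed), width = 0.15,
                         alpha = 0.7) +
    ggplot2::labs(x = NULL, y = metric,
                  title = "Positional-encoding ablation",
                  colour = "seed") +
    ggplot2::theme_minimal()
}
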