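#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a ball-histogram model
#'
#' Returns one row per attribute with its template, sampling radius, count
#' vector and random-forest importance (mean decrease in Gini).
#'
#' @param x A `bh_model`.
#' @param ... Unused.
#' @return A tibble ordered by decreasing importance.
#' @export
tidy.bh_model <- function(x, ...) {
  imp <- randomForest::importance(x$forest)[, 1]
  out <- tibble(
    attr_id = x$space$attr_id,
    template = vapply(x$space$template, paste, character(1), collapse = ","),
    radius = x$space$radius,
    counts = vapply(x$space$counts, paste, character(1), collapse = ","),
    importance = unname(imp)
  )
  dplyr::arrange(out, dplyr::desc(.data$importance))
}

#' @rdname tidy.bh_model
#' @export
glance.bh_model <- function(x, ...) {
  tibble(
    radius = x$radius,
    n_templates = length(x$templates),
    n_attributes = nrow(x$space),
    n_samples = x$n_samples,
    ntree = x$ntree,
    oob_error = tryCatch(x$forest$err.rate[x$forest$ntree, "OOB"],
                         error = function(e) NA_real_)
  )
}

#' Tidy cross-validation results
#'
#' `tidy()` returns the per-fold metrics and chosen hyperparameters;
#' `glance()` a one-row summary with mean and standard deviation of AUC and
#' accuracy.
#'
#' @param x A `bh_cv` from [cross_validate()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.bh_cv <- function(x, ...) {
  x$folds
}

#' @rdname tidy.bh_cv
#' @export
glance.bh_cv <- function(x, ...) {
  tibble(
    k = x$k,
    mean_auc = x$summary$mean[1], sd_auc = x$summary$sd[1],
    mean_accuracy = x$summary$mean[2], sd_accuracy = x$summary$sd[2]
  )
}

#' Plot cross-validation metrics
#'
#' Per-fold AUC and accuracy as points with the cross-fold mean as a line.
#'
#' @param object A `bh_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bh_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(object$folds, c("auc", "accuracy"),
                              names_to = "metric", values_to = "value")
  means <- dplyr::summarise(dplyr::group_by(long, .data$metric),
                            value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$fold), y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(data = means,
                        ggplot2::aes(yintercept = .data$value),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "fold", y = NULL,
                  title = sprintf("%d-fold cross-validation", object$k))
}
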