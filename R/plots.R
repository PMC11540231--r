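#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-K accuracy across repeats for an evaluation report
#'
#' Boxplots of the per-repeat accuracy at each neighbourhood size K (KNN
#' arm), or across repeats for the SVM arm, with the K-averaged mean drawn
#' as a dashed line.
#'
#' @param object an [evaluate_pipeline()] report.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- object$accuracy
  df$k <- factor(ifelse(is.na(df$k), "svm", as.character(df$k)),
                 levels = unique(ifelse(is.na(df$k), "svm", as.character(df$k))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$accuracy)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::geom_hline(yintercept = object$mean_accuracy, linetype = "dashed") +
    ggplot2::labs(
      x = "K (nearest neighbours)", y = "accuracy",
      title = sprintf(
        "%s subspace (dim %s): %.3f ± %.3f over %d repeats",
        object$config$method,
        ifelse(is.na(object$dim_used), "-", object$dim_used),
        object$mean_accuracy, object$sd_accuracy, object$config$n_repeats
      )
    ) +
    ggplot2::theme_minimal()
}

#' Scree-style spectrum plot for a linear subspace
#'
#' @param object a [fit_pca()] or [fit_multiclass_da()] fit.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot linear_subspace
#' @export
autoplot.linear_subspace <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "component", y = df$kind[1],
      title = paste0(object$method_tag, " spectrum")
    ) +
    ggplot2::theme_minimal()
}

#' Discrim-value spectrum of a Foley-Sammon basis
#'
#' @param object a [fit_foley_sammon()] fit.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot foley_sammon
#' @export
autoplot.foley_sammon <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$direction, y = .data$discrim_value)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(
      x = "direction", y = "discrim-value (Fisher ratio)",
      title = "Foley-Sammon discrim-value spectrum"
    ) +
    ggplot2::theme_minimal()
}

#' Objective trace of an NMF fit
#'
#' @param object an [fit_nmf()] fit.
#' @param ... unused.
#' @return a ggplot object (log-scale objective against iteration).
#' @method autoplot nmf_fit
#' @export
autoplot.nmf_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$objective)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "iteration", y = "||Y - KX||_F^2",
      title = sprintf("NMF objective (rank %d, seed %d)", object$rank, object$seed)
    ) +
    ggplot2::theme_minimal()
}

#' Scatter plot of a 2-D (or wider) projection
#'
#' Plots the first two columns of a projected feature table coloured by
#' label — the standard visual check that a subspace separates the classes.
#'
#' @param proj a tibble from [project()] (must keep its `label` column).
#' @return a ggplot object.
#' @export
plot_projection <- function(proj) {
  stopifnot(is.data.frame(proj), "label" %in% names(proj))
  coords <- setdiff(names(proj), c("id", "label"))
  if (length(coords) < 2L) stop("need at least two projected coordinates.")
  ggplot2::ggplot(proj, ggplot2::aes(
    x = .data[[coords[1]]], y = .data[[coords[2]]], color = .data$label
  )) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(color = "class") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
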