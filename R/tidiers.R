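# broom-style tidiers and plots for fitted mixture objects

#' Tidy a fitted GGMM
#'
#' One row per component-variable pair: mixing proportion, mean, marginal
#' variance and the node's degree in the component's learned graph.
#'
#' @param x a `ggmm` object.
#' @param ... unused.
#' @export
tidy.ggmm <- function(x, ...) {
  purrr::map_dfr(seq_len(x$K), function(k) {
    cc <- x$components[[k]]
    deg <- rowSums(as_adjacency(cc$graph))
    tibble::tibble(
      component = k,
      proportion = x$proportions[k],
      variable = x$variable_names,
      mean = as.numeric(cc$mean),
      variance = diag(cc$covariance),
      degree = as.integer(deg)
    )
  })
}

#' One-row fit summary of a GGMM
#'
#' @param x a `ggmm` object.
#' @param ... unused.
#' @export
glance.ggmm <- function(x, ...) {
  tibble::tibble(
    K = x$K,
    log_likelihood = x$log_likelihood,
    penalized_loglik = x$penalized_loglik,
    n_params = x$n_params,
    bic = x$bic,
    n_iterations = x$n_iterations,
    converged = x$converged,
    total_edges = sum(vapply(x$components,
                             function(cc) n_edges(cc$graph), numeric(1))),
    seed = x$seed
  )
}

#' Mean-profile plot of a fitted GGMM
#'
#' Component mean vectors by variable, one line per cluster.
#'
#' @param object a `ggmm` object.
#' @param ... unused.
#' @export
autoplot.ggmm <- function(object, ...) {
  df <- tidy(object)
  df$variable <- factor(df$variable, levels = object$variable_names)
  df$component <- factor(df$component)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$variable, y = .data$mean,
                                   color = .data$component,
                                   group = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "component mean", color = "cluster") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
tidy.ggmm_selection <- function(x, ...) x$bic_table

#' @export
glance.ggmm_selection <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(selected_K = x$model$K,
                                  n_failures = nrow(x$failures)),
                   glance(x$model))
}

#' BIC curve of a model-selection sweep
#'
#' @param object a `ggmm_selection`.
#' @param ... unused.
#' @export
autoplot.ggmm_selection <- function(object, ...) {
  df <- object$bic_table
  ggplot2::ggplot(df[df$status == "ok", ],
                  ggplot2::aes(x = .data$K, y = .data$bic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = df[df$K == object$model$K & df$status == "ok", ],
                        color = "red", size = 3) +
    ggplot2::labs(x = "number of clusters K", y = "BIC") +
    ggplot2::theme_minimal()
}
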