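#' Weighted signed networks over variables
#'
#' A `weighted_network` wraps a symmetric edge-weight matrix with a zero
#' diagonal, on either the covariance scale (component networks of a fitted
#' mixture) or the partial-correlation scale (regularized networks, entries
#' in \[-1, 1\]).
#'
#' @param weights symmetric numeric matrix with (numerically) zero diagonal.
#' @param variable_names node names; defaults to the matrix's column names.
#' @param scale `"covariance"` or `"partial_correlation"`.
#' @return an object of class `weighted_network` with fields `weights`,
#'   `variable_names`, `scale`.
#' @export
weighted_network <- function(weights,
                             variable_names = colnames(weights),
                             scale = c("covariance", "partial_correlation")) {
  scale <- match.arg(scale)
  weights <- as.matrix(weights)
  p <- nrow(weights)
  if (p != ncol(weights)) ggmnet_abort("bad_dimensions", "weights must be square")
  if (max(abs(weights - t(weights))) > 1e-12) {
    ggmnet_abort("bad_network", "weights must be symmetric within 1e-12")
  }
  weights <- 0.5 * (weights + t(weights))
  diag(weights) <- 0
  if (scale == "partial_correlation" && max(abs(weights)) > 1 + 1e-12) {
    ggmnet_abort("bad_network", "partial correlations must lie in [-1, 1]")
  }
  if (is.null(variable_names)) variable_names <- paste0("V", seq_len(p))
  dimnames(weights) <- list(variable_names, variable_names)
  structure(list(weights = weights, variable_names = variable_names,
                 scale = scale),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  ne <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat(sprintf("<weighted_network (%s): %d nodes, %d edges>\n",
              x$scale, length(x$variable_names), ne))
  invisible(x)
}

#' Tidy a weighted network into an edge list
#'
#' @param x a `weighted_network`.
#' @param ... unused.
#' @return a tibble with columns `from`, `to`, `weight`, one row per nonzero
#'   edge (upper triangle).
#' @export
tidy.weighted_network <- function(x, ...) {
  w <- x$weights
  idx <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
  tibble::tibble(
    from = x$variable_names[idx[, 1]],
    to = x$variable_names[idx[, 2]],
    weight = w[idx]
  )
}

#' @export
glance.weighted_network <- function(x, ...) {
  w <- x$weights[upper.tri(x$weights)]
  tibble::tibble(
    nodes = length(x$variable_names),
    edges = sum(w != 0),
    density = mean(w != 0),
    min_weight = if (any(w != 0)) min(w[w != 0]) else NA_real_,
    max_weight = if (any(w != 0)) max(w[w != 0]) else NA_real_,
    scale = x$scale
  )
}

#' Heatmap of a weighted network
#'
#' @param object a `weighted_network`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.weighted_network <- function(object, ...) {
  df <- tibble::as_tibble(object$weights, rownames = "from") |>
    tidyr::pivot_longer(-"from", names_to = "to", values_to = "weight")
  df$from <- factor(df$from, levels = object$variable_names)
  df$to <- factor(df$to, levels = rev(object$variable_names))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$from, y = .data$to,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = object$scale) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
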