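# Node centrality on weighted signed networks. Strength-type indexes are
# direct (absolute or signed) edge-weight sums; geodesic indexes use edge
# lengths 1/|weight| (strong associations = short distances), with igraph
# supplying Dijkstra distances and Brandes betweenness (tied shortest paths
# counted fractionally, endpoints excluded).

as_weighted_network <- function(net) {
  if (inherits(net, "weighted_network")) return(net)
  weighted_network(net)
}

igraph_from_network <- function(net) {
  w <- abs(net$weights)
  igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Strength centrality
#'
#' Sum of absolute edge weights connected to each node.
#'
#' @param net a [weighted_network()] (or a symmetric weight matrix).
#' @return named numeric vector over nodes.
#' @export
net_strength <- function(net) {
  net <- as_weighted_network(net)
  setNames(rowSums(abs(net$weights)), net$variable_names)
}

#' Expected influence
#'
#' Sum of raw (signed) edge weights connected to each node.
#'
#' @inheritParams net_strength
#' @export
net_expected_influence <- function(net) {
  net <- as_weighted_network(net)
  setNames(rowSums(net$weights), net$variable_names)
}

#' All-pairs geodesic distances
#'
#' Shortest-path lengths with edge length `1 / |weight|`; unconnected pairs
#' are `Inf`.
#'
#' @inheritParams net_strength
#' @return a `p x p` distance matrix with zero diagonal.
#' @export
shortest_path_lengths <- function(net) {
  net <- as_weighted_network(net)
  g <- igraph_from_network(net)
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  dimnames(d) <- list(net$variable_names, net$variable_names)
  d
}

#' Closeness centrality
#'
#' Inverse of the sum of geodesic distances from a node to all other nodes;
#' zero when any other node is unreachable.
#'
#' @inheritParams net_strength
#' @export
net_closeness <- function(net) {
  net <- as_weighted_network(net)
  d <- shortest_path_lengths(net)
  diag(d) <- 0
  tot <- rowSums(d)
  out <- ifelse(is.finite(tot) & tot > 0, 1 / tot, 0)
  setNames(out, net$variable_names)
}

#' Betweenness centrality
#'
#' Number of times a node lies on shortest paths between other nodes, over
#' edge lengths `1 / |weight|`; equal-length paths are counted fractionally
#' and endpoints are excluded.
#'
#' @inheritParams net_strength
#' @export
net_betweenness <- function(net) {
  net <- as_weighted_network(net)
  g <- igraph_from_network(net)
  b <- igraph::betweenness(g, weights = 1 / igraph::E(g)$weight,
                           directed = FALSE)
  setNames(as.numeric(b), net$variable_names)
}

# validate / coerce a community assignment against a network's nodes
as_community_map <- function(communities, variable_names) {
  if (is.data.frame(communities)) {
    if (ncol(communities) < 2L) {
      ggmnet_abort("missing_community",
                   "community data frame needs (variable, community) columns")
    }
    communities <- setNames(as.character(communities[[2]]),
                            as.character(communities[[1]]))
  }
  if (is.null(names(communities))) {
    ggmnet_abort("missing_community", "communities must be named by variable")
  }
  missing <- setdiff(variable_names, names(communities))
  if (length(missing) > 0L) {
    ggmnet_abort("missing_community", paste0(
      "unmapped nodes: ", paste(missing, collapse = ", ")))
  }
  as.character(communities[variable_names])
}

#' Bridge strength
#'
#' Sum of absolute weights of a node's edges to nodes in *other* communities
#' (1-step bridge centrality).
#'
#' @inheritParams net_strength
#' @param communities named character vector (or two-column data frame)
#'   mapping every node to a community label.
#' @export
bridge_strength <- function(net, communities) {
  net <- as_weighted_network(net)
  comm <- as_community_map(communities, net$variable_names)
  cross <- outer(comm, comm, `!=`)
  setNames(rowSums(abs(net$weights) * cross), net$variable_names)
}

#' Bridge expected influence
#'
#' Signed sum of a node's edge weights to other communities (1-step).
#'
#' @inheritParams bridge_strength
#' @export
bridge_expected_influence <- function(net, communities) {
  net <- as_weighted_network(net)
  comm <- as_community_map(communities, net$variable_names)
  cross <- outer(comm, comm, `!=`)
  setNames(rowSums(net$weights * cross), net$variable_names)
}

#' z-standardize a vector of index values
#'
#' Centers and scales by the population standard deviation (denominator `n`)
#' across nodes, the convention for standardized centrality panels.
#'
#' @param values numeric vector, length >= 2.
#' @export
z_standardize <- function(values) {
  if (length(values) < 2L) ggmnet_abort("bad_dimensions", "need length >= 2")
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  if (s == 0) ggmnet_abort("degenerate_values", "values are constant")
  (values - m) / s
}

z_or_na <- function(values, index) {
  tryCatch(z_standardize(values), ggmnet_degenerate_values = function(e) {
    warn(sprintf("%s is constant across nodes; z-scores set to NA", index))
    rep(NA_real_, length(values))
  })
}

#' Centrality table for a weighted network
#'
#' Computes strength, expected influence, closeness and betweenness — plus
#' bridge strength and bridge expected influence when a community map is
#' given — each raw and z-standardized across the network's nodes.
#'
#' @inheritParams bridge_strength
#' @param communities optional community map enabling the bridge indexes.
#' @param long return long format (`node`, `index`, `value`, `z`) instead of
#'   one column pair per index.
#' @return a tibble, one row per node (wide) or node-index pair (long).
#' @examples
#' w <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
#' w["a", "b"] <- w["b", "a"] <- 0.5
#' w["b", "c"] <- w["c", "b"] <- -0.3
#' centrality_table(weighted_network(w))
#' @export
centrality_table <- function(net, communities = NULL, long = FALSE) {
  net <- as_weighted_network(net)
  idx <- list(
    strength = net_strength(net),
    expected_influence = net_expected_influence(net),
    closeness = net_closeness(net),
    betweenness = net_betweenness(net)
  )
  comm_col <- NULL
  if (!is.null(communities)) {
    comm_col <- as_community_map(communities, net$variable_names)
    idx$bridge_strength <- bridge_strength(net, communities)
    idx$bridge_expected_influence <- bridge_expected_influence(net, communities)
  }
  out <- tibble::tibble(node = net$variable_names)
  if (!is.null(comm_col)) out$community <- comm_col
  for (nm in names(idx)) {
    out[[nm]] <- as.numeric(idx[[nm]])
    out[[paste0("z_", nm)]] <- z_or_na(out[[nm]], nm)
  }
  if (long) {
    raw <- out |>
      dplyr::select(!dplyr::starts_with("z_")) |>
      tidyr::pivot_longer(-dplyr::any_of(c("node", "community")),
                          names_to = "index", values_to = "value")
    zs <- out |>
      dplyr::select(dplyr::any_of(c("node", "community")),
                    dplyr::starts_with("z_")) |>
      tidyr::pivot_longer(-dplyr::any_of(c("node", "community")),
                          names_to = "index", values_to = "z")
    zs$index <- sub("^z_", "", zs$index)
    out <- dplyr::left_join(raw, zs,
                            by = intersect(c("node", "community", "index"),
                                           names(raw)))
  }
  out
}

#' Plot standardized centrality profiles
#'
#' Line-and-point panels of z-standardized centrality indexes by node, one
#' facet per index.
#'
#' @param table output of [centrality_table()] (wide format).
#' @return a ggplot object.
#' @export
plot_centrality <- function(table) {
  df <- table |>
    dplyr::select(dplyr::any_of("node"), dplyr::starts_with("z_")) |>
    tidyr::pivot_longer(dplyr::starts_with("z_"),
                        names_to = "index", values_to = "z")
  df$index <- sub("^z_", "", df$index)
  df$node <- factor(df$node, levels = rev(table$node))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$node, group = 1)) +
    ggplot2::geom_path(color = "grey50") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~index, nrow = 1) +
    ggplot2::labs(x = "z-score", y = NULL) +
    ggplot2::theme_minimal()
}
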