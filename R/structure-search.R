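#' Penalized structure score
#'
#' The score used to compare candidate graph structures: the profile Gaussian
#' log-likelihood minus a per-edge penalty
#' \eqn{(1 + \beta)\,(\log n_{\mathrm{eff}} / 2)\,|E|}. With `beta = 0` this
#' is a BIC-type penalized likelihood (each free edge parameter charged
#' `log(n_eff)/2`).
#'
#' @param loglik profile log-likelihood of the graph's constrained MLE.
#' @param n_edges number of edges of the candidate graph.
#' @param n_eff effective sample size supporting the component (> 1).
#' @param beta extra tuning weight on the penalty; default 0.
#' @return the penalized score (higher is better).
#' @export
penalized_score <- function(loglik, n_edges, n_eff, beta = 0) {
  if (n_eff <= 1) ggmnet_abort("bad_dimensions", "`n_eff` must exceed 1")
  loglik - (1 + beta) * (log(n_eff) / 2) * n_edges
}

per_edge_penalty <- function(n_eff, beta) (1 + beta) * log(n_eff) / 2

#' Penalized-likelihood graph structure search
#'
#' Finds the undirected graph maximizing [penalized_score()] where the
#' log-likelihood term is profiled over the graph-constrained covariance MLE.
#' `greedy_stepwise` starts from the empty graph and repeatedly toggles the
#' single edge (addition or removal) that most increases the score, stopping
#' at a local optimum; `exhaustive` (p <= 5 only) enumerates every graph.
#' Score ties prefer fewer edges, then the lexicographically smallest edge
#' set.
#'
#' @param S sample covariance matrix.
#' @param n_eff effective sample size behind `S`.
#' @param beta penalty tuning weight (default 0).
#' @param strategy `"greedy_stepwise"` or `"exhaustive"`.
#' @param tol,max_sweeps passed to the constrained MLE.
#' @return a [graph_structure()] with attributes `score`, `loglik`,
#'   `covariance` and `precision` of the winning fit.
#' @export
structure_search <- function(S, n_eff, beta = 0,
                             strategy = c("greedy_stepwise", "exhaustive"),
                             tol = 1e-8, max_sweeps = 2000L) {
  strategy <- match.arg(strategy)
  S <- as.matrix(S)
  p <- nrow(S)
  if (n_eff <= 1) ggmnet_abort("bad_dimensions", "`n_eff` must exceed 1")
  pen <- per_edge_penalty(n_eff, beta)
  if (strategy == "exhaustive") {
    if (p > 5L) {
      ggmnet_abort("unsupported",
                   "exhaustive search supports at most 5 variables")
    }
    res <- cpp_exhaustive_search(S, n_eff, pen, tol, as.integer(max_sweeps))
  } else {
    res <- cpp_greedy_search(S, n_eff, pen, matrix(0L, p, p), tol,
                             as.integer(max_sweeps))
  }
  if (res$status != 0L) {
    ggmm_fail("not_positive_definite",
              "no graph admits a positive-definite constrained MLE")
  }
  g <- graph_from_adjacency01(res$adj)
  attr(g, "score") <- res$score
  attr(g, "loglik") <- res$loglik
  attr(g, "covariance") <- res$sigma
  attr(g, "precision") <- res$omega
  g
}
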