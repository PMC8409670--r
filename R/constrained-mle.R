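#' Graph-constrained maximum-likelihood covariance
#'
#' Computes the Gaussian MLE of a covariance matrix constrained so that its
#' inverse (the precision) is zero at every variable pair not joined by an
#' edge. At the optimum the fitted covariance matches the sample covariance on
#' the diagonal and on every edge, while off-graph precision entries are
#' exactly zero — the classical covariance-selection solution, computed by
#' edge-wise iterative proportional fitting.
#'
#' @param S symmetric sample covariance matrix with positive diagonal.
#' @param graph a [graph_structure()] over the same variables.
#' @param tol convergence tolerance on the constrained moments (default 1e-8).
#' @param max_sweeps maximum IPF sweeps over the edge set (default 10000).
#' @return the fitted covariance matrix, with the precision matrix in
#'   attribute `"precision"`.
#' @examples
#' S <- matrix(c(1, .5, .4, .5, 1, .6, .4, .6, 1), 3)
#' g <- graph_structure(3, rbind(c(1, 2), c(2, 3)))
#' constrained_covariance_mle(S, g)[1, 3] # 0.5 * 0.6 / 1 = 0.30
#' @export
constrained_covariance_mle <- function(S, graph, tol = 1e-8, max_sweeps = 10000L) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S) || max(abs(S - t(S))) > 1e-8) {
    ggmnet_abort("bad_dimensions", "S must be a symmetric square matrix")
  }
  if (any(diag(S) <= 0)) {
    ggmm_fail("not_positive_definite", "S has non-positive diagonal entries")
  }
  if (!inherits(graph, "graph_structure") || graph$p != nrow(S)) {
    ggmnet_abort("bad_graph", "graph does not match S")
  }
  fit <- cpp_ipf_ggm(S, as_adjacency(graph), tol, as.integer(max_sweeps), NULL)
  if (fit$status == 2L) {
    ggmm_fail("not_positive_definite",
              "sample covariance not positive definite on an edge marginal")
  }
  if (fit$status == 1L) {
    ggmm_fail("no_convergence",
              sprintf("IPF did not reach tol %g in %d sweeps", tol, max_sweeps))
  }
  sigma <- fit$sigma
  dimnames(sigma) <- dimnames(S)
  attr(sigma, "precision") <- fit$omega
  sigma
}
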