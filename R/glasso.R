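# Regularized partial-correlation networks: L1-penalized Gaussian precision
# estimation (graphical lasso) with the extended BIC selecting the penalty.

#' Graphical lasso precision estimate
#'
#' Maximizes `log det(Omega) - tr(S Omega) - lambda * sum_{i != j} |Omega_ij|`
#' over positive-definite precision matrices by blockwise coordinate descent.
#' Off-diagonal entries shrunk by the soft-threshold operator are exactly
#' zero. The diagonal is unpenalized, so `lambda = 0` returns the inverse of
#' `S`.
#'
#' @param S symmetric positive-semidefinite sample covariance with positive
#'   diagonal.
#' @param lambda nonnegative L1 penalty.
#' @param tol relative convergence tolerance on the working covariance
#'   (default 1e-8).
#' @param max_iter maximum outer sweeps (default 10000).
#' @return the estimated precision matrix (symmetric positive definite).
#' @export
glasso_fit <- function(S, lambda, tol = 1e-8, max_iter = 10000L) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S) || max(abs(S - t(S))) > 1e-8) {
    ggmnet_abort("bad_dimensions", "S must be a symmetric square matrix")
  }
  if (any(diag(S) <= 0)) ggmnet_abort("bad_network", "S needs a positive diagonal")
  if (lambda < 0) ggmnet_abort("bad_network", "lambda must be nonnegative")
  res <- cpp_glasso(S, lambda, tol, as.integer(max_iter))
  if (res$status == 2L) {
    ggmm_fail("not_positive_definite", "S is singular and lambda is 0")
  }
  if (res$status == 1L) {
    ggmm_fail("no_convergence", sprintf(
      "graphical lasso did not converge in %d sweeps", max_iter))
  }
  omega <- res$omega
  dimnames(omega) <- dimnames(S)
  omega
}

#' Partial correlations from a precision matrix
#'
#' `weight(i, j) = -omega_ij / sqrt(omega_ii * omega_jj)` with a zero
#' diagonal: the correlation between two variables after conditioning on all
#' the others.
#'
#' @param omega symmetric positive-definite precision matrix.
#' @param variable_names optional node names.
#' @return a [weighted_network()] on the partial-correlation scale.
#' @export
precision_to_pcor <- function(omega, variable_names = colnames(omega)) {
  omega <- as.matrix(omega)
  if (any(diag(omega) <= 0)) {
    ggmnet_abort("invalid_precision", "precision diagonal must be positive")
  }
  d <- 1 / sqrt(diag(omega))
  w <- -omega * tcrossprod(d)
  diag(w) <- 0
  weighted_network(w, variable_names = variable_names,
                   scale = "partial_correlation")
}

#' Extended BIC for a sparse precision fit
#'
#' `-2 loglik + |E| log(n) + 4 gamma |E| log(p)`: BIC on the edge count plus
#' an extra penalty scaled by `gamma * log(p)` that guards against spurious
#' edges when many are tested.
#'
#' @param loglik unpenalized Gaussian log-likelihood of the fitted precision.
#' @param n_edges number of nonzero off-diagonal pairs.
#' @param n sample size.
#' @param p number of variables.
#' @param gamma nonnegative EBIC hyperparameter.
#' @export
ebic_score <- function(loglik, n_edges, n, p, gamma) {
  if (n <= 0 || p <= 1) ggmnet_abort("bad_dimensions", "need n > 0 and p > 1")
  -2 * loglik + n_edges * log(n) + 4 * gamma * n_edges * log(p)
}

# unpenalized Gaussian log-likelihood of a precision given MLE covariance S
gaussian_loglik_precision <- function(omega, S, n) {
  ld <- determinant(omega, logarithm = TRUE)
  (n / 2) * (as.numeric(ld$modulus) - sum(S * omega) -
               nrow(S) * log(2 * pi))
}

#' Estimate a regularized partial-correlation network
#'
#' Computes the sample covariance (MLE, denominator `n`) of the supplied
#' rows, fits the graphical lasso along a descending `lambda` grid, scores
#' every fit by [ebic_score()] with the unpenalized Gaussian log-likelihood,
#' and returns the partial-correlation network of the minimizer. Ties prefer
#' the larger `lambda` (sparser network).
#'
#' The default grid is 100 logarithmically spaced values from
#' `lambda_max = max |S_offdiag|` down to `0.01 * lambda_max`.
#'
#' @param data matrix or data frame of the cluster's rows.
#' @param gamma EBIC hyperparameter (default 0.5, the conventional
#'   conservative setting).
#' @param lambda_grid optional descending positive penalty grid.
#' @param n_lambda,lambda_min_ratio grid construction when `lambda_grid` is
#'   `NULL`.
#' @param tol graphical-lasso convergence tolerance.
#' @return a [weighted_network()] with attributes `lambda`, `ebic`,
#'   `precision` and a tibble `path` (lambda, edges, EBIC along the grid).
#' @examples
#' sim <- psychopathology_fixture(n = 300, seed = 3)
#' net <- select_network(sim$data)
#' glance(net)
#' @export
select_network <- function(data, gamma = 0.5, lambda_grid = NULL,
                           n_lambda = 100L, lambda_min_ratio = 0.01,
                           tol = 1e-8) {
  if (NROW(data) == 0L) ggmnet_abort("empty_cluster", "no rows supplied")
  X <- as_data_matrix(data)
  n <- nrow(X); p <- ncol(X)
  if (n < p + 1) {
    warn(sprintf("only %d rows for %d variables; network may be unstable",
                 n, p))
  }
  Xc <- scale(X, center = TRUE, scale = FALSE)
  S <- crossprod(Xc) / n
  if (is.null(lambda_grid)) {
    lambda_max <- max(abs(S[upper.tri(S)]))
    if (lambda_max <= 0) {
      omega <- diag(1 / diag(S), p)
      net <- precision_to_pcor(omega, colnames(X))
      attr(net, "lambda") <- NA_real_
      attr(net, "ebic") <- ebic_score(
        gaussian_loglik_precision(omega, S, n), 0L, n, p, gamma)
      attr(net, "precision") <- omega
      return(net)
    }
    lambda_grid <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                           length.out = n_lambda))
  } else {
    if (length(lambda_grid) == 0L || any(lambda_grid <= 0) ||
        is.unsorted(rev(lambda_grid))) {
      ggmnet_abort("bad_network", "lambda_grid must be descending and positive")
    }
  }
  best <- NULL
  path <- vector("list", length(lambda_grid))
  for (i in seq_along(lambda_grid)) {
    lam <- lambda_grid[i]
    omega <- glasso_fit(S, lam, tol = tol)
    ne <- sum(omega[upper.tri(omega)] != 0)
    ll <- gaussian_loglik_precision(omega, S, n)
    score <- ebic_score(ll, ne, n, p, gamma)
    path[[i]] <- tibble::tibble(lambda = lam, edges = ne, ebic = score)
    # strict improvement required, so ties keep the earlier (larger) lambda
    if (is.null(best) || score < best$score - 1e-12) {
      best <- list(lambda = lam, omega = omega, score = score)
    }
  }
  net <- precision_to_pcor(best$omega, colnames(X))
  attr(net, "lambda") <- best$lambda
  attr(net, "ebic") <- best$score
  attr(net, "precision") <- best$omega
  attr(net, "path") <- dplyr::bind_rows(path)
  net
}
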