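# Multivariate Gaussian log-densities and the E-step of the mixture EM.
# Everything is done in log space via the Cholesky factor so responsibilities
# stay well defined even where every component density underflows.

#' Validate and coerce a subjects-by-variables data matrix
#'
#' Accepts a numeric matrix or a data frame of numeric columns. Requires at
#' least 2 rows and 2 columns, no missing entries, and nonzero sample variance
#' in every column.
#'
#' @param data matrix or data frame, rows = subjects, columns = variables.
#' @return numeric matrix with column names.
#' @export
as_data_matrix <- function(data) {
  if (is.data.frame(data)) {
    bad <- !vapply(data, is.numeric, logical(1))
    if (any(bad)) {
      ggmnet_abort("parse_error", paste0(
        "non-numeric columns: ", paste(names(data)[bad], collapse = ", ")))
    }
    data <- as.matrix(data)
  }
  if (!is.matrix(data) || !is.numeric(data)) {
    ggmnet_abort("parse_error", "`data` must be a numeric matrix or data frame")
  }
  if (anyNA(data)) {
    idx <- which(is.na(data), arr.ind = TRUE)
    ggmnet_abort("missing_data", sprintf(
      "missing values, first at row %d column %d", idx[1, 1], idx[1, 2]))
  }
  if (nrow(data) < 2L || ncol(data) < 2L) {
    ggmnet_abort("bad_dimensions", "need at least 2 rows and 2 columns")
  }
  v <- apply(data, 2L, stats::var)
  if (any(v <= 0)) {
    ggmnet_abort("constant_column", paste0(
      "zero-variance columns: ",
      paste(colnames(data)[v <= 0] %||% which(v <= 0), collapse = ", ")))
  }
  if (is.null(colnames(data))) colnames(data) <- paste0("V", seq_len(ncol(data)))
  data
}

# Cholesky with a positive-definiteness check; signals not_positive_definite
chol_pd <- function(sigma, K = NA_integer_) {
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch) || any(diag(ch) <= sqrt(1e-8))) {
    ggmm_fail("not_positive_definite",
              "covariance is not positive definite (min eigenvalue <= 1e-8)",
              K = K)
  }
  ch
}

# rows of X evaluated under one Gaussian; returns length-n vector of log phi
mvn_log_density_rows <- function(X, mean, sigma) {
  ch <- chol_pd(sigma)
  p <- ncol(X)
  z <- backsolve(ch, t(X) - mean, transpose = TRUE)
  -0.5 * p * log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

#' Multivariate Gaussian log-density
#'
#' Evaluates \eqn{\log \Phi(x \mid \mu, \Sigma)} for a single observation.
#'
#' @param x numeric vector of length `p`.
#' @param mean numeric mean vector of length `p`.
#' @param covariance `p x p` positive-definite covariance matrix.
#' @return the log-density, a finite scalar.
#' @examples
#' gaussian_log_density(0, 0, matrix(1)) # -0.5 * log(2 * pi)
#' @export
gaussian_log_density <- function(x, mean, covariance) {
  x <- as.numeric(x)
  mean <- as.numeric(mean)
  covariance <- as.matrix(covariance)
  if (length(x) != length(mean) || length(x) != nrow(covariance) ||
      nrow(covariance) != ncol(covariance)) {
    ggmnet_abort("bad_dimensions", "x, mean and covariance dimensions disagree")
  }
  as.numeric(mvn_log_density_rows(matrix(x, nrow = 1L), mean, covariance))
}

# n x K matrix of log(tau_k) + log phi_k(x_i)
weighted_log_density_matrix <- function(X, model) {
  K <- model$K
  out <- matrix(NA_real_, nrow(X), K)
  for (k in seq_len(K)) {
    out[, k] <- log(model$proportions[k]) +
      mvn_log_density_rows(X, model$components[[k]]$mean,
                           model$components[[k]]$covariance)
  }
  out
}

# log-sum-exp over rows; also the observed-data log-likelihood contribution
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Posterior responsibilities (E-step)
#'
#' For every row of `data`, the posterior probability of each mixture
#' component: \eqn{\tau_k \Phi(x_i \mid \mu_k, \Sigma_k)} normalized over
#' components. Computed in log space.
#'
#' @param data matrix or data frame accepted by [as_data_matrix()].
#' @param model a fitted [fit_ggmm()] model (or any list with `K`,
#'   `proportions`, `components`).
#' @return an `n x K` matrix; rows sum to one.
#' @export
e_step <- function(data, model) {
  # lighter validation than as_data_matrix: scoring points needs dimensions
  # and completeness, not column variance
  if (is.data.frame(data)) data <- as.matrix(data)
  if (!is.matrix(data) || !is.numeric(data) || anyNA(data)) {
    ggmnet_abort("parse_error", "`data` must be a complete numeric matrix")
  }
  X <- data
  if (ncol(X) != length(model$components[[1]]$mean)) {
    ggmnet_abort("bad_dimensions", "data and model dimensions disagree")
  }
  ld <- weighted_log_density_matrix(X, model)
  lse <- row_logsumexp(ld)
  if (any(!is.finite(lse))) {
    ggmnet_abort("numeric_failure", "degenerate densities in E-step")
  }
  z <- exp(ld - lse)
  z / rowSums(z)
}
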