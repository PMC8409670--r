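# Structural EM for Gaussian graphical mixture models: E-step responsibilities,
# weighted-moment M-step, per-component graph search under a BIC-type
# penalized likelihood, and graph-constrained covariance MLE, iterated to
# convergence of the penalized log-likelihood.

# one-hot responsibilities from hard labels
one_hot <- function(labels, K, n) {
  z <- matrix(0, n, K)
  z[cbind(seq_len(n), labels)] <- 1
  z
}

# weighted MLE moments for one component
weighted_moments <- function(X, w) {
  nk <- sum(w)
  mu <- colSums(X * w) / nk
  Xc <- sweep(X, 2L, mu)
  S <- crossprod(Xc * sqrt(w)) / nk
  list(n_eff = nk, mean = mu, S = 0.5 * (S + t(S)))
}

# a few unconstrained EM iterations to rank restart seeds (emEM-style);
# returns -Inf log-likelihood when a start degenerates
short_unconstrained_em <- function(X, z, iters = 5L) {
  n <- nrow(X); p <- ncol(X); K <- ncol(z)
  ll <- -Inf
  for (t in seq_len(iters)) {
    nk <- colSums(z)
    if (any(nk < p + 1)) return(list(ll = -Inf, z = z))
    comp <- vector("list", K)
    ok <- TRUE
    for (k in seq_len(K)) {
      m <- weighted_moments(X, z[, k])
      ch <- tryCatch(chol(m$S), error = function(e) NULL)
      if (is.null(ch) || any(diag(ch) <= sqrt(1e-8))) { ok <- FALSE; break }
      comp[[k]] <- list(mean = m$mean, covariance = m$S)
    }
    if (!ok) return(list(ll = -Inf, z = z))
    model <- list(K = K, proportions = nk / n, components = comp)
    ld <- weighted_log_density_matrix(X, model)
    lse <- row_logsumexp(ld)
    ll <- sum(lse)
    z <- exp(ld - lse)
  }
  list(ll = ll, z = z)
}

# seeded k-means hard partition converted to responsibilities
kmeans_init <- function(X, K, seed) {
  set.seed(seed)
  n <- nrow(X)
  if (K == 1L) return(matrix(1, n, 1L))
  km <- tryCatch(
    stats::kmeans(X, centers = K, nstart = 1L, iter.max = 50L),
    error = function(e) NULL)
  if (is.null(km)) {
    labels <- sample(rep_len(seq_len(K), n))
  } else {
    labels <- km$cluster
  }
  one_hot(labels, K, n)
}

#' Fit a Gaussian graphical mixture model by structural EM
#'
#' Fits a `K`-component mixture of multivariate Gaussians whose component
#' covariances are constrained to undirected graph structures learned during
#' fitting. Each iteration alternates the E-step (posterior
#' responsibilities), a weighted-moment M-step (mixing proportions, means,
#' per-component weighted sample covariances), a per-component graph search
#' maximizing the BIC-type penalized profile likelihood (see
#' [structure_search()]; effective sample size = the component's
#' responsibility mass), and the graph-constrained covariance MLE
#' ([constrained_covariance_mle()]). Iteration stops when the relative change
#' in the penalized log-likelihood drops below `tolerance`.
#'
#' Initialization uses `n_restarts` seeded k-means hard partitions, each
#' refined by a short unconstrained EM burn-in; the best-scoring start then
#' runs the full structural EM. Within structural EM the graph search warm
#' starts from the previous iteration's graph (the first iteration searches
#' from the empty graph).
#'
#' A component whose responsibility mass falls below `p + 1`, or whose
#' constrained covariance is not positive definite (minimum eigenvalue below
#' 1e-8), aborts the fit with a typed failure condition rather than silently
#' regularizing; [select_ggmm()] records these as failure records.
#'
#' @param data matrix or data frame, rows = subjects, columns = variables.
#' @param K number of mixture components (>= 1).
#' @param max_iterations maximum structural-EM iterations (default 500).
#' @param tolerance relative penalized log-likelihood change declaring
#'   convergence (default 1e-6).
#' @param n_restarts independent seeded initializations (default 10).
#' @param seed single integer seed governing all randomness of the fit.
#' @param beta extra tuning weight on the per-edge structure penalty
#'   (default 0, the plain BIC-type penalty).
#' @param search_strategy `"greedy_stepwise"` (default) or `"exhaustive"`
#'   (p <= 5 only).
#' @param structure `"search"` learns each component's graph; `"complete"` or
#'   `"empty"` fixes all graphs (the former reduces the model to an ordinary
#'   Gaussian mixture).
#' @param init_resp optional `n x K` responsibility matrix to start from,
#'   bypassing the restart scheme (useful for controlled comparisons).
#' @param ipf_tol,ipf_max_sweeps constrained-MLE control.
#' @return an object of class `ggmm`: proportions, per-component means,
#'   covariances, precisions and graphs, log-likelihood, penalized
#'   log-likelihood trace, parameter count, BIC, iteration count, convergence
#'   flag and seed.
#' @seealso [select_ggmm()], [classify()], [covariance_network()]
#' @examples
#' sim <- psychopathology_fixture(n = 300, seed = 1)
#' fit <- fit_ggmm(sim$data, K = 2, n_restarts = 2, seed = 1)
#' glance(fit)
#' @export
fit_ggmm <- function(data, K, max_iterations = 500L, tolerance = 1e-6,
                     n_restarts = 10L, seed = 1L, beta = 0,
                     search_strategy = c("greedy_stepwise", "exhaustive"),
                     structure = c("search", "complete", "empty"),
                     init_resp = NULL, ipf_tol = 1e-8, ipf_max_sweeps = 2000L) {
  X <- as_data_matrix(data)
  n <- nrow(X); p <- ncol(X)
  K <- as.integer(K)
  search_strategy <- match.arg(search_strategy)
  structure <- match.arg(structure)
  if (K < 1L) ggmnet_abort("bad_dimensions", "K must be at least 1")
  if (search_strategy == "exhaustive" && p > 5L) {
    ggmnet_abort("unsupported", "exhaustive search supports at most 5 variables")
  }
  if (n <= K * (p + 1)) {
    warn(sprintf("n = %d is small for K = %d components with p = %d variables",
                 n, K, p))
  }

  # --- initialization -------------------------------------------------------
  if (!is.null(init_resp)) {
    z <- as.matrix(init_resp)
    if (nrow(z) != n || ncol(z) != K) {
      ggmnet_abort("bad_dimensions", "init_resp must be n x K")
    }
  } else if (K == 1L) {
    z <- matrix(1, n, 1L)
  } else {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      z0 <- kmeans_init(X, K, seed = seed + r - 1L)
      cand <- short_unconstrained_em(X, z0)
      if (is.null(best) || cand$ll > best$ll) best <- cand
    }
    if (!is.finite(best$ll)) {
      ggmm_fail("empty_component",
                sprintf("no initialization supports %d components", K), K = K)
    }
    z <- best$z
  }

  # --- structural EM --------------------------------------------------------
  adj <- replicate(K, matrix(0L, p, p), simplify = FALSE)
  comp <- vector("list", K)
  obj_trace <- ll_trace <- numeric(0)
  graphs_changed <- logical(0)
  prev_obj <- -Inf
  converged <- FALSE
  iter <- 0L

  z_mstep <- z
  while (iter < max_iterations) {
    iter <- iter + 1L
    z_mstep <- z
    nk <- colSums(z)
    if (any(nk < p + 1)) {
      ggmm_fail("empty_component", sprintf(
        "component weight %.2f below p + 1 = %d", min(nk), p + 1L), K = K)
    }
    tau <- nk / n
    changed <- FALSE
    for (k in seq_len(K)) {
      m <- weighted_moments(X, z[, k])
      if (structure == "search") {
        pen <- per_edge_penalty(m$n_eff, beta)
        res <- if (search_strategy == "greedy_stepwise") {
          cpp_greedy_search(m$S, m$n_eff, pen, adj[[k]], ipf_tol,
                            as.integer(ipf_max_sweeps))
        } else {
          cpp_exhaustive_search(m$S, m$n_eff, pen, ipf_tol,
                                as.integer(ipf_max_sweeps))
        }
        if (res$status != 0L) {
          ggmm_fail("not_positive_definite", sprintf(
            "component %d covariance became not positive definite", k), K = K)
        }
        if (!identical(res$adj, adj[[k]])) changed <- TRUE
        adj[[k]] <- res$adj
        sigma <- res$sigma; omega <- res$omega
        n_edges_k <- res$n_edges
        pen_k <- pen * n_edges_k
      } else if (structure == "complete") {
        sigma <- m$S
        ch <- tryCatch(chol(sigma), error = function(e) NULL)
        if (is.null(ch)) {
          ggmm_fail("not_positive_definite", sprintf(
            "component %d covariance became not positive definite", k), K = K)
        }
        omega <- chol2inv(ch)
        adj[[k]] <- as_adjacency(complete_graph(p))
        n_edges_k <- p * (p - 1) / 2
        pen_k <- per_edge_penalty(m$n_eff, beta) * n_edges_k
      } else {
        sigma <- diag(diag(m$S), p)
        omega <- diag(1 / diag(m$S), p)
        adj[[k]] <- matrix(0L, p, p)
        n_edges_k <- 0L
        pen_k <- 0
      }
      ev_min <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
      if (ev_min <= 1e-8) {
        ggmm_fail("not_positive_definite", sprintf(
          "component %d covariance min eigenvalue %.3g <= 1e-8", k, ev_min),
          K = K)
      }
      comp[[k]] <- list(mean = m$mean, covariance = sigma, precision = omega,
                        n_eff = m$n_eff, n_edges = n_edges_k, penalty = pen_k)
    }
    model_now <- list(K = K, proportions = tau, components = comp)
    ld <- weighted_log_density_matrix(X, model_now)
    lse <- row_logsumexp(ld)
    ll <- sum(lse)
    z <- exp(ld - lse)
    obj <- ll - sum(vapply(comp, `[[`, numeric(1), "penalty"))
    ll_trace <- c(ll_trace, ll)
    obj_trace <- c(obj_trace, obj)
    graphs_changed <- c(graphs_changed, changed)
    if (iter > 1L &&
        abs(obj - prev_obj) < tolerance * (abs(prev_obj) + 1e-10)) {
      converged <- TRUE
      prev_obj <- obj
      break
    }
    prev_obj <- obj
  }

  components <- lapply(seq_len(K), function(k) {
    g <- graph_from_adjacency01(adj[[k]])
    sigma <- comp[[k]]$covariance
    dimnames(sigma) <- list(colnames(X), colnames(X))
    list(mean = setNames(comp[[k]]$mean, colnames(X)),
         covariance = sigma,
         precision = comp[[k]]$precision,
         graph = g,
         n_eff = comp[[k]]$n_eff)
  })
  n_params <- (K - 1L) + K * p +
    sum(vapply(components, function(cc) p + n_edges(cc$graph), numeric(1)))
  fit <- structure(list(
    K = K,
    proportions = colSums(z) / n,
    components = components,
    log_likelihood = ll_trace[length(ll_trace)],
    penalized_loglik = prev_obj,
    n_params = as.integer(n_params),
    bic = NA_real_,
    n = n,
    variable_names = colnames(X),
    n_iterations = iter,
    converged = converged,
    seed = as.integer(seed),
    beta = beta,
    structure = structure,
    objective_trace = obj_trace,
    loglik_trace = ll_trace,
    graphs_changed = graphs_changed,
    responsibilities = z,        # posterior at the returned parameters
    mstep_weights = z_mstep      # weights that produced those parameters
  ), class = "ggmm")
  fit$bic <- model_bic(fit, n)
  fit
}

#' Bayesian information criterion of a fitted GGMM
#'
#' `-2 * log-likelihood + n_params * log(n)`; lower is better. The parameter
#' count is `(K - 1)` mixing proportions plus `K * p` means plus, per
#' component, `p` variances and one covariance per edge.
#'
#' @param model a fitted `ggmm`.
#' @param n number of observations the model was fitted on.
#' @export
model_bic <- function(model, n) {
  -2 * model$log_likelihood + model$n_params * log(n)
}

#' @export
print.ggmm <- function(x, ...) {
  cat(sprintf(
    "<ggmm: K = %d, p = %d, n = %d>\n  log-likelihood %.3f, BIC %.3f (%d params)\n  %s after %d iterations\n",
    x$K, length(x$variable_names), x$n, x$log_likelihood, x$bic, x$n_params,
    if (x$converged) "converged" else "not converged", x$n_iterations))
  cat("  edges per component:",
      paste(vapply(x$components, function(cc) n_edges(cc$graph), numeric(1)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Select the number of clusters by BIC
#'
#' Fits a GGMM for every candidate `K` and returns the fit with the lowest
#' BIC. Candidate values whose fit fails (non-positive-definite component
#' covariance, component weight collapsing below `p + 1`, no convergence) are
#' recorded as failure records and excluded from the comparison rather than
#' aborting the sweep.
#'
#' @param data matrix or data frame, rows = subjects.
#' @param K_range ascending integer vector of candidate component counts.
#' @param ... passed on to [fit_ggmm()].
#' @param seed integer seed reused for every candidate fit.
#' @return an object of class `ggmm_selection`: the selected `model`, all
#'   successful `fits`, a `bic_table` tibble (one row per candidate), and a
#'   `failures` tibble.
#' @examples
#' sim <- psychopathology_fixture(n = 400, seed = 2)
#' sel <- select_ggmm(sim$data, K_range = 1:2, n_restarts = 2, seed = 1)
#' sel$bic_table
#' @export
select_ggmm <- function(data, K_range = 1:5, ..., seed = 1L) {
  K_range <- as.integer(K_range)
  if (length(K_range) == 0L || is.unsorted(K_range)) {
    ggmnet_abort("bad_dimensions", "K_range must be non-empty and ascending")
  }
  fits <- list()
  failures <- tibble::tibble(K = integer(), reason = character(),
                             detail = character())
  rows <- list()
  for (K in K_range) {
    res <- tryCatch(
      fit_ggmm(data, K = K, seed = seed, ...),
      ggmnet_failure = function(cond) cond)
    if (inherits(res, "ggmm")) {
      fits[[as.character(K)]] <- res
      rows[[as.character(K)]] <- tibble::tibble(
        K = K, status = "ok", bic = res$bic,
        log_likelihood = res$log_likelihood, n_params = res$n_params,
        converged = res$converged, reason = NA_character_)
    } else {
      failures <- dplyr::bind_rows(failures, failure_record(res, K))
      rows[[as.character(K)]] <- tibble::tibble(
        K = K, status = "failed", bic = NA_real_,
        log_likelihood = NA_real_, n_params = NA_integer_,
        converged = NA, reason = res$reason %||% "no_convergence")
    }
  }
  bic_table <- dplyr::bind_rows(rows)
  if (length(fits) == 0L) {
    ggmnet_abort("no_valid_model", "every candidate K failed to fit")
  }
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  best <- fits[[which.min(bics)]]
  structure(list(model = best, fits = fits, bic_table = bic_table,
                 failures = failures, K_range = K_range, seed = seed),
            class = "ggmm_selection")
}

#' @export
print.ggmm_selection <- function(x, ...) {
  cat(sprintf("<ggmm_selection: K in {%s}, selected K = %d>\n",
              paste(x$K_range, collapse = ", "), x$model$K))
  print(x$bic_table)
  invisible(x)
}

#' Maximum a posteriori cluster labels
#'
#' Assigns each row of `data` to the component with the largest posterior
#' responsibility; ties break to the lowest component index.
#'
#' @param model a fitted `ggmm` (or the `model` of a `ggmm_selection`).
#' @param data matrix or data frame matching the model's variables.
#' @return integer vector of cluster labels in `1..K`.
#' @export
classify <- function(model, data) {
  if (inherits(model, "ggmm_selection")) model <- model$model
  z <- e_step(data, model)
  max.col(z, ties.method = "first")
}

#' Cross-tabulate cluster labels against a grouping
#'
#' Counts subjects by group and cluster, with row and column totals — the
#' cluster-by-diagnosis concordance table.
#'
#' @param labels integer cluster labels.
#' @param groups categorical vector of the same length (e.g. diagnostic
#'   labels).
#' @return a tibble with one row per group plus a `Total` row, and one
#'   `cluster_k` column per cluster plus a `Total` column.
#' @export
cluster_crosstab <- function(labels, groups) {
  if (length(labels) != length(groups)) {
    ggmnet_abort("bad_dimensions", "labels and groups must have equal length")
  }
  labels <- as.integer(labels)
  K <- max(labels)
  tab <- table(group = as.character(groups),
               cluster = factor(labels, levels = seq_len(K)))
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = dimnames(tab))
  out <- tibble::as_tibble(counts, .name_repair = "minimal")
  names(out) <- paste0("cluster_", seq_len(K))
  out <- dplyr::bind_cols(tibble::tibble(group = rownames(tab)), out)
  out$Total <- unname(rowSums(counts))
  total_row <- c(list(group = "Total"),
                 lapply(out[, -1, drop = FALSE], function(x) unname(sum(x))))
  dplyr::bind_rows(out, tibble::as_tibble(total_row))
}

#' Per-cluster covariance network
#'
#' The covariance network estimated jointly with the clustering: edge weights
#' are the fitted component covariances on the learned graph's edges, zero
#' elsewhere, with a zero diagonal.
#'
#' @param model a fitted `ggmm`.
#' @param k component index in `1..K`.
#' @return a [weighted_network()] on the covariance scale.
#' @export
covariance_network <- function(model, k) {
  if (inherits(model, "ggmm_selection")) model <- model$model
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > model$K) {
    ggmnet_abort("bad_index", sprintf("k must be in 1..%d", model$K))
  }
  cc <- model$components[[k]]
  w <- cc$covariance * as_adjacency(cc$graph)
  diag(w) <- 0
  weighted_network(w, variable_names = model$variable_names,
                   scale = "covariance")
}
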