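# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: densities via the literal closed form, geodesics
# via exhaustive simple-path enumeration, an independently coded plain
# Gaussian-mixture EM, and ARI from mclust.

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# literal multivariate normal log-density: -1/2 (p log 2pi + log det + quad)
oracle_mvn_logdens <- function(x, mu, sigma) {
  p <- length(x)
  -0.5 * (p * log(2 * pi) + determinant(sigma)$modulus[1] +
            t(x - mu) %*% solve(sigma) %*% (x - mu))[1]
}

# all simple paths between s and t with lengths 1/|w|; returns list of dists
oracle_all_paths <- function(w, s, t) {
  p <- nrow(w)
  len <- ifelse(w != 0, 1 / abs(w), Inf)
  out <- list()
  rec <- function(path, dist) {
    cur <- path[length(path)]
    if (cur == t) {
      out[[length(out) + 1]] <<- list(path = path, dist = dist)
      return()
    }
    for (nxt in seq_len(p)) {
      if (nxt %in% path || !is.finite(len[cur, nxt])) next
      rec(c(path, nxt), dist + len[cur, nxt])
    }
  }
  rec(s, 0)
  out
}

oracle_distances <- function(w) {
  p <- nrow(w)
  d <- matrix(Inf, p, p)
  diag(d) <- 0
  for (s in seq_len(p - 1)) {
    for (t in (s + 1):p) {
      paths <- oracle_all_paths(w, s, t)
      if (length(paths) > 0) {
        d[s, t] <- d[t, s] <- min(vapply(paths, `[[`, numeric(1), "dist"))
      }
    }
  }
  d
}

# fractional-counting betweenness by enumeration; endpoints excluded,
# each unordered pair counted once
oracle_betweenness <- function(w) {
  p <- nrow(w)
  b <- numeric(p)
  for (s in seq_len(p - 1)) {
    for (t in (s + 1):p) {
      paths <- oracle_all_paths(w, s, t)
      if (length(paths) == 0) next
      dists <- vapply(paths, `[[`, numeric(1), "dist")
      shortest <- paths[dists <= min(dists) + 1e-9]
      for (v in seq_len(p)) {
        if (v == s || v == t) next
        through <- sum(vapply(shortest, function(pp) v %in% pp$path,
                              logical(1)))
        b[v] <- b[v] + through / length(shortest)
      }
    }
  }
  b
}

# independently coded unconstrained Gaussian-mixture EM from a given
# responsibility start; MLE covariances (denominator n_k)
oracle_gmm_em <- function(X, z, max_iter = 2000, tol = 1e-12) {
  n <- nrow(X); p <- ncol(X); K <- ncol(z)
  ll_old <- -Inf
  ll <- NA_real_
  for (it in seq_len(max_iter)) {
    nk <- colSums(z)
    tau <- nk / n
    logd <- matrix(NA_real_, n, K)
    for (k in seq_len(K)) {
      mu <- colSums(X * z[, k]) / nk[k]
      Xc <- sweep(X, 2, mu)
      S <- crossprod(Xc * sqrt(z[, k])) / nk[k]
      S <- (S + t(S)) / 2
      ch <- chol(S)
      zz <- backsolve(ch, t(Xc), transpose = TRUE)
      logd[, k] <- log(tau[k]) - 0.5 * p * log(2 * pi) -
        sum(log(diag(ch))) - 0.5 * colSums(zz^2)
    }
    mx <- apply(logd, 1, max)
    lse <- mx + log(rowSums(exp(logd - mx)))
    ll <- sum(lse)
    z <- exp(logd - lse)
    if (abs(ll - ll_old) < tol * (abs(ll_old) + 1e-10)) break
    ll_old <- ll
  }
  list(loglik = ll, z = z)
}

# generic convex minimization of the penalized objective by proximal
# gradient (ISTA) on the precision matrix: a different algorithm family from
# the blockwise coordinate descent it checks
oracle_glasso_optim <- function(S, lambda, step = 0.05, iters = 200000,
                                tol = 1e-12) {
  p <- nrow(S)
  om <- diag(1 / diag(S), p)
  off <- !diag(p)
  for (it in seq_len(iters)) {
    grad <- solve(om) - S        # gradient of logdet - tr(S om)
    cand <- om + step * grad
    shrunk <- sign(cand) * pmax(abs(cand) - step * lambda, 0)
    cand[off] <- shrunk[off]     # diagonal unpenalized
    cand <- (cand + t(cand)) / 2
    ev <- min(eigen(cand, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 1e-10) { step <- step / 2; next }
    if (max(abs(cand - om)) < tol) { om <- cand; break }
    om <- cand
  }
  om
}

# population partial correlation of (i, j) given the rest via the Schur
# complement of the covariance: the regression-residual definition
oracle_partial_cor <- function(sigma, i, j) {
  a <- c(i, j)
  b <- setdiff(seq_len(nrow(sigma)), a)
  cond <- sigma[a, a] - sigma[a, b] %*% solve(sigma[b, b]) %*% sigma[b, a]
  cond[1, 2] / sqrt(cond[1, 1] * cond[2, 2])
}

# small two-component, p = 4 well-separated mixture used in several tests
two_component_sim <- function(n = 400, seed = 42) {
  model <- true_model(
    proportions = c(0.5, 0.5),
    means = list(rep(-5, 4), rep(5, 4)),
    graphs = list(empty_graph(4), empty_graph(4)),
    precisions = list(diag(4), diag(4))
  )
  sample_ggmm(model, n = n, seed = seed)
}

random_network <- function(p, seed, density = 0.5) {
  set.seed(seed)
  w <- matrix(0, p, p)
  idx <- which(upper.tri(w))
  on <- idx[stats::runif(length(idx)) < density]
  w[on] <- stats::runif(length(on), 0.2, 0.9) *
    sample(c(-1, 1), length(on), replace = TRUE)
  w <- w + t(w)
  weighted_network(w, variable_names = letters[seq_len(p)],
                   scale = "covariance")
}

fixture_model_for_tests <- function() {
  psychopathology_fixture(n = 1, seed = 1)$model
}
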