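test_that("lambda = 0 inverts the sample covariance", {
  set.seed(4)
  X <- MASS::mvrnorm(120, rep(0, 4), diag(4) + 0.4)
  S <- crossprod(scale(X, scale = FALSE)) / 120
  expect_equal(glasso_fit(S, 0), solve(S), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("full shrinkage empties the network", {
  S <- matrix(c(1, .5, .3, .5, 1, .2, .3, .2, 1), 3)
  om <- glasso_fit(S, lambda = 0.6)
  expect_true(all(om[upper.tri(om)] == 0))
})

test_that("p = 3 fit matches generic numeric optimization", {
  S <- diag(3)
  S[1, 2] <- S[2, 1] <- 0.5
  om <- glasso_fit(S, lambda = 0.1)
  om_opt <- oracle_glasso_optim(S, lambda = 0.1)
  expect_equal(om, om_opt, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("KKT conditions hold at the glasso solution", {
  for (seed in 1:5) {
    set.seed(seed)
    p <- 5
    X <- MASS::mvrnorm(150, rep(0, p),
                       solve(graph_constrained_precision(
                         random_graph(p, 0.5, seed), seed = seed)))
    S <- crossprod(scale(X, scale = FALSE)) / 150
    lam <- 0.3 * max(abs(S[upper.tri(S)]))
    om <- glasso_fit(S, lam)
    sig <- solve(om)
    resid <- 0
    for (i in 1:(p - 1)) for (j in (i + 1):p) {
      g <- sig[i, j] - S[i, j]
      if (om[i, j] != 0) {
        resid <- max(resid, abs(g - lam * sign(om[i, j])))
      } else {
        resid <- max(resid, max(0, abs(g) - lam))
      }
    }
    resid <- max(resid, max(abs(diag(sig) - diag(S))))
    expect_lt(resid, 1e-5)
    ev <- eigen(om, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
})

test_that("edge count is non-increasing along a descending lambda grid", {
  set.seed(12)
  X <- MASS::mvrnorm(200, rep(0, 6), diag(6) + 0.35)
  S <- crossprod(scale(X, scale = FALSE)) / 200
  lams <- exp(seq(log(max(abs(S[upper.tri(S)]))), log(0.01), length.out = 25))
  counts <- vapply(lams, function(l) {
    om <- glasso_fit(S, l)
    sum(om[upper.tri(om)] != 0)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))  # lams descending => counts ascending
})

test_that("precision converts to partial correlations correctly", {
  expect_true(all(precision_to_pcor(diag(c(2, 3, 4)))$weights == 0))
  om <- matrix(c(2, -1, -1, 2), 2)
  expect_equal(precision_to_pcor(om)$weights[1, 2], 0.5)
  # regression-residual (Schur complement) oracle on a random 4x4 precision
  set.seed(31)
  A <- matrix(rnorm(16), 4)
  om4 <- crossprod(A) + diag(4)
  pc <- precision_to_pcor(om4)$weights
  sig <- solve(om4)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(pc[i, j], oracle_partial_cor(sig, i, j), tolerance = 1e-10)
  }
  expect_error(precision_to_pcor(matrix(c(-1, 0, 0, 1), 2)),
               class = "ggmnet_invalid_precision")
})

test_that("EBIC reduces to BIC and evaluates its closed form", {
  expect_equal(ebic_score(-50, 0, 100, 5, 0.5), 100)
  expect_equal(ebic_score(-50, 3, 100, 5, 0),
               100 + 3 * log(100))
  expect_equal(ebic_score(-50, 3, exp(1), exp(1), 0.5), 100 + 3 + 6)
})

test_that("EBIC selection suppresses null edges and recovers a chain", {
  # independence: at most one spurious edge in >= 9/10 seeds
  spurious <- vapply(1:10, function(s) {
    set.seed(s)
    X <- matrix(rnorm(500 * 6), 500, 6)
    colnames(X) <- letters[1:6]
    net <- select_network(X, gamma = 0.5)
    nrow(tidy(net))
  }, numeric(1))
  expect_gte(sum(spurious <= 1), 9)

  # chain precision: every true edge detected in every seed, spurious edges
  # few and weak (EBIC-tuned glasso keeps occasional near-zero extras; it
  # does not achieve exact support recovery), and exact recovery in roughly
  # half the seeds
  p <- 6
  om <- diag(p)
  for (i in 1:(p - 1)) om[i, i + 1] <- om[i + 1, i] <- -0.35
  sig <- solve(om)
  chain_edges <- cbind(1:(p - 1), 2:p)
  res <- vapply(1:10, function(s) {
    set.seed(s)
    X <- MASS::mvrnorm(1000, rep(0, p), sig)
    colnames(X) <- letters[1:p]
    w <- select_network(X, gamma = 0.5)$weights
    mask <- upper.tri(w)
    mask[chain_edges] <- FALSE
    c(all_chain = all(w[chain_edges] != 0),
      n_spurious = sum(w[mask] != 0),
      max_spurious = max(abs(w[mask])))
  }, numeric(3))
  expect_equal(sum(res["all_chain", ]), 10)
  expect_true(all(res["n_spurious", ] <= 2))
  expect_true(all(res["max_spurious", ] < 0.05))
  expect_gte(sum(res["n_spurious", ] == 0), 4)
})

test_that("a single-lambda grid is returned as-is and ties prefer sparser", {
  set.seed(6)
  X <- MASS::mvrnorm(150, rep(0, 4), diag(4) + 0.3)
  colnames(X) <- letters[1:4]
  S <- crossprod(scale(X, scale = FALSE)) / 150
  net <- select_network(X, lambda_grid = 0.2)
  expect_equal(attr(net, "lambda"), 0.2)
  direct <- precision_to_pcor(glasso_fit(S, 0.2), letters[1:4])
  expect_equal(net$weights, direct$weights, tolerance = 1e-10)
})

test_that("networks are symmetric, zero-diagonal, bounded on every path", {
  sim <- psychopathology_fixture(n = 300, seed = 19)
  fit <- fit_ggmm(sim$data, K = 2, n_restarts = 2, seed = 2)
  labs <- classify(fit, sim$data)
  for (k in sort(unique(labs))) {
    net <- select_network(sim$data[labs == k, , drop = FALSE])
    w <- net$weights
    expect_equal(w, t(w))
    expect_equal(diag(w), rep(0, ncol(w)), ignore_attr = TRUE)
    expect_true(all(abs(w) <= 1))
  }
  expect_error(select_network(sim$data[0, ]), class = "ggmnet_empty_cluster")
})
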