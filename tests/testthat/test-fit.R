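test_that("K = 1 with a complete graph recovers the sample moments", {
  set.seed(11)
  X <- MASS::mvrnorm(80, c(1, -1, 0), diag(3) + 0.4)
  colnames(X) <- c("a", "b", "c")
  fit <- fit_ggmm(X, K = 1, structure = "complete", seed = 1)
  S <- crossprod(scale(X, scale = FALSE)) / 80
  expect_equal(unname(fit$components[[1]]$mean), unname(colMeans(X)),
               tolerance = 1e-8)
  expect_equal(unname(fit$components[[1]]$covariance), unname(S),
               tolerance = 1e-8)
  expect_equal(fit$proportions, 1)
})

test_that("well-separated components are recovered exactly", {
  sim <- two_component_sim(n = 400, seed = 42)
  fit <- fit_ggmm(sim$data, K = 2, n_restarts = 3, seed = 1)
  labs <- classify(fit, sim$data)
  expect_equal(ari(labs, sim$labels), 1.0)
  expect_true(fit$converged)
})

test_that("complete-graph fits match an independently coded GMM EM", {
  sim <- two_component_sim(n = 200, seed = 9)
  X <- as.matrix(sim$data)
  set.seed(5)
  km <- kmeans(X, centers = 2, nstart = 1)
  z0 <- matrix(0, nrow(X), 2)
  z0[cbind(seq_len(nrow(X)), km$cluster)] <- 1
  fit <- fit_ggmm(X, K = 2, structure = "complete", init_resp = z0,
                  tolerance = 1e-12, max_iterations = 3000, seed = 1)
  oracle <- oracle_gmm_em(X, z0)
  expect_equal(fit$log_likelihood, oracle$loglik, tolerance = 1e-6)
})

test_that("penalized objective is monotone at fixed graph structures", {
  sim <- psychopathology_fixture(n = 600, seed = 21)
  fit <- fit_ggmm(sim$data, K = 3, n_restarts = 2, seed = 3)
  tr <- fit$objective_trace
  same_graph <- !fit$graphs_changed
  for (t in seq_along(tr)[-1]) {
    if (same_graph[t]) {
      expect_gte(tr[t], tr[t - 1] - 1e-6 * abs(tr[t - 1]))
    }
  }
})

test_that("fitted components satisfy the precision-support invariant", {
  sim <- psychopathology_fixture(n = 600, seed = 8)
  fit <- fit_ggmm(sim$data, K = 2, n_restarts = 2, seed = 2)
  for (cc in fit$components) {
    adj <- as_adjacency(cc$graph)
    off <- cc$precision * (1 - adj)
    diag(off) <- 0
    expect_lt(max(abs(off)), 1e-6)
    ev <- eigen(cc$covariance, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 1e-8)
  }
  expect_equal(sum(fit$proportions), 1, tolerance = 1e-10)
})

test_that("column permutation permutes parameters and preserves fit", {
  sim <- psychopathology_fixture(n = 500, seed = 13)
  X <- as.matrix(sim$data)
  perm <- c(4, 1, 12, 6, 2, 9, 3, 11, 5, 8, 10, 7)
  fit1 <- fit_ggmm(X, K = 2, n_restarts = 2, seed = 6)
  fit2 <- fit_ggmm(X[, perm], K = 2, n_restarts = 2, seed = 6)
  expect_equal(fit1$log_likelihood, fit2$log_likelihood, tolerance = 1e-6)
  expect_equal(fit1$bic, fit2$bic, tolerance = 1e-6)
  expect_equal(classify(fit1, X), classify(fit2, X[, perm]))
  for (k in 1:2) {
    expect_equal(unname(fit2$components[[k]]$mean),
                 unname(fit1$components[[k]]$mean[perm]), tolerance = 1e-6)
    expect_equal(unname(fit2$components[[k]]$covariance),
                 unname(fit1$components[[k]]$covariance[perm, perm]),
                 tolerance = 1e-6)
  }
})

test_that("parameter counting follows the free-parameter formula", {
  # K=1, p=2, complete: 0 + 2 + (2 + 1) = 5
  set.seed(2)
  X2 <- MASS::mvrnorm(60, c(0, 0), diag(2) + 0.5)
  f1 <- fit_ggmm(X2, K = 1, structure = "complete", seed = 1)
  expect_equal(f1$n_params, 5L)
  expect_equal(model_bic(f1, 60),
               -2 * f1$log_likelihood + 5 * log(60))
  # K=1, p=3, empty graph: 3 + 3 = 6
  X3 <- MASS::mvrnorm(60, rep(0, 3), diag(3))
  f2 <- fit_ggmm(X3, K = 1, structure = "empty", seed = 1)
  expect_equal(f2$n_params, 6L)
  # K=3, p=12, all complete: 2 + 36 + 3 * (12 + 66) = 272
  sim <- psychopathology_fixture(n = 700, seed = 3)
  f3 <- fit_ggmm(sim$data, K = 3, structure = "complete", n_restarts = 2,
                 seed = 1)
  expect_equal(f3$n_params, 272L)
})

test_that("BIC selection picks the true K on separated data", {
  sim <- two_component_sim(n = 400, seed = 7)
  sel <- select_ggmm(sim$data, K_range = 1:4, n_restarts = 3, seed = 2)
  expect_equal(sel$model$K, 2L)
  expect_equal(nrow(sel$bic_table), 4L)
})

test_that("degenerate K values fail typed and selection proceeds", {
  sim <- psychopathology_fixture(n = 20, seed = 5)
  sel <- select_ggmm(sim$data, K_range = 1:2, n_restarts = 2, seed = 1)
  expect_equal(sel$model$K, 1L)
  expect_gte(nrow(sel$failures), 1L)
  expect_true(all(sel$failures$reason %in%
                    c("empty_component", "not_positive_definite",
                      "no_convergence")))
  # single-candidate sweep returns that fit with no failures
  sel1 <- select_ggmm(sim$data, K_range = 1L, n_restarts = 2, seed = 1)
  expect_equal(sel1$model$K, 1L)
  expect_equal(nrow(sel1$failures), 0L)
})

test_that("MAP labels equal brute-force density comparison", {
  sim <- two_component_sim(n = 150, seed = 3)
  fit <- fit_ggmm(sim$data, K = 2, n_restarts = 2, seed = 4)
  labs <- classify(fit, sim$data)
  X <- as.matrix(sim$data)
  brute <- apply(X, 1, function(x) {
    scores <- vapply(1:2, function(k) {
      log(fit$proportions[k]) +
        oracle_mvn_logdens(x, fit$components[[k]]$mean,
                           fit$components[[k]]$covariance)
    }, numeric(1))
    which.max(scores)
  })
  expect_equal(labs, unname(brute))
  # point at a component mean of a separated model takes that label
  at_mu1 <- matrix(fit$components[[1]]$mean, 1,
                   dimnames = list(NULL, fit$variable_names))
  expect_equal(classify(fit, rbind(at_mu1, at_mu1))[1], 1L)
})

test_that("cross-tabulation counts and margins are exact", {
  tab <- cluster_crosstab(c(1, 1, 2), c("A", "B", "A"))
  expect_equal(tab$cluster_1, c(1, 1, 2))
  expect_equal(tab$cluster_2, c(1, 0, 1))
  expect_equal(tab$Total, c(2, 1, 3))
  # single group: row equals label frequencies
  tab2 <- cluster_crosstab(c(1, 2, 2, 3), rep("g", 4))
  expect_equal(unlist(tab2[1, c("cluster_1", "cluster_2", "cluster_3")]),
               c(cluster_1 = 1, cluster_2 = 2, cluster_3 = 1))
  # random fixture: margins reproduce independent tallies
  set.seed(99)
  labs <- sample(1:3, 200, replace = TRUE)
  grp <- sample(letters[1:4], 200, replace = TRUE)
  tab3 <- cluster_crosstab(labs, grp)
  expect_equal(tab3$Total[tab3$group == "Total"], 200)
  for (g in letters[1:4]) {
    expect_equal(tab3$Total[tab3$group == g], sum(grp == g))
  }
  for (k in 1:3) {
    expect_equal(tab3[[paste0("cluster_", k)]][tab3$group == "Total"],
                 sum(labs == k))
  }
})

test_that("component covariance networks mask by the learned graph", {
  sim <- psychopathology_fixture(n = 500, seed = 17)
  fit <- fit_ggmm(sim$data, K = 2, n_restarts = 2, seed = 2)
  net <- covariance_network(fit, 1)
  adj <- as_adjacency(fit$components[[1]]$graph)
  expect_equal(net$weights[adj == 1],
               fit$components[[1]]$covariance[adj == 1])
  expect_true(all(net$weights[adj == 0 & diag(12) == 0] == 0))
  expect_equal(diag(net$weights), rep(0, 12), ignore_attr = TRUE)
  expect_error(covariance_network(fit, 3), class = "ggmnet_bad_index")
  # empty and complete graph components reduce trivially
  f_empty <- fit_ggmm(sim$data, K = 1, structure = "empty", seed = 1)
  expect_true(all(covariance_network(f_empty, 1)$weights == 0))
  f_full <- fit_ggmm(sim$data, K = 1, structure = "complete", seed = 1)
  w <- covariance_network(f_full, 1)$weights
  off <- upper.tri(w)
  expect_equal(w[off], f_full$components[[1]]$covariance[off])
})

test_that("tidiers summarize fits as tibbles", {
  sim <- two_component_sim(n = 150, seed = 2)
  fit <- fit_ggmm(sim$data, K = 2, n_restarts = 2, seed = 1)
  td <- tidy(fit)
  expect_equal(nrow(td), 8L)  # K * p rows
  expect_true(all(c("component", "variable", "mean", "variance") %in%
                    names(td)))
  gl <- glance(fit)
  expect_equal(gl$K, 2L)
  expect_s3_class(autoplot(fit), "ggplot")
})
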