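chain_net <- function() {
  w <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  w["a", "b"] <- w["b", "a"] <- 0.5
  w["b", "c"] <- w["c", "b"] <- 0.5
  weighted_network(w, scale = "covariance")
}

signed_net <- function() {
  w <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  w["a", "b"] <- w["b", "a"] <- 0.5
  w["b", "c"] <- w["c", "b"] <- -0.3
  weighted_network(w, scale = "covariance")
}

test_that("strength and expected influence are absolute and signed sums", {
  net <- signed_net()
  expect_equal(net_strength(net), c(a = 0.5, b = 0.8, c = 0.3))
  expect_equal(net_expected_influence(net), c(a = 0.5, b = 0.2, c = -0.3))
  empty <- weighted_network(matrix(0, 3, 3))
  expect_equal(unname(net_strength(empty)), rep(0, 3))
  # all-positive network: the two coincide
  pos <- chain_net()
  expect_equal(net_strength(pos), net_expected_influence(pos))
  # naive double-loop oracle on a random signed network
  net6 <- random_network(6, seed = 5)
  s <- numeric(6); e <- numeric(6)
  for (i in 1:6) for (j in 1:6) {
    s[i] <- s[i] + abs(net6$weights[i, j])
    e[i] <- e[i] + net6$weights[i, j]
  }
  expect_equal(unname(net_strength(net6)), s)
  expect_equal(unname(net_expected_influence(net6)), e)
})

test_that("geodesics use inverse absolute weights", {
  d <- shortest_path_lengths(chain_net())
  expect_equal(d["a", "b"], 2)
  expect_equal(d["b", "c"], 2)
  expect_equal(d["a", "c"], 4)
  # complete unit-weight network: all off-diagonal distances 1
  w <- matrix(1, 4, 4); diag(w) <- 0
  d4 <- shortest_path_lengths(weighted_network(w))
  expect_equal(unname(d4[upper.tri(d4)]), rep(1, 6))
  # isolated node: infinite distances
  w5 <- matrix(0, 3, 3); w5[1, 2] <- w5[2, 1] <- 1
  d5 <- shortest_path_lengths(weighted_network(w5))
  expect_true(all(is.infinite(d5[3, -3])))
})

test_that("closeness inverts summed distances, zero when disconnected", {
  expect_equal(net_closeness(chain_net())[["b"]], 0.25)
  w <- matrix(1, 4, 4); diag(w) <- 0
  expect_equal(unname(net_closeness(weighted_network(w))), rep(1 / 3, 4))
  w5 <- matrix(0, 3, 3); w5[1, 2] <- w5[2, 1] <- 1
  expect_equal(unname(net_closeness(weighted_network(w5))[3]), 0)
})

test_that("betweenness matches brute-force path enumeration", {
  expect_equal(unname(net_betweenness(chain_net())), c(0, 1, 0))
  w <- matrix(1, 5, 5); diag(w) <- 0
  expect_equal(unname(net_betweenness(weighted_network(w))), rep(0, 5))
  for (seed in c(2, 7, 23)) {
    net <- random_network(7, seed = seed)
    expect_equal(unname(net_betweenness(net)),
                 oracle_betweenness(net$weights), tolerance = 1e-9)
    expect_equal(unname(shortest_path_lengths(net)),
                 oracle_distances(net$weights), tolerance = 1e-9)
  }
})

test_that("bridge indexes sum only cross-community edges", {
  net <- signed_net()
  comm <- c(a = "C1", b = "C1", c = "C2")
  expect_equal(bridge_strength(net, comm),
               c(a = 0, b = 0.3, c = 0.3))
  expect_equal(bridge_expected_influence(net, comm),
               c(a = 0, b = -0.3, c = -0.3))
  # single community: all zeros
  one <- c(a = "X", b = "X", c = "X")
  expect_equal(unname(bridge_strength(net, one)), rep(0, 3))
  expect_equal(unname(bridge_expected_influence(net, one)), rep(0, 3))
  # masked-sum oracle on a random instance
  net6 <- random_network(6, seed = 8)
  comm6 <- setNames(sample(c("P", "Q", "R"), 6, replace = TRUE),
                    net6$variable_names)
  bs <- numeric(6); be <- numeric(6)
  for (i in 1:6) for (j in 1:6) {
    if (comm6[i] != comm6[j]) {
      bs[i] <- bs[i] + abs(net6$weights[i, j])
      be[i] <- be[i] + net6$weights[i, j]
    }
  }
  expect_equal(unname(bridge_strength(net6, comm6)), bs)
  expect_equal(unname(bridge_expected_influence(net6, comm6)), be)
  expect_error(bridge_strength(net6, comm6[-1]),
               class = "ggmnet_missing_community")
})

test_that("strength dominates expected influence everywhere", {
  for (seed in 1:5) {
    net <- random_network(6, seed = seed)
    comm <- setNames(rep(c("A", "B"), 3), net$variable_names)
    expect_true(all(net_strength(net) >=
                      abs(net_expected_influence(net)) - 1e-12))
    expect_true(all(bridge_strength(net, comm) >=
                      abs(bridge_expected_influence(net, comm)) - 1e-12))
  }
})

test_that("rescaling weights scales indexes covariantly", {
  net <- random_network(6, seed = 14)
  c0 <- 2.5
  net2 <- weighted_network(net$weights * c0,
                           variable_names = net$variable_names)
  expect_equal(net_strength(net2), c0 * net_strength(net))
  expect_equal(net_expected_influence(net2),
               c0 * net_expected_influence(net))
  expect_equal(shortest_path_lengths(net2),
               shortest_path_lengths(net) / c0)
  expect_equal(net_betweenness(net2), net_betweenness(net))
})

test_that("z-standardization uses the population SD", {
  expect_equal(z_standardize(c(1, 2, 3)),
               c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  z <- z_standardize(rnorm(10))
  expect_equal(z_standardize(z), z, tolerance = 1e-12)
  expect_error(z_standardize(rep(2, 5)),
               class = "ggmnet_degenerate_values")
})

test_that("centrality tables carry raw and z columns with zero mean unit SD", {
  net <- random_network(8, seed = 3)
  comm <- setNames(rep(c("A", "B"), 4), net$variable_names)
  tab <- centrality_table(net, communities = comm)
  expect_equal(nrow(tab), 8L)
  for (col in c("z_strength", "z_expected_influence", "z_closeness",
                "z_betweenness", "z_bridge_strength",
                "z_bridge_expected_influence")) {
    v <- tab[[col]]
    if (all(is.na(v))) next
    expect_equal(mean(v), 0, tolerance = 1e-10)
    expect_equal(sqrt(mean((v - mean(v))^2)), 1, tolerance = 1e-10)
  }
  long <- centrality_table(net, communities = comm, long = TRUE)
  expect_true(all(c("node", "index", "value", "z") %in% names(long)))
  expect_equal(nrow(long), 8L * 6L)
  expect_s3_class(plot_centrality(tab), "ggplot")
})

test_that("merging communities into one kills the bridge indexes", {
  net <- random_network(6, seed = 20)
  merged <- setNames(rep("ALL", 6), net$variable_names)
  expect_true(all(bridge_strength(net, merged) == 0))
  expect_true(all(bridge_expected_influence(net, merged) == 0))
})
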