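# Synthetic graph-structured Gaussian mixture data with known ground truth,
# including a 12-variable, 4-cluster psychopathology-style fixture. All
# numeric constants in the fixture are invented package constants chosen for
# clear cluster recoverability, not estimates from any empirical dataset.

#' Erdős–Rényi random graph structure
#'
#' Each of the `p(p-1)/2` possible edges is included independently with
#' probability `density`.
#'
#' @param p number of nodes (>= 2).
#' @param density edge probability in \[0, 1\].
#' @param seed integer seed; identical seeds give identical graphs.
#' @return a [graph_structure()].
#' @export
random_graph <- function(p, density, seed = 1L) {
  if (p < 2L) ggmnet_abort("bad_graph", "need p >= 2")
  if (density < 0 || density > 1) ggmnet_abort("bad_graph", "density in [0,1]")
  set.seed(seed)
  pairs <- t(utils::combn(p, 2L))
  keep <- stats::runif(nrow(pairs)) < density
  graph_structure(p, pairs[keep, , drop = FALSE])
}

#' Random precision matrix supported on a graph
#'
#' Draws edge precisions uniformly from `weight_range` with random signs and
#' sets off-graph entries to exact zero; the diagonal is inflated to the row
#' absolute sum plus `margin`, so the matrix is strictly diagonally dominant
#' and hence positive definite.
#'
#' @param graph a [graph_structure()].
#' @param weight_range length-2 positive interval for absolute edge weights.
#' @param seed integer seed.
#' @param margin diagonal dominance margin (default 0.1).
#' @return a `p x p` positive-definite precision matrix with zeros exactly
#'   off-graph.
#' @export
graph_constrained_precision <- function(graph, weight_range = c(0.25, 0.6),
                                        seed = 1L, margin = 0.1) {
  stopifnot(inherits(graph, "graph_structure"))
  set.seed(seed)
  p <- graph$p
  omega <- matrix(0, p, p)
  m <- n_edges(graph)
  if (m > 0L) {
    w <- stats::runif(m, weight_range[1], weight_range[2]) *
      sample(c(-1, 1), m, replace = TRUE)
    omega[graph$edges] <- w
    omega[graph$edges[, 2:1, drop = FALSE]] <- w
  }
  diag(omega) <- rowSums(abs(omega)) + margin
  omega
}

#' Ground-truth graph-structured mixture model
#'
#' Bundles the generating parameters of a mixture whose component precisions
#' are supported on known graphs, for use with [sample_ggmm()].
#'
#' @param proportions mixing proportions (positive, summing to 1).
#' @param means list of K mean vectors of length `p`.
#' @param graphs list of K [graph_structure()]s.
#' @param precisions list of K positive-definite precision matrices with
#'   zeros exactly off the matching graph.
#' @param variable_names optional variable names.
#' @param communities optional named community map over the variables.
#' @return an object of class `ggmm_true_model`.
#' @export
true_model <- function(proportions, means, graphs, precisions,
                       variable_names = NULL, communities = NULL) {
  K <- length(proportions)
  if (length(means) != K || length(graphs) != K || length(precisions) != K) {
    ggmnet_abort("bad_dimensions", "component lists must all have length K")
  }
  if (abs(sum(proportions) - 1) > 1e-10 || any(proportions <= 0)) {
    ggmnet_abort("bad_dimensions", "proportions must be positive and sum to 1")
  }
  p <- length(means[[1]])
  for (k in seq_len(K)) {
    om <- precisions[[k]]
    adj <- as_adjacency(graphs[[k]])
    off <- om * (1 - adj)
    diag(off) <- 0
    if (any(off != 0)) {
      ggmnet_abort("bad_graph", sprintf(
        "precision %d has nonzeros off its graph", k))
    }
    ev <- min(eigen(om, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 0) {
      ggmnet_abort("bad_network", sprintf("precision %d is not PD", k))
    }
  }
  if (is.null(variable_names)) variable_names <- paste0("V", seq_len(p))
  structure(list(K = K, proportions = proportions, means = means,
                 graphs = graphs, precisions = precisions,
                 variable_names = variable_names, communities = communities),
            class = "ggmm_true_model")
}

#' Sample from a graph-structured Gaussian mixture
#'
#' Component labels are drawn from the mixing proportions, then each row from
#' its component's Gaussian (covariance = inverse of the generating
#' precision). Deterministic per seed.
#'
#' @param model a [true_model()].
#' @param n number of rows (>= 1).
#' @param seed integer seed.
#' @return a list with `data` (tibble, `n x p`) and `labels` (integer vector).
#' @export
sample_ggmm <- function(model, n, seed = 1L) {
  stopifnot(inherits(model, "ggmm_true_model"), n >= 1)
  set.seed(seed)
  K <- model$K
  p <- length(model$means[[1]])
  labels <- sample.int(K, n, replace = TRUE, prob = model$proportions)
  X <- matrix(NA_real_, n, p)
  for (k in seq_len(K)) {
    rows <- which(labels == k)
    if (length(rows) == 0L) next
    sigma <- solve(model$precisions[[k]])
    X[rows, ] <- MASS::mvrnorm(length(rows), mu = model$means[[k]],
                               Sigma = sigma)
  }
  colnames(X) <- model$variable_names
  list(data = tibble::as_tibble(X), labels = labels)
}

# fixture constants (invented): symptom-factor names, disorder communities,
# mean profiles on a "strong = 3.5 / moderate = 1.5 / weak = 0" scale, and
# sparse precisions with the OCD block mutually connected in every component
fixture_variables <- function() {
  c("MDD1", "MDD2", "PD1", "PD2", "PD3", "SAD",
    "OCD1", "OCD2", "OCD3", "OCD4", "OCD5", "OCD6")
}

fixture_communities <- function() {
  setNames(c("MDD", "MDD", "PD", "PD", "PD", "SAD", rep("OCD", 6)),
           fixture_variables())
}

fixture_mean <- function(mdd, pd, sad, ocd) {
  c(rep(mdd, 2), rep(pd, 3), sad, rep(ocd, 6))
}

# builds one component precision: diag 2.5, OCD clique at -0.25, plus the
# given extra edges with stated values
fixture_precision <- function(extra) {
  vars <- fixture_variables()
  p <- length(vars)
  omega <- matrix(0, p, p, dimnames = list(vars, vars))
  ocd <- 7:12
  for (i in ocd) for (j in ocd) if (i != j) omega[i, j] <- -0.25
  for (e in extra) {
    omega[e$i, e$j] <- omega[e$j, e$i] <- e$w
  }
  diag(omega) <- 2.5
  omega
}

edge <- function(i, j, w) list(i = i, j = j, w = w)

fixture_model <- function() {
  vars <- fixture_variables()
  # strong OCD/PD, moderate MDD/SAD | moderate MDD/PD/SAD, weak OCD |
  # all weak | all strong — proportions are the four cluster shares
  means <- list(
    fixture_mean(mdd = 1.5, pd = 3.5, sad = 1.5, ocd = 3.5),
    fixture_mean(mdd = 1.5, pd = 1.5, sad = 1.5, ocd = 0.0),
    fixture_mean(mdd = 0.0, pd = 0.0, sad = 0.0, ocd = 0.0),
    fixture_mean(mdd = 3.5, pd = 3.5, sad = 3.5, ocd = 3.5)
  )
  # variable indices: MDD1=1 MDD2=2 PD1=3 PD2=4 PD3=5 SAD=6 OCD1..6=7..12
  extras <- list(
    list(edge(1, 2, -0.4), edge(3, 4, -0.4), edge(4, 5, -0.4),
         edge(3, 5, -0.4), edge(5, 6, -0.4), edge(1, 6, -0.4)),
    list(edge(1, 2, -0.4), edge(3, 4, -0.4), edge(4, 5, -0.4),
         edge(1, 6, -0.4), edge(3, 6, 0.3)),
    list(edge(1, 2, -0.4), edge(3, 4, -0.4), edge(1, 6, -0.4)),
    list(edge(1, 2, -0.4), edge(3, 4, -0.4), edge(4, 5, -0.4),
         edge(3, 5, -0.4), edge(1, 6, -0.4), edge(2, 7, 0.3),
         edge(6, 12, -0.3))
  )
  precisions <- lapply(extras, fixture_precision)
  graphs <- lapply(precisions, function(om) {
    a <- (om != 0) * 1L
    diag(a) <- 0L
    graph_from_adjacency01(a)
  })
  true_model(
    proportions = c(235, 357, 138, 791) / 1521,
    means = lapply(means, setNames, vars),
    graphs = graphs,
    precisions = precisions,
    variable_names = vars,
    communities = fixture_communities()
  )
}

#' Psychopathology-style ground-truth fixture
#'
#' Generates data from a 12-variable, 4-component graph-structured Gaussian
#' mixture emulating a transdiagnostic symptom-score setting: variables
#' `MDD1`, `MDD2` (depressive), `PD1`–`PD3` (panic), `SAD` (social anxiety)
#' and `OCD1`–`OCD6` (obsessive-compulsive), with communities MDD / PD / SAD
#' / OCD. The four components are: strong OCD and PD with moderate MDD and
#' SAD; moderate MDD, PD and SAD with weak OCD; weak symptoms throughout;
#' and strong symptoms throughout. The OCD variables are mutually connected
#' in every component's graph. All numeric constants (mean levels, edge
#' precisions, proportions) are invented package constants set for clear
#' recoverability — between-component mean separation exceeds three
#' within-component standard deviations.
#'
#' @param n number of subjects (>= 200 recommended).
#' @param seed integer seed.
#' @return a list with `data` (tibble), `labels` (integer vector), `model`
#'   (the generating [true_model()]) and `communities` (named character
#'   vector).
#' @export
psychopathology_fixture <- function(n = 1500L, seed = 1L) {
  model <- fixture_model()
  sim <- sample_ggmm(model, n = n, seed = seed)
  list(data = sim$data, labels = sim$labels, model = model,
       communities = model$communities)
}
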