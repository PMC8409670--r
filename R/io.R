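# Delimited-text readers/writers and the staged pipeline runners used by the
# command-line interface: fit -> networks/centrality, plus simulate. All
# artifacts are diff-able text (JSON for models and sidecars, CSV/TSV for
# tables).

#' Read a subjects-by-variables data file
#'
#' Delimited text with a header row of variable names and one row per
#' subject. Missing cells are rejected with their row and column named;
#' non-numeric cells raise a parse error. Column order is preserved.
#'
#' @param path file path.
#' @param delimiter field separator; comma default, tab accepted.
#' @param group_column optional name of a categorical column (e.g. diagnosis)
#'   to split off; returned as attribute `"groups"`.
#' @return a tibble of numeric columns (attribute `"groups"` holds the
#'   grouping vector when requested).
#' @export
read_data_matrix <- function(path, delimiter = ",", group_column = NULL) {
  if (!file.exists(path)) {
    ggmnet_abort("parse_error", sprintf("file not found: %s", path))
  }
  raw <- tryCatch(
    utils::read.table(path, sep = delimiter, header = TRUE,
                      check.names = FALSE, colClasses = "character",
                      na.strings = NULL, quote = "\"", comment.char = ""),
    error = function(e) ggmnet_abort("parse_error", conditionMessage(e)))
  groups <- NULL
  if (!is.null(group_column)) {
    if (!group_column %in% names(raw)) {
      ggmnet_abort("parse_error", sprintf(
        "group column '%s' not found", group_column))
    }
    groups <- raw[[group_column]]
    raw <- raw[, setdiff(names(raw), group_column), drop = FALSE]
  }
  for (j in seq_along(raw)) {
    cell <- trimws(raw[[j]])
    blank <- which(cell == "" | is.na(cell) | cell == "NA")
    if (length(blank) > 0L) {
      ggmnet_abort("missing_data", sprintf(
        "missing value at row %d, column '%s'", blank[1], names(raw)[j]))
    }
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num))
    if (length(bad) > 0L) {
      ggmnet_abort("parse_error", sprintf(
        "non-numeric value '%s' at row %d, column '%s'",
        cell[bad[1]], bad[1], names(raw)[j]))
    }
    raw[[j]] <- num
  }
  out <- tibble::as_tibble(raw)
  attr(out, "groups") <- groups
  out
}

#' Write a weighted network as a TSV edge list
#'
#' Columns `node_i`, `node_j`, `weight`; one row per nonzero edge.
#'
#' @param net a [weighted_network()].
#' @param path output path.
#' @export
write_network_tsv <- function(net, path) {
  el <- tidy(net)
  names(el) <- c("node_i", "node_j", "weight")
  readr::write_tsv(el, path)
  invisible(path)
}

# JSON-serializable summary of a fitted model
model_to_list <- function(model) {
  list(
    K = model$K,
    proportions = as.numeric(model$proportions),
    variable_names = model$variable_names,
    components = lapply(model$components, function(cc) {
      list(mean = as.numeric(cc$mean),
           covariance = unname(cc$covariance),
           edges = if (n_edges(cc$graph) > 0) unname(cc$graph$edges)
                   else matrix(integer(0), ncol = 2))
    }),
    log_likelihood = model$log_likelihood,
    bic = model$bic,
    n_params = model$n_params,
    n_iterations = model$n_iterations,
    converged = model$converged,
    seed = model$seed
  )
}

#' Resolved run configuration
#'
#' Collects pipeline settings, applying (in increasing precedence) package
#' defaults, a JSON config file, and directly supplied values. The resolved
#' configuration is serialized verbatim into every output directory so a run
#' can be reproduced exactly.
#'
#' @param input path to the data file.
#' @param out output directory.
#' @param k_min,k_max candidate cluster-count range.
#' @param max_iterations,tolerance,n_restarts,beta structural-EM settings
#'   (see [fit_ggmm()]).
#' @param gamma EBIC hyperparameter for the network stage.
#' @param community_map optional path to a two-column (variable, community)
#'   file.
#' @param group_column optional grouping-column name in the data file.
#' @param delimiter field separator of the input file.
#' @param seed integer seed for the whole run.
#' @param n,log_level simulation size and logging verbosity.
#' @param config_file optional JSON file of the same fields; direct arguments
#'   override it.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(input = NULL, out = "ggmnet_run", k_min = 1L,
                       k_max = 5L, max_iterations = 500L, tolerance = 1e-6,
                       n_restarts = 10L, beta = 0, gamma = 0.5,
                       community_map = NULL, group_column = NULL,
                       delimiter = ",", seed = 1L, n = 1500L,
                       log_level = "info", config_file = NULL) {
  cfg <- list(input = input, out = out, k_min = k_min, k_max = k_max,
              max_iterations = max_iterations, tolerance = tolerance,
              n_restarts = n_restarts, beta = beta, gamma = gamma,
              community_map = community_map, group_column = group_column,
              delimiter = delimiter, seed = seed, n = n,
              log_level = log_level)
  if (!is.null(config_file)) {
    file_cfg <- jsonlite::read_json(config_file, simplifyVector = TRUE)
    supplied <- names(as.list(match.call()))
    keep <- setdiff(intersect(names(file_cfg), names(cfg)), supplied)
    cfg[keep] <- file_cfg[keep]
  }
  if (cfg$k_min > cfg$k_max) {
    ggmnet_abort("bad_dimensions", "k_min must not exceed k_max")
  }
  structure(cfg, class = "run_config")
}

make_logger <- function(dir, level = "info") {
  lines <- character(0)
  log_file <- file.path(dir, "run.log")
  function(msg, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(msg, ...))
    lines <<- c(lines, line)
    if (level %in% c("info", "debug")) message(line)
    writeLines(lines, log_file)
    invisible(line)
  }
}

write_config <- function(config, dir) {
  jsonlite::write_json(unclass(config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
}

#' Run the clustering stage and write its artifacts
#'
#' Reads the data, selects the number of clusters by BIC over
#' `k_min..k_max`, and writes to the output directory: the resolved
#' `config.json`, `model.json` (proportions, means, covariances, edge lists,
#' BIC), `labels.csv` (subject_index, cluster), `bic_table.csv` across K with
#' failure reasons, `failures.csv`, per-cluster covariance-network TSV edge
#' lists, and `run.log`.
#'
#' @param config a [run_config()].
#' @return the `ggmm_selection`, invisibly.
#' @export
run_fit <- function(config) {
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  log <- make_logger(config$out, config$log_level)
  write_config(config, config$out)
  data <- read_data_matrix(config$input, config$delimiter,
                           config$group_column)
  log("read %d rows x %d variables from %s", nrow(data), ncol(data),
      config$input)
  sel <- select_ggmm(data, K_range = seq(config$k_min, config$k_max),
                     max_iterations = config$max_iterations,
                     tolerance = config$tolerance,
                     n_restarts = config$n_restarts, beta = config$beta,
                     seed = config$seed)
  for (i in seq_len(nrow(sel$bic_table))) {
    row <- sel$bic_table[i, ]
    if (row$status == "ok") {
      log("K = %d: BIC %.2f", row$K, row$bic)
    } else {
      log("K = %d: failed (%s)", row$K, row$reason)
    }
  }
  log("selected K = %d", sel$model$K)
  labels <- classify(sel$model, data)
  for (k in seq_len(sel$model$K)) {
    log("cluster %d: %d subjects", k, sum(labels == k))
  }
  jsonlite::write_json(model_to_list(sel$model),
                       file.path(config$out, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_csv(tibble::tibble(subject_index = seq_along(labels),
                                  cluster = labels),
                   file.path(config$out, "labels.csv"))
  readr::write_csv(sel$bic_table, file.path(config$out, "bic_table.csv"))
  readr::write_csv(sel$failures, file.path(config$out, "failures.csv"))
  net_dir <- file.path(config$out, "networks")
  dir.create(net_dir, showWarnings = FALSE)
  for (k in seq_len(sel$model$K)) {
    write_network_tsv(covariance_network(sel$model, k),
                      file.path(net_dir,
                                sprintf("cluster_%d_covariance.tsv", k)))
  }
  invisible(sel)
}

read_community_file <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) {
    df <- utils::read.table(path, sep = ",", header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE)
  }
  setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Run the per-cluster network and centrality stage
#'
#' Consumes a [run_fit()] output directory (labels) plus the original data,
#' and writes per cluster: a regularized partial-correlation edge list
#' (TSV), the full symmetric matrix (CSV), a JSON sidecar with the chosen
#' lambda and EBIC, and a centrality table (raw and z-standardized). With a
#' community map, bridge centrality tables are added; with a grouping
#' column, a cluster-by-group cross-tabulation CSV.
#'
#' Clusters with fewer rows than variables are still attempted; a warning is
#' logged and flagged in the sidecar.
#'
#' @param config a [run_config()] whose `out` contains `labels.csv`.
#' @return invisibly, the list of per-cluster networks.
#' @export
run_networks_and_centrality <- function(config) {
  log <- make_logger(config$out, config$log_level)
  labels_path <- file.path(config$out, "labels.csv")
  if (!file.exists(labels_path)) {
    ggmnet_abort("parse_error", "labels.csv not found; run the fit stage first")
  }
  labels <- readr::read_csv(labels_path, show_col_types = FALSE)$cluster
  data <- read_data_matrix(config$input, config$delimiter,
                           config$group_column)
  groups <- attr(data, "groups")
  communities <- NULL
  if (!is.null(config$community_map)) {
    communities <- read_community_file(config$community_map)
  } else {
    log("no community map supplied; bridge centrality skipped")
  }
  p <- ncol(data)
  nets <- list()
  for (k in sort(unique(labels))) {
    rows <- labels == k
    low_n <- sum(rows) < p + 1
    if (low_n) {
      log("cluster %d has %d rows for %d variables; network may be unstable",
          k, sum(rows), p)
    }
    net <- withCallingHandlers(
      select_network(data[rows, , drop = FALSE], gamma = config$gamma),
      warning = function(w) invokeRestart("muffleWarning"))
    nets[[as.character(k)]] <- net
    write_network_tsv(net, file.path(config$out,
                                     sprintf("cluster_%d_pcor.tsv", k)))
    mat <- tibble::as_tibble(net$weights, rownames = "node")
    readr::write_csv(mat, file.path(config$out,
                                    sprintf("cluster_%d_pcor_matrix.csv", k)))
    jsonlite::write_json(
      list(cluster = k, n = sum(rows), lambda = attr(net, "lambda"),
           ebic = attr(net, "ebic"), low_n = low_n),
      file.path(config$out, sprintf("cluster_%d_network.json", k)),
      auto_unbox = TRUE, digits = NA)
    tab <- centrality_table(net, communities = communities)
    readr::write_tsv(tab, file.path(config$out,
                                    sprintf("cluster_%d_centrality.tsv", k)))
    if (!is.null(communities)) {
      bridge <- tab[, c("node", "community",
                        "bridge_strength", "z_bridge_strength",
                        "bridge_expected_influence",
                        "z_bridge_expected_influence")]
      readr::write_tsv(bridge, file.path(config$out,
                                         sprintf("cluster_%d_bridge.tsv", k)))
    }
    log("cluster %d: network with %d edges (lambda %.4g)", k,
        nrow(tidy(net)), attr(net, "lambda"))
  }
  if (!is.null(groups)) {
    readr::write_csv(cluster_crosstab(labels, groups),
                     file.path(config$out, "crosstab.csv"))
    log("wrote cluster-by-group cross-tabulation")
  }
  invisible(nets)
}

#' Simulate fixture data to disk
#'
#' Writes the psychopathology-style fixture: `data.csv`, `labels.csv`, the
#' community map `communities.tsv`, and the generating model as
#' `true_model.json`.
#'
#' @param config a [run_config()]; uses its `n`, `seed` and `out`.
#' @export
run_simulate <- function(config) {
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  write_config(config, config$out)
  sim <- psychopathology_fixture(n = config$n, seed = config$seed)
  readr::write_csv(sim$data, file.path(config$out, "data.csv"))
  readr::write_csv(tibble::tibble(subject_index = seq_along(sim$labels),
                                  cluster = sim$labels),
                   file.path(config$out, "labels.csv"))
  readr::write_tsv(tibble::tibble(variable = names(sim$communities),
                                  community = unname(sim$communities)),
                   file.path(config$out, "communities.tsv"))
  model <- sim$model
  jsonlite::write_json(
    list(K = model$K, proportions = model$proportions,
         variable_names = model$variable_names,
         means = lapply(model$means, as.numeric),
         precisions = lapply(model$precisions, unname),
         edges = lapply(model$graphs, function(g) unname(g$edges))),
    file.path(config$out, "true_model.json"), auto_unbox = TRUE, digits = NA)
  invisible(sim)
}
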