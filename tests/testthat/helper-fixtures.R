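# Shared fixtures: built in code, no stored data files.

# Named coefficient vector assigning `value` to every edge of a DAG.
edge_coefs <- function(dag, value) {
  stats::setNames(rep_len(value, nrow(dag$edges)),
                  paste0(dag$edges$parent, "->", dag$edges$child))
}

# Random recursive DAG over generic nodes X1..Xp (no role constraints).
random_recursive_dag <- function(p = 6, n_edges = 7) {
  nodes <- paste0("X", seq_len(p))
  pairs <- t(utils::combn(p, 2))  # row i < j: edge from earlier to later
  pick <- sample(nrow(pairs), n_edges)
  edges <- cbind(nodes[pairs[pick, 1]], nodes[pairs[pick, 2]])
  path_dag(edges, name = "random", nodes = nodes)
}

# Tiny raw category matrix fixture.
small_cm <- function(values, category = "RES", ids = NULL) {
  m <- as.matrix(values)
  if (is.null(rownames(m))) {
    rownames(m) <- ids %||% paste0("s", seq_len(nrow(m)))
  }
  category_matrix(m, category)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small community simulation for pipeline tests (scaled down for speed).
quick_sim_config <- function(scenario = "adjustment", seed = 11, ...) {
  args <- list(...)
  if (is.null(args$n_transitions)) args$n_transitions <- 6
  do.call(community_sim_config,
          c(list(scenario = scenario, seed = seed), args))
}
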