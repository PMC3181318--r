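#' Construct a candidate causal structure (directed acyclic graph)
#'
#' A `path_dag` encodes one hypothesised causal ordering of the rate-of-change
#' variables: which category drives which, with resources (RES) as the root
#' driver and community metabolism (BCM) as the terminal response.  Candidate
#' structures are compared against data with [fit_path_model()].
#'
#' When `nodes` is exactly the six standard rate variables (see
#' [rate_variables()]), two role constraints are enforced: RES may have no
#' parents and BCM no children.  Arbitrary node sets (e.g. for simulation
#' studies of the engine itself) skip the role check but are still required to
#' be acyclic.
#'
#' @param edges Two-column character matrix, data frame, or list of
#'   length-2 character vectors; each row/element is one `parent -> child`
#'   edge.
#' @param name Identifier for the model (e.g. `"B-DAG4"`).
#' @param scenario Optional scenario tag, `"adjustment"` or `"replacement"`.
#' @param nodes Node set; defaults to the union of nodes named in `edges`
#'   with the six standard rate variables when the edges use them.
#' @return An object of class `path_dag` with elements `nodes`, `edges`
#'   (data frame with columns `parent`, `child`), `name`, `scenario`.
#' @examples
#' chain <- path_dag(rbind(c("RES", "SCC"), c("SCC", "PS"), c("PS", "BCM")))
#' validate_dag(chain)
#' @export
path_dag <- function(edges, name = "custom", scenario = NA_character_,
                     nodes = NULL) {
  if (is.list(edges) && !is.data.frame(edges)) {
    edges <- do.call(rbind, lapply(edges, function(e) as.character(e)))
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) != 2L) {
    stop("`edges` must have two columns (parent, child)", call. = FALSE)
  }
  names(edges) <- c("parent", "child")
  edges$parent <- as.character(edges$parent)
  edges$child <- as.character(edges$child)

  if (is.null(nodes)) {
    seen <- unique(c(edges$parent, edges$child))
    nodes <- if (all(seen %in% rate_variables())) rate_variables() else seen
  }
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names", call. = FALSE)
  unknown <- setdiff(c(edges$parent, edges$child), nodes)
  if (length(unknown)) {
    stop("edge references unknown node(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }

  dag <- structure(
    list(nodes = nodes, edges = edges, name = name, scenario = scenario),
    class = "path_dag"
  )
  validate_dag(dag)  # fails on cycles, self-loops, duplicates, role violations
  dag
}

#' Validate a causal structure and return a topological node order
#'
#' Checks that the graph is acyclic with no self-loops or duplicated edges,
#' and (for the standard six rate variables) that RES is exogenous and BCM
#' terminal.  Kahn's algorithm supplies the topological order used by the
#' fitting and simulation code.
#'
#' @param dag A [path_dag()].
#' @return Character vector: the nodes in a topological order (parents before
#'   children).
#' @export
validate_dag <- function(dag) {
  stopifnot(inherits(dag, "path_dag"))
  edges <- dag$edges
  if (any(edges$parent == edges$child)) {
    stop("self-loop on node ", edges$parent[edges$parent == edges$child][1L],
         call. = FALSE)
  }
  if (anyDuplicated(paste(edges$parent, edges$child))) {
    stop("duplicate edges in DAG '", dag$name, "'", call. = FALSE)
  }
  if (setequal(dag$nodes, rate_variables())) {
    if (any(edges$child == "RES")) {
      stop("RES is the driving variable and may have no parents", call. = FALSE)
    }
    if (any(edges$parent == "BCM")) {
      stop("BCM is the terminal response and may have no children", call. = FALSE)
    }
  }

  # Kahn's algorithm
  nodes <- dag$nodes
  indeg <- vapply(nodes, function(v) sum(edges$child == v), integer(1))
  order <- character(0)
  avail <- nodes[indeg == 0L]
  indeg <- indeg[setdiff(nodes, avail)]
  remaining <- edges
  while (length(avail)) {
    v <- avail[1L]
    avail <- avail[-1L]
    order <- c(order, v)
    out <- remaining$parent == v
    for (ch in remaining$child[out]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) avail <- c(avail, ch)
    }
    remaining <- remaining[!out, , drop = FALSE]
  }
  if (length(order) < length(nodes)) {
    stop("cycle detected involving: ",
         paste(setdiff(nodes, order), collapse = ", "), call. = FALSE)
  }
  order
}

#' Degrees of freedom of a path model's chi-square test
#'
#' With p observed variables there are p(p+1)/2 non-redundant covariance
#' moments; a recursive path model with uncorrelated exogenous variables
#' spends p variance parameters (exogenous variances plus residual variances)
#' and one parameter per edge, leaving
#' `df = p(p+1)/2 - p - n_edges`.
#' For six variables and seven edges this gives df = 8, the value carried by
#' the accepted models of both response scenarios.
#'
#' @param dag A [path_dag()].
#' @return Integer degrees of freedom.
#' @export
model_df <- function(dag) {
  stopifnot(inherits(dag, "path_dag"))
  p <- length(dag$nodes)
  df <- p * (p + 1L) / 2L - p - nrow(dag$edges)
  if (df < 0L) {
    stop("model '", dag$name, "' is over-parameterized (df = ", df, ")",
         call. = FALSE)
  }
  as.integer(df)
}

#' Parents of a node
#' @param dag A [path_dag()].
#' @param node Node name.
#' @return Character vector of parent node names (possibly empty).
#' @export
dag_parents <- function(dag, node) {
  dag$edges$parent[dag$edges$child == node]
}

#' Load the nine-model candidate library
#'
#' The candidate causal structures span two scenarios.  In the Replacement
#' scenario (models A-DAG1..A-DAG4) a resource shift first changes community
#' composition — the identity of the dominant phylotypes — and the new taxa
#' bring different single-cell characteristics.  In the Adjustment scenario
#' (models B-DAG1..B-DAG5) the existing phylotypes adjust their single-cell
#' activity first, and composition changes only as a rearrangement of
#' relative abundances, if at all.  Every Replacement model therefore opens
#' with the edge RES -> BCC and every Adjustment model with RES -> SCC.
#'
#' The library ships as a JSON data file so that edge sets can be amended
#' without code changes; pass `path` to load an alternative library of the
#' same format (`[{"name": ..., "scenario": ..., "edges": [[parent, child],
#' ...]}, ...]`).
#'
#' @param path Optional path to a JSON library file; default: the library
#'   installed with the package.
#' @return Named list of [path_dag()] objects, in library order.
#' @export
build_model_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "dag_library.json", package = "ratepath")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("DAG library file not found: ", path, call. = FALSE)
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  dags <- lapply(raw, function(m) {
    path_dag(m$edges, name = m$name, scenario = m$scenario %||% NA_character_)
  })
  names(dags) <- vapply(dags, `[[`, character(1), "name")
  dags
}

#' @export
print.path_dag <- function(x, ...) {
  cat("path_dag '", x$name, "'", sep = "")
  if (!is.na(x$scenario)) cat(" [", x$scenario, " scenario]", sep = "")
  cat("\n  nodes:", paste(x$nodes, collapse = ", "), "\n")
  cat("  edges:", paste(edge_label(x$edges$parent, x$edges$child),
                        collapse = ", "), "\n")
  invisible(x)
}
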