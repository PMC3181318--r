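# Recursive path-model (SEM) engine: standardized equation-wise estimation,
# implied covariance, ML discrepancy and chi-square model testing.

# Coerce a rate table / data frame to the standardized data matrix over the
# DAG's nodes.  Variables are always re-standardized here so coefficients are
# standardized path coefficients regardless of upstream scaling.
sem_data_matrix <- function(dag, data) {
  data <- as.data.frame(data)
  missing <- setdiff(dag$nodes, names(data))
  if (length(missing)) {
    stop("data lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(data[dag$nodes])
  if (!is.numeric(x)) stop("rate columns must be numeric", call. = FALSE)
  if (anyNA(x)) stop("missing values in rate columns", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  }
  scale(x)
}

#' Estimate standardized path coefficients equation by equation
#'
#' Each endogenous node is regressed on its parents by ordinary least squares
#' on the standardized scale, so the coefficients are standardized path
#' coefficients (SD change in the child per SD change in the parent) and the
#' residual variance of each equation is `1 - R^2`.  For recursive models
#' with uncorrelated residuals these equation-wise estimates coincide with
#' the maximum-likelihood optimum of the covariance-structure discrepancy
#' (see [ml_discrepancy()]); [ml_fit_numeric()] provides the numerical
#' cross-check.
#'
#' @param dag A [path_dag()].
#' @param data Data frame (e.g. a rate table) containing one numeric column
#'   per DAG node.
#' @return List with `coefficients` (named `"parent->child"`),
#'   `residual_variances` (named by node; for an exogenous node this is its
#'   standardized variance, 1), and `n`.
#' @export
fit_equations <- function(dag, data) {
  x <- sem_data_matrix(dag, data)
  n <- nrow(x)
  S <- stats::cov(x)
  coefs <- numeric(0)
  psis <- stats::setNames(numeric(length(dag$nodes)), dag$nodes)
  for (node in dag$nodes) {
    pa <- dag_parents(dag, node)
    if (!length(pa)) {
      psis[node] <- S[node, node]
      next
    }
    Sxx <- S[pa, pa, drop = FALSE]
    qr_x <- qr(Sxx)
    if (qr_x$rank < length(pa)) {
      stop("collinear parents in equation for node ", node, call. = FALSE)
    }
    beta <- drop(solve(qr_x, S[pa, node, drop = FALSE]))
    psi <- S[node, node] - drop(S[node, pa, drop = FALSE] %*% beta)
    coefs[edge_label(pa, node)] <- beta
    psis[node] <- psi
  }
  list(coefficients = coefs, residual_variances = psis, n = n)
}

#' Covariance matrix implied by a parameterized path model
#'
#' For the structural system `x = B x + e` with strictly lower-triangular
#' (in topological order) coefficient matrix B and diagonal residual
#' covariance Psi, the implied covariance is
#' `Sigma = (I - B)^-1 Psi (I - B)^-T`.
#'
#' @param dag A [path_dag()].
#' @param coefficients Named numeric vector, names `"parent->child"`.
#' @param residual_variances Named numeric vector, one non-negative entry per
#'   node (exogenous nodes carry their total variance).
#' @return Symmetric positive-definite matrix with the DAG's nodes as
#'   dimnames, in `dag$nodes` order.
#' @export
implied_covariance <- function(dag, coefficients, residual_variances) {
  nodes <- dag$nodes
  p <- length(nodes)
  if (!all(nodes %in% names(residual_variances))) {
    stop("residual_variances must name every node", call. = FALSE)
  }
  lab <- edge_label(dag$edges$parent, dag$edges$child)
  if (!all(names(coefficients) %in% lab)) {
    stop("coefficient(s) for unknown edge(s): ",
         paste(setdiff(names(coefficients), lab), collapse = ", "),
         call. = FALSE)
  }
  B <- matrix(0, p, p, dimnames = list(nodes, nodes))
  for (k in seq_along(lab)) {
    if (lab[k] %in% names(coefficients)) {
      B[dag$edges$child[k], dag$edges$parent[k]] <- coefficients[[lab[k]]]
    }
  }
  IB <- diag(p) - B
  # acyclic B => I - B invertible; guard anyway
  inv <- tryCatch(solve(IB), error = function(e) {
    stop("(I - B) is singular; structure is not recursive", call. = FALSE)
  })
  Psi <- diag(residual_variances[nodes], p)
  Sigma <- inv %*% Psi %*% t(inv)
  Sigma <- (Sigma + t(Sigma)) / 2
  dimnames(Sigma) <- list(nodes, nodes)
  Sigma
}

#' Maximum-likelihood discrepancy between sample and implied covariance
#'
#' `F = log|Sigma| + tr(S Sigma^-1) - log|S| - p`, the multivariate-normal
#' ML discrepancy; it is non-negative and zero exactly when `S == Sigma`.
#' Scaled by (n - 1) it gives the model's chi-square statistic.
#'
#' @param S Sample covariance matrix (symmetric positive definite).
#' @param Sigma Model-implied covariance matrix of the same dimension.
#' @return The scalar discrepancy.
#' @export
ml_discrepancy <- function(S, Sigma) {
  if (!isTRUE(all.equal(dim(S), dim(Sigma)))) {
    stop("S and Sigma must have the same dimension", call. = FALSE)
  }
  p <- nrow(S)
  chS <- tryCatch(chol(S), error = function(e) {
    stop("S is not positive definite", call. = FALSE)
  })
  chSig <- tryCatch(chol(Sigma), error = function(e) {
    stop("Sigma is not positive definite", call. = FALSE)
  })
  logdetS <- 2 * sum(log(diag(chS)))
  logdetSig <- 2 * sum(log(diag(chSig)))
  tr <- sum(diag(chol2inv(chSig) %*% S))
  f <- logdetSig + tr - logdetS - p
  max(f, 0)  # clip tiny negative round-off
}

#' Fit one candidate causal structure and test its covariance fit
#'
#' Chains [fit_equations()], [implied_covariance()] and [ml_discrepancy()];
#' the test statistic is `T = (n - 1) * F_ml`, referred to a chi-square
#' distribution with [model_df()] degrees of freedom.  A model is *retained*
#' ("significant" in the sense of a fit test) when the chi-square test does
#' NOT reject it, i.e. `p >= alpha`.  `r2` per endogenous node is
#' `1 - residual variance` on the standardized scale: the variance explained
#' by the ensemble of its (direct and indirect) upstream variables.
#'
#' @param dag A [path_dag()].
#' @param data Data frame with one numeric column per node (typically a
#'   rate table from [build_rate_table()]).
#' @param alpha Rejection level for the chi-square fit test.
#' @return Object of class `path_fit`: `dag`, `coefficients`,
#'   `residual_variances`, `implied_covariance`, `F_ml`, `T`, `df`,
#'   `p_value`, `r2`, `n`, `alpha`, `rejected`.
#' @export
fit_path_model <- function(dag, data, alpha = 0.05) {
  est <- fit_equations(dag, data)
  x <- sem_data_matrix(dag, data)
  S <- stats::cov(x)
  Sigma <- implied_covariance(dag, est$coefficients, est$residual_variances)
  f <- ml_discrepancy(S, Sigma)
  df <- model_df(dag)
  T_stat <- (est$n - 1) * f
  p_value <- if (df == 0L) 1 else stats::pchisq(T_stat, df, lower.tail = FALSE)
  endo <- unique(dag$edges$child)
  r2 <- 1 - est$residual_variances[endo]
  r2 <- pmin(pmax(r2, 0), 1)
  structure(
    list(dag = dag, coefficients = est$coefficients,
         residual_variances = est$residual_variances,
         implied_covariance = Sigma, F_ml = f, T = T_stat, df = df,
         p_value = p_value, r2 = r2, n = est$n, alpha = alpha,
         rejected = p_value < alpha),
    class = "path_fit"
  )
}

#' @export
print.path_fit <- function(x, ...) {
  cat(sprintf("path_fit '%s': chi-square = %.3f, df = %d, p = %.4f (n = %d) -- %s\n",
              x$dag$name, x$T, x$df, x$p_value, x$n,
              if (x$rejected) "REJECTED" else "retained"))
  if (length(x$coefficients)) {
    cat("  standardized path coefficients:\n")
    for (nm in names(x$coefficients)) {
      cat(sprintf("    %-12s %+.3f\n", nm, x$coefficients[[nm]]))
    }
  }
  if (length(x$r2)) {
    cat("  r2:", paste(sprintf("%s = %.2f", names(x$r2), x$r2), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Numerical maximum-likelihood fit (cross-check)
#'
#' Minimizes [ml_discrepancy()] over all path coefficients and log residual
#' variances with `stats::nlminb`.  For recursive models with uncorrelated
#' residuals the optimum coincides with the equation-wise OLS estimates of
#' [fit_equations()]; this routine exists to verify that identity numerically
#' and for non-standard extensions.
#'
#' @param dag A [path_dag()].
#' @param S Sample covariance matrix over the DAG's nodes (standardized
#'   scale).
#' @param start Optional list with `coefficients` and `residual_variances`
#'   to start from; defaults to zeros / unit variances.
#' @return List with `coefficients`, `residual_variances`, `F_ml`,
#'   `convergence` (0 = success).
#' @export
ml_fit_numeric <- function(dag, S, start = NULL) {
  nodes <- dag$nodes
  S <- S[nodes, nodes]
  lab <- edge_label(dag$edges$parent, dag$edges$child)
  nE <- length(lab)
  b0 <- if (!is.null(start)) start$coefficients[lab] else rep(0, nE)
  v0 <- if (!is.null(start)) start$residual_variances[nodes] else rep(1, length(nodes))
  par0 <- c(b0, log(pmax(v0, 1e-8)))
  obj <- function(par) {
    coefs <- stats::setNames(par[seq_len(nE)], lab)
    psis <- stats::setNames(exp(par[nE + seq_along(nodes)]), nodes)
    Sigma <- implied_covariance(dag, coefs, psis)
    out <- tryCatch(ml_discrepancy(S, Sigma), error = function(e) NA_real_)
    if (!is.finite(out)) 1e10 else out
  }
  opt <- stats::nlminb(par0, obj,
                       control = list(rel.tol = 1e-15, x.tol = 1e-12,
                                      iter.max = 2000, eval.max = 4000))
  list(
    coefficients = stats::setNames(opt$par[seq_len(nE)], lab),
    residual_variances = stats::setNames(exp(opt$par[nE + seq_along(nodes)]),
                                         nodes),
    F_ml = opt$objective,
    convergence = opt$convergence
  )
}

#' Test every model of a candidate library against a rate table
#'
#' Fits each structure with [fit_path_model()], partitions the library into
#' rejected and retained models at level `alpha`, and ranks the retained
#' models by descending p-value (ties: fewer edges first, then library
#' order).
#'
#' @param library Named list of [path_dag()] (see [build_model_library()]).
#' @param data Rate table / data frame.
#' @param alpha Rejection level.
#' @return Object of class `library_report`: `fits` (named list of
#'   `path_fit`), `summary` (data frame: model, scenario, n_edges, df, T, p,
#'   rejected, rank), `alpha`, `n`.
#' @export
test_model_library <- function(library, data, alpha = 0.05) {
  fits <- lapply(library, fit_path_model, data = data, alpha = alpha)
  summ <- data.frame(
    model = vapply(fits, function(f) f$dag$name, character(1)),
    scenario = vapply(fits, function(f) as.character(f$dag$scenario),
                      character(1)),
    n_edges = vapply(fits, function(f) nrow(f$dag$edges), integer(1)),
    df = vapply(fits, `[[`, integer(1), "df"),
    T = vapply(fits, `[[`, numeric(1), "T"),
    p = vapply(fits, `[[`, numeric(1), "p_value"),
    rejected = vapply(fits, `[[`, logical(1), "rejected"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  summ$rank <- NA_integer_
  keep <- which(!summ$rejected)
  if (length(keep)) {
    ord <- keep[order(-summ$p[keep], summ$n_edges[keep], keep)]
    summ$rank[ord] <- seq_along(ord)
  }
  structure(list(fits = fits, summary = summ, alpha = alpha,
                 n = if (length(fits)) fits[[1]]$n else 0L),
            class = "library_report")
}

#' @export
print.library_report <- function(x, ...) {
  cat(sprintf("Candidate-library test: %d models, n = %d, alpha = %.2f\n",
              nrow(x$summary), x$n, x$alpha))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Subset analyses: per date, gradient-intensity split, single resource
#'
#' Re-runs the library test on subsets of the rate table:
#' * `by_date` — one test per sampling date;
#' * `by_intensity_median_split` — transitions are split into two
#'   equal-sized groups by the magnitude of resource change (the RES rate
#'   column), "high" and "low", and each group is tested;
#' * `single_resource` — the ensemble RES rate is replaced by the rate
#'   computed from one named resource variable (e.g. DOC), asking whether a
#'   single resource drives the cascade.
#'
#' Subsets smaller than `min_n` are skipped with a warning: the chi-square
#' statistic scales with (n - 1) and is not meaningful for tiny subsets.
#'
#' @param rt Rate table ([build_rate_table()]).
#' @param mode One of `"by_date"`, `"by_intensity_median_split"`,
#'   `"single_resource"`.
#' @param library Candidate library (named list of [path_dag()]).
#' @param alpha Rejection level.
#' @param single_resource Column name of the single-resource rate (required
#'   for mode `"single_resource"`; the column must exist in `rt`, see the
#'   `single_resource` argument of [build_rate_table()]).
#' @param min_n Minimum subset size.
#' @return Named list of `library_report` objects (one per subset), with an
#'   attribute `skipped` naming subsets below `min_n`.
#' @export
subset_analysis <- function(rt, mode = c("by_date", "by_intensity_median_split",
                                         "single_resource"),
                            library, alpha = 0.05, single_resource = NULL,
                            min_n = 10) {
  mode <- match.arg(mode)
  rt <- as.data.frame(rt)
  run_one <- function(sub) test_model_library(library, sub, alpha = alpha)
  reports <- list()
  skipped <- character(0)

  if (mode == "by_date") {
    if (!"date" %in% names(rt)) stop("rate table lacks a 'date' column",
                                     call. = FALSE)
    for (d in unique(rt$date)) {
      sub <- rt[rt$date == d, , drop = FALSE]
      if (nrow(sub) < min_n) {
        warning("subset '", d, "' has n = ", nrow(sub), " < ", min_n,
                "; skipped", call. = FALSE)
        skipped <- c(skipped, d)
      } else {
        reports[[as.character(d)]] <- run_one(sub)
      }
    }
  } else if (mode == "by_intensity_median_split") {
    ord <- order(rt$RES)
    n_low <- floor(nrow(rt) / 2)
    groups <- list(low = rt[ord[seq_len(n_low)], , drop = FALSE],
                   high = rt[ord[-seq_len(n_low)], , drop = FALSE])
    for (g in names(groups)) {
      if (nrow(groups[[g]]) < min_n) {
        warning("subset '", g, "' has n = ", nrow(groups[[g]]), " < ", min_n,
                "; skipped", call. = FALSE)
        skipped <- c(skipped, g)
      } else {
        reports[[g]] <- run_one(groups[[g]])
      }
    }
  } else {
    if (is.null(single_resource)) {
      stop("mode 'single_resource' requires `single_resource`", call. = FALSE)
    }
    if (!single_resource %in% names(rt)) {
      stop("rate table lacks column '", single_resource, "'", call. = FALSE)
    }
    sub <- rt
    sub$RES <- rt[[single_resource]]
    if (nrow(sub) < min_n) {
      warning("table has n = ", nrow(sub), " < ", min_n, "; skipped",
              call. = FALSE)
      skipped <- c(skipped, single_resource)
    } else {
      reports[[single_resource]] <- run_one(sub)
    }
  }
  attr(reports, "skipped") <- skipped
  reports
}
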