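# Path-model engine: estimation, implied covariance, ML discrepancy,
# chi-square testing, library comparison and subset analyses.

test_that("a single-edge coefficient equals the Pearson correlation", {
  set.seed(1)
  x <- rnorm(200)
  y <- 0.6 * x + rnorm(200)
  dag <- path_dag(rbind(c("X", "Y")), nodes = c("X", "Y"))
  est <- fit_equations(dag, data.frame(X = x, Y = y))
  expect_equal(unname(est$coefficients["X->Y"]), cor(x, y),
               tolerance = 1e-12)
  # exogenous node: no coefficients, unit standardized variance
  expect_equal(unname(est$residual_variances["X"]), 1, tolerance = 1e-12)
})

test_that("fit_equations recovers generating parameters from simulated data", {
  lib <- build_model_library()
  dag <- lib[["B-DAG4"]]
  truth <- edge_coefs(dag, 0.7)
  params <- sem_parameters(dag, truth, residual_sd = 1, n_samples = 5000,
                           seed = 99)
  d <- sample_rate_sem(params)
  est <- fit_equations(dag, d)
  # standardized-scale truth differs from the raw 0.7 because downstream
  # variances exceed 1; recompute it from the generating covariance
  Sigma <- implied_covariance(dag, truth,
                              stats::setNames(rep(1, 6), dag$nodes))
  Dinv <- diag(1 / sqrt(diag(Sigma)))
  dimnames(Sigma) <- list(dag$nodes, dag$nodes)
  R <- cov2cor(Sigma)
  for (k in seq_len(nrow(dag$edges))) {
    pa <- dag$edges$parent[k]; ch <- dag$edges$child[k]
    lab <- paste0(pa, "->", ch)
    pa_all <- dag$edges$parent[dag$edges$child == ch]
    beta_std <- solve(R[pa_all, pa_all], R[pa_all, ch])[match(pa, pa_all)]
    se <- 3 / sqrt(5000)  # generous 3-SE band
    expect_lt(abs(est$coefficients[[lab]] - beta_std), 3 * se)
  }
})

test_that("implied covariance follows the recursive path algebra", {
  nodes <- c("X", "Y", "Z")
  empty <- path_dag(matrix(character(0), 0, 2), nodes = nodes)
  psi <- c(X = 2, Y = 3, Z = 0.5)
  expect_equal(implied_covariance(empty, numeric(0), psi),
               diag(c(2, 3, 0.5)), ignore_attr = TRUE)

  chain <- path_dag(rbind(c("X", "Y")), nodes = c("X", "Y"))
  Sigma <- implied_covariance(chain, c("X->Y" = 0.8),
                              c(X = 1, Y = 1 - 0.8^2))
  expect_equal(Sigma["X", "Y"], 0.8, tolerance = 1e-12)
  expect_equal(Sigma["Y", "Y"], 1, tolerance = 1e-12)
})

test_that("implied covariance matches a Monte-Carlo simulation oracle", {
  set.seed(2024)
  dag <- random_recursive_dag(5, 6)
  coefs <- edge_coefs(dag, 0)
  coefs[] <- runif(length(coefs), 0.3, 0.8) * sample(c(-1, 1),
                                                     length(coefs), TRUE)
  psi <- stats::setNames(runif(5, 0.5, 1.5), dag$nodes)
  Sigma <- implied_covariance(dag, coefs, psi)
  params <- sem_parameters(dag, coefs, residual_sd = sqrt(psi),
                           n_samples = 2e5, seed = 8)
  S_mc <- cov(as.matrix(sample_rate_sem(params)))
  # Monte-Carlo SE of a covariance entry is O(1/sqrt(n)) times its scale
  scale <- sqrt(outer(diag(Sigma), diag(Sigma)))
  expect_true(all(abs(S_mc[dag$nodes, dag$nodes] - Sigma) <
                    3 * 3 * scale / sqrt(2e5)))
  expect_true(all(eigen(Sigma, symmetric = TRUE)$values > 0))
})

test_that("ML discrepancy has its closed-form values and eigen cross-check", {
  S <- diag(2); expect_equal(ml_discrepancy(S, S), 0)
  expect_equal(ml_discrepancy(matrix(2), matrix(1)), 1 - log(2),
               tolerance = 1e-12)
  set.seed(31)
  for (i in 1:5) {
    A <- crossprod(matrix(rnorm(36), 6)) / 6 + diag(6) * 0.5
    B <- crossprod(matrix(rnorm(36), 6)) / 6 + diag(6) * 0.5
    # numerically independent evaluation via eigendecomposition of B^-1 A
    ev <- eigen(solve(B, A), only.values = TRUE)$values
    oracle <- sum(Re(ev)) - sum(log(Re(ev))) - 6
    expect_equal(ml_discrepancy(A, B), oracle, tolerance = 1e-10)
    expect_gte(ml_discrepancy(A, B), 0)
  }
  expect_error(ml_discrepancy(diag(2), -diag(2)), "positive definite")
})

test_that("equation-wise OLS coincides with the numerical ML optimum", {
  set.seed(55)
  for (i in 1:8) {
    dag <- random_recursive_dag(6, sample(3:10, 1))
    coefs <- edge_coefs(dag, 0)
    coefs[] <- runif(length(coefs), 0.2, 0.8)
    d <- sample_rate_sem(sem_parameters(dag, coefs, 1, n_samples = 300,
                                        seed = 1000 + i))
    est <- fit_equations(dag, d)
    S <- cov(scale(as.matrix(d[dag$nodes])))
    # start from perturbed values
    start <- list(
      coefficients = est$coefficients +
        runif(length(est$coefficients), -0.05, 0.05),
      residual_variances = est$residual_variances *
        exp(runif(6, -0.05, 0.05)))
    names(start$coefficients) <- names(est$coefficients)
    ml <- ml_fit_numeric(dag, S, start = start)
    expect_lt(max(abs(ml$coefficients[names(est$coefficients)] -
                        est$coefficients)), 1e-6)
    expect_lt(max(abs(ml$residual_variances[dag$nodes] -
                        est$residual_variances[dag$nodes])), 1e-6)
  }
})

test_that("adding an edge never increases the minimized discrepancy", {
  set.seed(77)
  base <- path_dag(rbind(c("X1", "X2"), c("X2", "X3")),
                   nodes = paste0("X", 1:4))
  bigger <- path_dag(rbind(c("X1", "X2"), c("X2", "X3"), c("X1", "X3"),
                           c("X3", "X4")), nodes = paste0("X", 1:4))
  d <- as.data.frame(matrix(rnorm(400), 100,
                            dimnames = list(NULL, paste0("X", 1:4))))
  d$X2 <- 0.5 * d$X1 + rnorm(100)
  d$X3 <- 0.4 * d$X2 + 0.3 * d$X1 + rnorm(100)
  f_base <- fit_path_model(base, d)
  f_big <- fit_path_model(bigger, d)
  expect_lte(f_big$F_ml, f_base$F_ml + 1e-12)
})

test_that("fit_path_model produces coherent chi-square bookkeeping", {
  lib <- build_model_library()
  d <- sample_rate_sem(sem_parameters(lib[["B-DAG4"]],
                                      edge_coefs(lib[["B-DAG4"]], 0.7),
                                      1, n_samples = 400, seed = 3))
  f <- fit_path_model(lib[["B-DAG4"]], d)
  expect_gte(f$T, 0)
  expect_identical(f$df, 8L)
  expect_equal(f$T, (f$n - 1) * f$F_ml, tolerance = 1e-12)
  expect_equal(f$p_value, pchisq(f$T, 8, lower.tail = FALSE))
  expect_true(all(f$r2 >= 0 & f$r2 <= 1))
  # r2 of a single-parent node equals the squared standardized coefficient
  expect_equal(unname(f$r2["SCC"]),
               unname(f$coefficients["RES->SCC"]^2), tolerance = 1e-12)

  # saturated model: perfect fit by construction
  nodes <- paste0("X", 1:4)
  sat <- t(utils::combn(4, 2))
  sat_dag <- path_dag(cbind(nodes[sat[, 1]], nodes[sat[, 2]]), nodes = nodes)
  d4 <- as.data.frame(matrix(rnorm(200), 50, dimnames = list(NULL, nodes)))
  f_sat <- fit_path_model(sat_dag, d4)
  expect_identical(f_sat$df, 0L)
  expect_lt(f_sat$T, 1e-8)
  expect_false(f_sat$rejected)
})

test_that("T is invariant to a node relabeling consistent with the DAG", {
  set.seed(13)
  dag <- path_dag(rbind(c("X1", "X2"), c("X2", "X3")),
                  nodes = paste0("X", 1:3))
  d <- as.data.frame(matrix(rnorm(300), 100,
                            dimnames = list(NULL, paste0("X", 1:3))))
  f1 <- fit_path_model(dag, d)
  relab <- path_dag(rbind(c("A", "B"), c("B", "C")), nodes = c("A", "B", "C"))
  d2 <- stats::setNames(d, c("A", "B", "C"))
  f2 <- fit_path_model(relab, d2)
  expect_equal(f1$T, f2$T, tolerance = 1e-12)
})

test_that("library testing ranks retained models and flags rejections", {
  lib <- build_model_library()
  d <- sample_rate_sem(sem_parameters(lib[["B-DAG4"]],
                                      edge_coefs(lib[["B-DAG4"]], 0.7),
                                      1, n_samples = 2000, seed = 17))
  rep <- test_model_library(lib, d)
  summ <- rep$summary
  expect_identical(nrow(summ), 9L)
  expect_false(summ$rejected[summ$model == "B-DAG4"])
  expect_true(summ$rejected[summ$model == "A-DAG1"])
  keep <- which(!summ$rejected)
  expect_identical(sort(summ$rank[keep]), seq_along(keep))
  expect_identical(summ$model[which(summ$rank == 1)], "B-DAG4")
})

test_that("subset analyses split the table as specified", {
  lib <- build_model_library()
  dag <- lib[["B-DAG4"]]
  d <- sample_rate_sem(sem_parameters(dag, edge_coefs(dag, 0.7), 1,
                                      n_samples = 38, seed = 21))
  d$date <- rep(c("June", "July"), each = 19)

  by_date <- subset_analysis(d, "by_date", lib)
  expect_named(by_date, c("June", "July"))
  expect_identical(by_date$June$n, 19L)

  # single date label: identical to the full-table report
  d1 <- d; d1$date <- "June"
  one <- subset_analysis(d1, "by_date", lib)
  full <- test_model_library(lib, d1)
  expect_equal(one$June$summary$T, full$summary$T, tolerance = 1e-12)

  # median split of 38 rows: two groups of 19
  split <- subset_analysis(d, "by_intensity_median_split", lib)
  expect_identical(split$low$n, 19L)
  expect_identical(split$high$n, 19L)
  # low group really holds the smaller RES rates
  expect_lt(max(sort(d$RES)[1:19]), min(sort(d$RES)[20:38]) + 1e-12)

  # single-resource mode swaps the driver column
  d$DOC <- d$RES + rnorm(38, sd = 0.01)
  sr <- subset_analysis(d, "single_resource", lib, single_resource = "DOC")
  expect_named(sr, "DOC")

  # small subsets are skipped with a warning
  d_small <- d[1:12, ]; d_small$date <- rep(c("a", "b"), 6)
  wraps <- testthat::capture_warnings(out <- subset_analysis(d_small,
                                                             "by_date", lib))
  expect_true(any(grepl("skipped", wraps)))
  expect_length(out, 0L)
  expect_setequal(attr(out, "skipped"), c("a", "b"))
})
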