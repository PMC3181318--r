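# Rate-of-change statistics and the rate table.

test_that("transition series validate their temporal backbone", {
  expect_error(transition_series("T1", "June", "s1", 0), "at least 2")
  expect_error(transition_series("T1", "June", c("s1", "s2"), c(1, 2)),
               "head site")
  expect_error(transition_series("T1", "June", c("s1", "s2", "s3"),
                                 c(0, 5, 5)), "strictly increasing")
})

test_that("head-dissimilarity series reads the matrix in site order", {
  t2 <- transition_series("T1", "June", c("s1", "s2"), c(0, 2))
  d <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("s1", "s2"),
                                                c("s1", "s2")))
  ser <- head_dissimilarity_series(d, t2)
  expect_equal(ser$hours, c(0, 2))
  expect_equal(unname(ser$dissimilarity), c(0, 4))

  # 4-site synthetic transition: pairs equal the head row in site order
  set.seed(14)
  x <- matrix(rnorm(12), 4, dimnames = list(paste0("s", 1:4), NULL))
  dm <- euclidean_distance_matrix(category_matrix(x, "RES",
                                                  stage = "standardized"))
  t4 <- transition_series("T2", "June", paste0("s", c(1, 3, 2, 4)),
                          c(0, 1, 4, 9))
  ser <- head_dissimilarity_series(dm, t4)
  expect_equal(unname(ser$dissimilarity),
               unname(dm["s1", paste0("s", c(1, 3, 2, 4))]))
  expect_equal(ser$dissimilarity[1], 0)

  expect_error(head_dissimilarity_series(dm,
    transition_series("T3", "June", c("s1", "zz"), c(0, 1))), "zz")
})

test_that("rate_of_change is exact OLS with a free intercept", {
  r <- suppressWarnings(rate_of_change(data.frame(h = c(0, 2, 4),
                                                  v = c(0, 4, 8))))
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  expect_identical(r$n, 3L)

  r0 <- rate_of_change(data.frame(h = c(0, 2, 4), v = c(3, 3, 3)))
  expect_equal(r0$slope, 0, tolerance = 1e-12)
  expect_true(is.na(r0$r_squared))

  # closed-form OLS oracle on random points
  set.seed(15)
  for (i in 1:10) {
    h <- sort(runif(10, 0, 40)); v <- rnorm(10)
    r <- rate_of_change(data.frame(h, v))
    oracle <- sum((h - mean(h)) * (v - mean(v))) / sum((h - mean(h))^2)
    expect_equal(r$slope, oracle, tolerance = 1e-12)
  }
  expect_error(rate_of_change(data.frame(h = c(1, 1), v = c(0, 2))),
               "degenerate")
  expect_error(rate_of_change(data.frame(h = 1, v = 0)), "at least 2")
})

test_that("rates scale inversely with the time unit", {
  set.seed(16)
  h <- c(0, 3, 9, 20); v <- rnorm(4)
  slope_h <- rate_of_change(data.frame(h, v))$slope
  slope_min <- rate_of_change(data.frame(h * 60, v))$slope
  expect_equal(slope_min, slope_h / 60, tolerance = 1e-12)
})

test_that("two-site rates equal the finite difference", {
  t2 <- transition_series("T1", "June", c("s1", "s2"), c(0, 10))
  r <- abundance_rate(c(1e6, 3e6), t2)
  expect_equal(r$slope, 2e5, tolerance = 1e-9)  # (3e6-1e6)/10 cells/h
  expect_equal(abundance_rate(c(5, 5), t2)$slope, 0)

  # cross-operation consistency: abundance_rate == rate_of_change on the
  # head-difference series under the same anchor policy
  t4 <- transition_series("T2", "July", paste0("s", 1:4), c(0, 2, 7, 11))
  ab <- c(2e6, 1.5e6, 3.2e6, 2.8e6)
  diffs <- data.frame(hours = t4$transit_times_h, value = ab - ab[1])
  expect_equal(abundance_rate(ab, t4)$slope,
               rate_of_change(diffs[-1, ])$slope, tolerance = 1e-12)
  expect_equal(abundance_rate(ab, t4, include_anchor = "always")$slope,
               rate_of_change(diffs)$slope, tolerance = 1e-12)
})

test_that("diversity and banding rates reflect the generating scenario", {
  # identical lanes: both rates 0
  bands <- matrix(rep(c(5, 3, 2, 0), each = 3), 3,
                  dimnames = list(paste0("s", 1:3), paste0("b", 1:4)))
  t3 <- transition_series("T1", "June", paste0("s", 1:3), c(0, 4, 9))
  db <- diversity_and_banding_rates(bands, t3)
  expect_equal(db$H_rate$slope, 0, tolerance = 1e-12)
  expect_equal(db$banding_rate$slope, 0, tolerance = 1e-12)

  # adjustment scenario: banding slope exactly 0 on every transition
  ds <- simulate_transition_dataset(quick_sim_config(scenario = "adjustment",
                                                     seed = 23))
  for (t in ds$transitions[1:4]) {
    db <- diversity_and_banding_rates(ds$bands, t)
    expect_equal(db$banding_rate$slope, 0, tolerance = 1e-12)
  }

  # replacement with full turnover: banding slope strictly positive
  ds <- simulate_transition_dataset(quick_sim_config(scenario = "replacement",
                                                     turnover_fraction = 1,
                                                     seed = 23))
  for (t in ds$transitions[1:4]) {
    db <- diversity_and_banding_rates(ds$bands, t)
    expect_gt(db$banding_rate$slope, 0)
  }
})

test_that("the rate table has the design shape and provenance", {
  cfg <- community_sim_config(seed = 37)  # default: 13 transitions, 3 dates
  ds <- simulate_transition_dataset(cfg)
  rt <- build_rate_table(ds$categories, ds$bands, ds$transitions,
                         single_resource = "DOC")
  expect_identical(nrow(rt), 39L)  # 13 transitions x 3 dates
  expect_true(all(c("transition", "date", rate_variables(), "H_prime",
                    "banding", "DOC") %in% names(rt)))
  prov <- attr(rt, "provenance")
  expect_true(all(prov$n >= 2))
  # every transition-date contributes provenance for every slope column
  expect_identical(nrow(prov), 39L * 9L)

  # without the single-resource request the DOC column is absent
  rt0 <- build_rate_table(ds$categories, ds$bands, ds$transitions[1:6])
  expect_false("DOC" %in% names(rt0))
  expect_identical(nrow(rt0), 6L)
})

test_that("rate regressions behave on exact, null and generated data", {
  rt <- data.frame(RES = c(0.5, 1, 2, 4, 8), BCM = c(0.5, 1, 2, 4, 8))
  rr <- suppressWarnings(rate_regression(rt, "RES", "BCM", log10 = TRUE))
  expect_equal(rr$slope, 1, tolerance = 1e-12)
  expect_equal(rr$r_squared, 1, tolerance = 1e-12)
  expect_identical(rr$n_excluded, 0L)

  # non-positive rates are excluded under log10, and counted
  rt$RES[2] <- -1
  rr <- suppressWarnings(rate_regression(rt, "RES", "BCM", log10 = TRUE))
  expect_identical(rr$n_used, 4L)
  expect_identical(rr$n_excluded, 1L)

  # independence: slope near 0 (null-simulation oracle)
  set.seed(44)
  slopes <- replicate(200, {
    d <- data.frame(x = rexp(50), y = rexp(50))
    rate_regression(d, "x", "y", log10 = TRUE)$slope
  })
  expect_lt(abs(mean(slopes)), 3 * sd(slopes) / sqrt(200))

  expect_error(rate_regression(data.frame(x = 1:2, y = 1:2), "x", "y",
                               log10 = FALSE), "fewer than 3")
})

test_that("a positive resource-to-metabolism cascade yields a positive cross-rate slope", {
  ds <- simulate_transition_dataset(community_sim_config(seed = 51))
  rt <- build_rate_table(ds$categories, ds$bands, ds$transitions)
  rr <- rate_regression(rt, "RES", "BCM", log10 = TRUE)
  expect_gt(rr$slope, 0)
  expect_lt(rr$p_value, 0.05)
})
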