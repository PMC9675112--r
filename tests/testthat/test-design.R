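test_that("standardization centers, scales, and records the transform", {
  st <- standardize(c(-1, 1), "two_point")
  expect_equal(st$values, c(-1, 1) / sqrt(2))
  expect_equal(st$record$scale, sqrt(2))

  x <- stats::rnorm(50)
  st1 <- standardize(x, "x")
  st2 <- standardize(st1$values, "x")
  expect_lt(max(abs(st2$values - st1$values)), 1e-12)
  expect_equal(st2$record$center, 0, tolerance = 1e-12)
  expect_equal(st2$record$scale, 1, tolerance = 1e-12)

  expect_error(standardize(rep(3, 10), "const_col"), "const_col")
})

test_that("unstandardizing with the scale record restores the input", {
  set.seed(7)
  x <- stats::rnorm(200, 48, 3.1)
  st <- standardize(x, "ozone")
  expect_lt(max(abs(unstandardize(st$values, st$record) - x)), 1e-10)
})

test_that("simulated ozone recovers its configured scale record", {
  ch <- simulate_cohort(simulation_config(n_dyads = 5000, seed = 31))
  st <- standardize(ch$ozone, "ozone")
  expect_lt(abs(st$record$center - 48.0), 3 * 3.1 / sqrt(5000))
  expect_lt(abs(st$record$scale - 3.1), 3 * 3.1 / sqrt(2 * 4999))
})

test_that("covariate encoding uses reference coding and geographic terms", {
  ch <- small_cohort(n = 200, seed = 4)
  W <- encode_covariates(ch, "birth_weight")
  expect_equal(sum(startsWith(colnames(W), "race_")), 3L)
  expect_false("race_nhw" %in% colnames(W))
  expect_equal(sum(colnames(W) == "intercept"), 1L)
  # no constant non-intercept columns
  sds <- apply(W[, colnames(W) != "intercept", drop = FALSE], 2, stats::sd)
  expect_true(all(sds > 0))
  # lon x lat column is the product of the standardized columns
  expect_equal(W[, "longitude:latitude"], W[, "longitude"] * W[, "latitude"])
  # adiposity adds exactly the days-to-measurement column
  Wa <- encode_covariates(ch, "adiposity")
  expect_equal(ncol(Wa), ncol(W) + 1L)
  expect_true("days_to_peapod" %in% colnames(Wa))
})

test_that("interaction expansion enumerates pairs then covariate products", {
  n <- 40
  set.seed(12)
  X <- matrix(stats::rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  Wi <- matrix(stats::rnorm(n * 2), n, 2, dimnames = list(NULL, c("u", "v")))
  Z <- expand_interactions(X, Wi)
  expect_equal(ncol(Z), choose(3, 2) + 3 * 2)
  expect_equal(attr(Z, "pair_count"), 3L)
  # brute-force oracle: every column equals the product its name claims
  for (nm in colnames(Z)) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    lhs <- if (parts[1] %in% colnames(X)) X[, parts[1]] else Wi[, parts[1]]
    rhs <- if (parts[2] %in% colnames(X)) X[, parts[2]] else Wi[, parts[2]]
    expect_equal(Z[, nm], lhs * rhs)
  }
  expect_false(anyDuplicated(colnames(Z)) > 0)
  # identity: product of all-ones columns is all ones
  X1 <- matrix(1, n, 2, dimnames = list(NULL, c("p", "q")))
  Zid <- expand_interactions(X1, NULL)
  expect_equal(as.vector(Zid[, "p:q"]), rep(1, n))
})

test_that("the full design has the documented column counts and scaling", {
  ch <- small_cohort(n = 150, seed = 6)
  d <- build_design(ch, "birth_weight", interactions = "full")
  p <- ncol(d$X)
  expect_equal(p, 21L)
  expect_equal(attr(d$Z, "pair_count"), choose(21, 2))
  eligible <- length(setdiff(colnames(d$W), c("intercept", "longitude:latitude")))
  expect_equal(ncol(d$Z), choose(p, 2) + p * eligible)
  expect_true(all(abs(colMeans(d$X)) < 1e-8))
  expect_true(all(abs(apply(d$X, 2, stats::sd) - 1) < 1e-8))
  # term names form a bijection onto the columns of [X | Z | W]
  all_names <- unlist(d$term_names, use.names = FALSE)
  expect_equal(length(all_names), length(unique(all_names)))
  expect_equal(length(all_names), ncol(d$X) + ncol(d$Z) + ncol(d$W))
})

test_that("coefficient of variation reproduces worked examples", {
  expect_equal(coefficient_of_variation(7.5, 0.6), 8L)
  expect_equal(coefficient_of_variation(52.2, 4.8), 9L)
  expect_equal(coefficient_of_variation(5, 5), 100L)
  expect_error(coefficient_of_variation(0, 1), "zero mean")
})

test_that("design matrices serialize to a directory of CSVs", {
  ch <- small_cohort(n = 60, seed = 13)
  d <- build_design(ch, "birth_weight", interactions = "pairs")
  dir <- withr::local_tempdir()
  write_design(d, dir)
  expect_true(all(file.exists(file.path(dir, c("y.csv", "X.csv", "Z.csv",
                                               "W.csv", "terms.csv",
                                               "scale_records.csv")))))
  X_back <- as.matrix(utils::read.csv(file.path(dir, "X.csv")))
  expect_equal(unname(X_back), unname(d$X), tolerance = 1e-12)
})
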