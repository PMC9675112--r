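test_that("noiseless construction is recovered exactly with zero SE", {
  set.seed(41)
  n <- 80
  W <- cbind(intercept = 1, w1 = stats::rnorm(n), w2 = stats::rnorm(n))
  ex <- stats::rnorm(n)
  y <- 5 * ex + W %*% c(10, 2, -3)
  res <- fit_single_exposure(ex, W, as.vector(y), "ex")
  expect_equal(res$estimate, 5, tolerance = 1e-10)
  expect_lt(res$se, 1e-8)
})

test_that("estimates agree with an independent normal-equations oracle", {
  set.seed(42)
  for (rep in 1:10) {
    n <- 50
    W <- cbind(intercept = 1, matrix(stats::rnorm(n * 3), n, 3,
                                     dimnames = list(NULL, paste0("w", 1:3))))
    ex <- stats::rnorm(n)
    y <- stats::rnorm(n, sd = 2)
    res <- fit_single_exposure(ex, W, y, "ex")
    A <- cbind(ex, W)
    coef_oracle <- solve(crossprod(A), crossprod(A, y))
    s2 <- sum((y - A %*% coef_oracle)^2) / (n - ncol(A))
    se_oracle <- sqrt(s2 * solve(crossprod(A))[1, 1])
    expect_lt(abs(res$estimate - coef_oracle[1]), 1e-8)
    expect_lt(abs(res$se - se_oracle), 1e-8)
    expect_equal(res$lower, res$estimate - 1.96 * res$se)
  }
})

test_that("a null exposure is rarely flagged", {
  set.seed(43)
  flags <- 0L
  for (rep in 1:50) {
    n <- 60
    W <- cbind(intercept = 1, w1 = stats::rnorm(n))
    ex <- stats::rnorm(n)
    y <- 3 * W[, "w1"] + stats::rnorm(n)
    res <- fit_single_exposure(ex, W, y, "ex")
    flags <- flags + (abs(res$estimate) > 3 * res$se)
  }
  expect_lte(flags, 2L)
})

test_that("rank deficiency is an error naming the collinear columns", {
  n <- 30
  W <- cbind(intercept = 1, dup = rep(1, n))
  expect_error(fit_single_exposure(stats::rnorm(n), W, stats::rnorm(n), "ex"),
               "collinear")
})

test_that("the single-exposure table has one isolated row per exposure", {
  ch <- small_cohort(n = 150, seed = 44)
  tab <- run_all_single_exposure(ch, "birth_weight")
  expect_equal(nrow(tab), 21L)
  expect_equal(tab$exposure, exposure_panel()$name)
  expect_false(anyNA(tab$estimate))
  # inject collinearity into one exposure only; other rows are unaffected
  ch2 <- ch
  ch2$pm25 <- ch$maternal_age  # duplicates a covariate column
  tab2 <- run_all_single_exposure(ch2, "birth_weight")
  expect_true(is.na(tab2$estimate[tab2$exposure == "pm25"]))
  expect_match(tab2$error[tab2$exposure == "pm25"], "collinear")
  expect_false(anyNA(tab2$estimate[tab2$exposure != "pm25"]))
  expect_equal(tab2$estimate[tab2$exposure == "ozone"],
               tab$estimate[tab$exposure == "ozone"])
})

test_that("a planted single-exposure effect is flagged and nulls are not", {
  ch <- simulate_cohort(simulation_config(
    n_dyads = 897, seed = 45, true_effects = c(unemployment = -120)))
  tab <- run_all_single_exposure(ch, "birth_weight")
  row <- tab[tab$exposure == "unemployment", ]
  expect_true(row$upper < 0)
  # under the global null, the vast majority of the 21 intervals contain 0
  # (co-exposure confounding only arises when an effect is present)
  ch0 <- small_cohort(n = 897, seed = 45)
  tab0 <- run_all_single_exposure(ch0, "birth_weight")
  expect_gte(sum(tab0$lower <= 0 & tab0$upper >= 0), 18L)
})

test_that("stratified runs partition the cohort and drop the stratifier", {
  ch <- small_cohort(n = 300, seed = 46)
  sr <- stratified_run(ch, "stratum", engine = "single_exposure")
  ns <- attr(sr, "stratum_n")
  expect_equal(sum(ns), 300L)
  expect_equal(sort(names(sr)), c("nhw", "other"))
  expect_equal(nrow(sr$nhw), 21L)

  # a stratum below the minimum size is skipped with a warning
  ch_small <- ch
  ch_small$stratum[1:295] <- "other"
  ch_small$stratum[296:300] <- "nhw"
  expect_warning(sr2 <- stratified_run(ch_small, "stratum",
                                       engine = "single_exposure"),
                 "skipped")
  expect_equal(names(sr2), "other")
})

test_that("an interaction planted in one stratum is found only there", {
  mk <- function(seed, effects) {
    simulate_cohort(simulation_config(
      n_dyads = 450, seed = seed, true_effects = effects))
  }
  a <- mk(47, stats::setNames(numeric(0), character(0)))
  b <- mk(48, c("ozone:temperature" = -320))
  a$stratum <- "A"; b$stratum <- "B"
  both <- rbind(as.data.frame(a), as.data.frame(b))
  attr(both, "exposure_spec") <- exposure_panel()
  class(both) <- c("cohort_table", "data.frame")
  sr <- stratified_run(both, "stratum", engine = "npb",
                       config = npb_config(n_iter = 1200, n_burn = 400,
                                           thin = 1, seed = 50),
                       interactions = "pairs")
  pip_a <- sr$A$summary$pip[sr$A$summary$term == "ozone:temperature"]
  pip_b <- sr$B$summary$pip[sr$B$summary$term == "ozone:temperature"]
  expect_lt(pip_a, 0.5)
  expect_gt(pip_b, 0.5)
})
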