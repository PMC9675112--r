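test_that("PIP is the exact-zero draw frequency, by independent recount", {
  b <- matrix(c(0, 0, 0, 10,
                1, 1, 0, 2), 4, 2,
              dimnames = list(NULL, c("t1", "t2")))
  ch <- fake_chain(b)
  expect_equal(compute_pip(ch, "t1"), 0.25)
  expect_equal(compute_pip(ch, "t2"), 0.75)
  # recount oracle: 1 - empirical frequency of exact zeros
  for (nm in c("t1", "t2")) {
    zeros <- sum(b[, nm] == 0)
    expect_equal(compute_pip(ch, nm), 1 - zeros / nrow(b))
  }
  expect_error(compute_pip(ch, "nope"), "unknown selection term")
})

test_that("posterior summaries match independent recomputation", {
  set.seed(8)
  nk <- 400
  b <- cbind(a = rep(3.5, nk), b = c(rep(0, 300), stats::rnorm(100, 10)))
  ch <- fake_chain(b)
  s <- summarize_posterior(ch)
  expect_equal(s$mean[s$term == "a"], 3.5)
  expect_equal(s$lower[s$term == "a"], 3.5)
  expect_equal(s$upper[s$term == "a"], 3.5)
  expect_equal(s$pip[s$term == "b"], 0.25)
  expect_equal(s$lower[s$term == "b"],
               unname(stats::quantile(b[, "b"], 0.025)))
  expect_equal(s$upper[s$term == "b"],
               unname(stats::quantile(b[, "b"], 0.975)))
  expect_true(all(s$lower <= s$upper))
})

test_that("sampler PIPs in the cluster-free limit match exact enumeration", {
  d <- tiny_design(n = 30, seed = 42)
  exact <- exact_spike_slab_pip(d, sigma2 = 1, pi0 = 0.75, tau = 1)
  fit <- npb_fit(d, npb_config(n_iter = 24000, n_burn = 4000, thin = 1,
                               mode = "independent_spike_slab",
                               fixed_sigma2 = 1, fixed_pi0 = 0.75,
                               slab_sd = 1, standardize_outcome = FALSE,
                               seed = 99))
  samp <- c(colMeans(fit$draws$beta != 0), colMeans(fit$draws$zeta != 0))
  expect_lt(max(abs(samp - exact)), 0.02)
})

test_that("enumeration oracle obeys its analytic limits", {
  d <- tiny_design(n = 30, seed = 1)
  # tau -> 0: slab indistinguishable from spike, PIP = 1 - pi0 for every term
  pips0 <- exact_spike_slab_pip(d, sigma2 = 1, pi0 = 0.6, tau = 1e-8)
  expect_equal(unname(pips0), rep(0.4, 3), tolerance = 1e-6)
  # a single near-noiseless predictor is selected with certainty
  set.seed(2)
  X <- matrix(stats::rnorm(40), 40, 1, dimnames = list(NULL, "x1"))
  y <- 3 * X[, 1] + stats::rnorm(40, 0, 1e-3)
  d1 <- design_matrices(y, X)
  expect_gt(exact_spike_slab_pip(d1, sigma2 = 1, pi0 = 0.5, tau = 1)[["x1"]],
            0.999)
  # a column orthogonal to y stays below its prior inclusion mass
  y2 <- stats::rnorm(40)
  y2 <- y2 - X[, 1] * sum(y2 * X[, 1]) / sum(X[, 1]^2)
  d2 <- design_matrices(y2, X)
  expect_lt(exact_spike_slab_pip(d2, sigma2 = 1, pi0 = 0.5, tau = 1)[["x1"]],
            0.5)
  # enumeration bound
  Xbig <- matrix(stats::rnorm(40 * 13), 40, 13)
  expect_error(exact_spike_slab_pip(design_matrices(y2, Xbig), 1, 0.5, 1),
               "enumeration bound")
})

test_that("spike draws are stored as exact zeros", {
  d <- tiny_design(n = 40, seed = 5)
  fit <- npb_fit(d, npb_config(n_iter = 1500, n_burn = 500, thin = 1, seed = 3))
  draws <- cbind(fit$draws$beta, fit$draws$zeta)
  expect_true(any(draws == 0))
  expect_true(all(draws == 0 | abs(draws) > 1e-12))
})

test_that("the sampler is reproducible given a seed and respects lengths", {
  d <- tiny_design(n = 40, seed = 5)
  cfg <- npb_config(n_iter = 800, n_burn = 300, thin = 2, seed = 7)
  f1 <- npb_fit(d, cfg)
  f2 <- npb_fit(d, cfg)
  expect_identical(f1$draws, f2$draws)
  expect_equal(f1$n_retained, (800 - 300) %/% 2)
  expect_true(all(f1$draws$sigma2 > 0))
  expect_error(npb_fit(d, npb_config(n_iter = 150, n_burn = 100, seed = 1)),
               ">= 100")
})

test_that("per-SD summaries are invariant to exposure column order", {
  set.seed(14)
  n <- 200
  X <- matrix(stats::rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 2 * X[, 1] - 1.5 * X[, 3] + stats::rnorm(n, 0, 1)
  d1 <- design_matrices(y, X)
  d2 <- design_matrices(y, X[, c(3, 1, 2)])
  cfg <- npb_config(n_iter = 4000, n_burn = 1000, thin = 1, seed = 21)
  s1 <- summarize_posterior(npb_fit(d1, cfg))
  cfg$seed <- 22L
  s2 <- summarize_posterior(npb_fit(d2, cfg))
  for (nm in c("a", "b", "c")) {
    expect_lt(abs(s1$pip[s1$term == nm] - s2$pip[s2$term == nm]), 0.05)
    expect_lt(abs(s1$mean[s1$term == nm] - s2$mean[s2$term == nm]),
              0.2 + 0.1 * abs(s1$mean[s1$term == nm]))
  }
})

test_that("sensitivity sweep agrees with itself on a single-point grid", {
  d <- tiny_design(n = 60, seed = 9, beta = c(2, 0), inter = 0)
  sw <- sensitivity_sweep(d, npb_config(n_iter = 1200, n_burn = 400, thin = 1,
                                        seed = 5), grid = 1)
  expect_equal(dim(sw$agreement), c(1L, 1L))
  expect_equal(sw$agreement[1, 1], 1)
  expect_equal(names(sw$selected), "a=b=1")
})

test_that("convergence diagnostics behave on white-noise and constant chains", {
  set.seed(30)
  nk <- 2000
  b <- cbind(t1 = stats::rnorm(nk))
  ch <- fake_chain(b, sigma2 = stats::rchisq(nk, 5))
  rep1 <- convergence_report(ch)
  ess <- rep1$ess[rep1$scalar == "t1"]
  expect_gt(ess, 0.8 * nk)
  expect_lte(ess, nk)
  # perfectly autocorrelated constant chain reports the ESS floor
  chc <- fake_chain(cbind(t1 = rep(2, nk)))
  expect_equal(convergence_report(chc)$ess[4], 1)
})

test_that("two seeds on a strong planted effect mix to PSRF < 1.1", {
  d <- tiny_design(n = 80, seed = 10, beta = c(3, 0), inter = 0, sigma = 0.8)
  cfg1 <- npb_config(n_iter = 3000, n_burn = 1000, thin = 1, seed = 1)
  cfg2 <- npb_config(n_iter = 3000, n_burn = 1000, thin = 1, seed = 2)
  f1 <- npb_fit(d, cfg1); f2 <- npb_fit(d, cfg2)
  rep2 <- convergence_report(f1, list(f2), terms = "x1")
  expect_lt(rep2$psrf[rep2$scalar == "sigma2"], 1.1)
  expect_lt(rep2$psrf[rep2$scalar == "x1"], 1.1)
})

test_that("chains persist to CSV with a JSON sidecar", {
  d <- tiny_design(n = 40, seed = 5)
  fit <- npb_fit(d, npb_config(n_iter = 600, n_burn = 200, thin = 1, seed = 3))
  dir <- withr::local_tempdir()
  write_chain(fit, dir)
  expect_true(all(file.exists(file.path(dir, c("beta.csv", "zeta.csv",
                                               "scalars.csv", "meta.json")))))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  expect_equal(meta$seed, 3L)
  expect_equal(meta$n_retained, fit$n_retained)
})
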