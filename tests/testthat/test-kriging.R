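test_that("empirical semivariogram matches hand enumeration", {
  # all-equal values: zero semivariance everywhere
  s <- monitor_snapshot(c(0, 1, 2, 5), c(0, 0, 0, 0), rep(3, 4))
  emp <- empirical_semivariogram(s, c(0, 3, 6))
  expect_equal(emp$gamma[emp$n_pairs > 0], rep(0, sum(emp$n_pairs > 0)))

  # two monitors, values 0 and 2, one bin: gamma = (1/2)(2^2)/1 = 2
  s2 <- monitor_snapshot(c(0, 1), c(0, 0), c(0, 2))
  emp2 <- empirical_semivariogram(s2, c(0, 2))
  expect_equal(emp2$gamma, 2)
  expect_equal(emp2$n_pairs, 1L)

  # five monitors on a line, linear values: brute-force pair loop oracle
  x <- 0:4
  v <- 2 * x + 1
  s3 <- monitor_snapshot(x, rep(0, 5), v)
  bins <- c(0, 1.5, 2.5, 3.5, 4.5)
  emp3 <- empirical_semivariogram(s3, bins)
  brute <- sapply(seq_len(length(bins) - 1), function(b) {
    acc <- c(); cnt <- 0
    for (i in 1:4) for (j in (i + 1):5) {
      d <- abs(x[i] - x[j])
      inbin <- if (b == 1) d >= bins[1] & d <= bins[2] else
        d > bins[b] & d <= bins[b + 1]
      if (inbin) { acc <- c(acc, (v[i] - v[j])^2); cnt <- cnt + 1 }
    }
    if (cnt == 0) NA_real_ else sum(acc) / (2 * cnt)
  })
  expect_equal(emp3$gamma, brute)
})

test_that("empty bins are reported with zero counts", {
  s <- monitor_snapshot(c(0, 10), c(0, 0), c(1, 2))
  emp <- empirical_semivariogram(s, c(0, 1, 5, 11))
  expect_equal(emp$n_pairs, c(0L, 0L, 1L))
  expect_true(all(is.na(emp$gamma[1:2])))
})

test_that("variogram fitting recovers noiseless model parameters", {
  lag <- seq(0.5, 15, by = 0.5)
  emp <- data.frame(lag = lag,
                    gamma = semivariance(lag, "exponential", 0, 1, 5),
                    n_pairs = 10L)
  f <- fit_variogram(emp, "exponential")
  expect_lt(abs(f$nugget - 0), 1e-4)
  expect_lt(abs(f$psill - 1), 1e-4)
  expect_lt(abs(f$range - 5), 1e-4)

  emp2 <- data.frame(lag = lag,
                     gamma = semivariance(lag, "spherical", 0.4, 2, 6),
                     n_pairs = 7L)
  f2 <- fit_variogram(emp2, "spherical")
  expect_lt(abs(f2$nugget - 0.4), 1e-4)
  expect_lt(abs(f2$psill - 2), 1e-4)
  expect_lt(abs(f2$range - 6), 1e-4)
})

test_that("flat variograms collapse to a pure-nugget model", {
  emp <- data.frame(lag = 1:6, gamma = rep(0.7, 6), n_pairs = 4L)
  f <- fit_variogram(emp, "exponential")
  expect_equal(f$nugget, 0.7, tolerance = 1e-8)
  expect_lt(f$psill, 1e-6)
})

test_that("fewer than three non-empty bins is an error", {
  emp <- data.frame(lag = c(1, NA, NA), gamma = c(0.5, NA, NA),
                    n_pairs = c(3L, 0L, 0L))
  expect_error(fit_variogram(emp), ">= 3 non-empty")
})

test_that("ordinary kriging is exact at monitor sites with zero nugget", {
  set.seed(21)
  m <- variogram_model("exponential", nugget = 0, psill = 2, range = 6)
  snap <- monitor_snapshot(stats::runif(6, 0, 20), stats::runif(6, 0, 20),
                           stats::rnorm(6, 50, 4))
  for (i in 1:6) {
    kp <- krige_point(m, snap, c(snap$x_km[i], snap$y_km[i]))
    expect_lt(abs(kp$prediction - snap$value[i]), 1e-8)
  }
})

test_that("kriging weights sum to one and variance is nonnegative", {
  set.seed(22)
  m <- variogram_model("exponential", nugget = 0.3, psill = 1.5, range = 8)
  for (rep in 1:20) {
    k <- sample(2:8, 1)
    snap <- monitor_snapshot(stats::runif(k, 0, 30), stats::runif(k, 0, 30),
                             stats::rnorm(k, 10, 2))
    kp <- krige_point(m, snap, stats::runif(2, 0, 30))
    expect_lt(abs(sum(kp$weights) - 1), 1e-8)
    expect_gte(kp$variance, 0)
  }
})

test_that("two equidistant monitors share weight equally", {
  m <- variogram_model("exponential", nugget = 0, psill = 1, range = 5)
  snap <- monitor_snapshot(c(0, 10), c(0, 0), c(40, 50))
  kp <- krige_point(m, snap, c(5, 0))
  expect_equal(kp$weights, c(0.5, 0.5), tolerance = 1e-10)
  expect_equal(kp$prediction, 45)
})

test_that("a single monitor predicts its own value everywhere", {
  m <- variogram_model("exponential", nugget = 0.1, psill = 1, range = 5)
  snap <- monitor_snapshot(3, 4, 42)
  kp <- krige_point(m, snap, c(20, 20))
  expect_equal(kp$prediction, 42)
  expect_equal(kp$weights, 1)
})

test_that("kriging predictions are translation-equivariant", {
  set.seed(23)
  m <- variogram_model("exponential", nugget = 0.2, psill = 1, range = 7)
  snap <- monitor_snapshot(stats::runif(5, 0, 20), stats::runif(5, 0, 20),
                           stats::rnorm(5))
  target <- c(8, 12)
  p0 <- krige_point(m, snap, target)$prediction
  snap$value <- snap$value + 100
  expect_equal(krige_point(m, snap, target)$prediction, p0 + 100,
               tolerance = 1e-8)
})

test_that("co-located monitors are averaged before solving", {
  m <- variogram_model("exponential", nugget = 0, psill = 1, range = 5)
  snap <- monitor_snapshot(c(0, 0, 10), c(0, 0, 0), c(40, 44, 50))
  kp <- krige_point(m, snap, c(5, 0))
  expect_equal(length(kp$weights), 2L)
  expect_equal(kp$prediction,
               krige_point(m, monitor_snapshot(c(0, 10), c(0, 0), c(42, 50)),
                           c(5, 0))$prediction)
})
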