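# Ordinary kriging: semivariogram models, empirical semivariograms, weighted
# least-squares variogram fitting, and the standard constrained kriging solve.

#' Semivariance of a parametric variogram model
#'
#' Exponential: `gamma(h) = nugget + psill * (1 - exp(-h / range))` for h > 0.
#' Spherical: `gamma(h) = nugget + psill * (1.5 h/r - 0.5 (h/r)^3)` for
#' `h <= range`, `nugget + psill` beyond. `gamma(0) = nugget` by convention
#' (the nugget is a discontinuity at the origin; co-located points share it).
#'
#' @param h Lag distances (km), vector or matrix.
#' @param family `"exponential"` or `"spherical"`.
#' @param nugget,psill,range Model parameters (nugget >= 0, psill >= 0,
#'   range > 0).
#' @return Semivariances, same shape as `h`.
#' @export
semivariance <- function(h, family = c("exponential", "spherical"),
                         nugget, psill, range) {
  family <- match.arg(family)
  stopifnot(nugget >= 0, psill >= 0, range > 0)
  g <- if (family == "exponential") {
    psill * (1 - exp(-h / range))
  } else {
    hr <- pmin(h / range, 1)
    psill * (1.5 * hr - 0.5 * hr^3)
  }
  g <- g + nugget
  g[h == 0] <- nugget
  g
}

#' Construct a variogram model object
#'
#' @inheritParams semivariance
#' @return Object of class `variogram_model` with fields `family`, `nugget`,
#'   `psill`, `range`.
#' @export
variogram_model <- function(family = c("exponential", "spherical"),
                            nugget, psill, range) {
  family <- match.arg(family)
  stopifnot(nugget >= 0, psill > 0 || nugget > 0, range > 0)
  structure(list(family = family, nugget = nugget, psill = psill, range = range),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("variogram_model: %s(nugget = %.4g, psill = %.4g, range = %.4g km)\n",
              x$family, x$nugget, x$psill, x$range))
  invisible(x)
}

#' Empirical semivariogram of a spatial snapshot
#'
#' Classical (Matheron) estimator: for each lag bin, half the mean squared
#' difference over all monitor pairs whose separation falls in the bin.
#'
#' @param snapshot data.frame with columns `x_km`, `y_km`, `value` (one row
#'   per monitor; >= 2 monitors).
#' @param bins Increasing vector of lag-bin edges (km); bin b is
#'   `(bins[b], bins[b+1]]` with the first bin closed at its left edge.
#' @return data.frame with one row per bin: `lag` (mean pair distance, NA if
#'   empty), `gamma` (semivariance, NA if empty), `n_pairs`.
#' @export
empirical_semivariogram <- function(snapshot, bins) {
  stopifnot(nrow(snapshot) >= 2, length(bins) >= 2, !is.unsorted(bins))
  D <- as.matrix(stats::dist(snapshot[, c("x_km", "y_km")]))
  v <- snapshot$value
  iu <- which(upper.tri(D), arr.ind = TRUE)
  d <- D[iu]
  sq <- (v[iu[, 1]] - v[iu[, 2]])^2
  idx <- findInterval(d, bins, left.open = TRUE, rightmost.closed = FALSE)
  idx[d == bins[1]] <- 1L  # left edge of the first bin is included
  nb <- length(bins) - 1L
  out <- data.frame(lag = rep(NA_real_, nb), gamma = rep(NA_real_, nb),
                    n_pairs = integer(nb))
  for (b in seq_len(nb)) {
    sel <- idx == b
    out$n_pairs[b] <- sum(sel)
    if (out$n_pairs[b] > 0) {
      out$lag[b] <- mean(d[sel])
      out$gamma[b] <- sum(sq[sel]) / (2 * out$n_pairs[b])
    }
  }
  out
}

#' Fit a variogram model to an empirical semivariogram
#'
#' Weighted least squares with pair-count weights: minimizes
#' `sum_b N_b * (gamma_b - gamma_model(lag_b))^2` over (nugget, partial sill,
#' range), subject to nugget >= 0, psill >= 0, range > 0. Because the model
#' is linear in (nugget, psill) for a fixed range, the fit is profiled:
#' nugget and partial sill are solved by constrained weighted linear least
#' squares at each candidate range, and the range is found by a grid scan
#' followed by a high-precision 1-D search, with a Levenberg-Marquardt polish.
#' A flat empirical variogram collapses to a pure-nugget solution.
#'
#' @param empirical data.frame as from [empirical_semivariogram()].
#' @param family Variogram family.
#' @return A `variogram_model`.
#' @export
fit_variogram <- function(empirical, family = c("exponential", "spherical")) {
  family <- match.arg(family)
  emp <- empirical[!is.na(empirical$gamma) & empirical$n_pairs > 0, , drop = FALSE]
  if (nrow(emp) < 3) {
    stop("need >= 3 non-empty lag bins to fit a variogram (got ", nrow(emp), ")")
  }
  lag <- emp$lag; gam <- emp$gamma; w <- emp$n_pairs

  gmax <- max(gam); gmin <- min(gam)
  if (gmax - gmin < 1e-12 * max(gmax, 1)) {
    return(variogram_model(family, nugget = stats::weighted.mean(gam, w),
                           psill = 1e-12, range = max(lag)))
  }

  # Profiled WLS: for fixed range, solve (nugget, psill) >= 0 in closed form.
  profile <- function(rng) {
    g <- semivariance(lag, family, 0, 1, rng)  # unit-psill shape, nugget 0
    A <- cbind(1, g)
    WA <- A * w
    fit <- tryCatch(solve(crossprod(WA, A), crossprod(WA, gam)),
                    error = function(e) c(stats::weighted.mean(gam, w), 0))
    nug <- fit[1]; ps <- fit[2]
    if (nug < 0) {
      nug <- 0
      ps <- sum(w * g * gam) / sum(w * g^2)
    }
    if (ps < 0) {
      ps <- 0
      nug <- stats::weighted.mean(gam, w)
    }
    list(par = c(nug, ps, rng),
         obj = sum(w * (gam - nug - ps * g)^2))
  }
  grid <- exp(seq(log(max(min(lag[lag > 0]) / 10, 1e-6)),
                  log(max(lag) * 20), length.out = 80))
  objs <- vapply(grid, function(r) profile(r)$obj, numeric(1))
  i <- which.min(objs)
  lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
  op <- stats::optimize(function(r) profile(r)$obj, c(lo, hi), tol = 1e-12)
  best <- profile(op$minimum)

  # Levenberg-Marquardt polish from the profiled solution.
  lower <- c(0, 0, 1e-8)
  upper <- c(gmax * 2 + 1e-8, gmax * 4 + 1e-8, max(lag) * 40)
  start <- pmin(pmax(best$par, lower + c(0, 1e-10, 1e-8)), upper)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      gam ~ semivariance(lag, family, nugget, psill, range),
      start = list(nugget = start[1], psill = start[2], range = start[3]),
      weights = w, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)
    ),
    error = function(e) NULL
  )
  par <- best$par
  if (!is.null(fit)) {
    cand <- stats::coef(fit)
    obj_cand <- sum(w * (gam - semivariance(lag, family, cand[1], cand[2],
                                            cand[3]))^2)
    if (obj_cand < best$obj) par <- cand
  }
  if (any(!is.finite(par))) {
    stop("variogram fit failed; empirical table: ",
         paste(utils::capture.output(print(emp)), collapse = "\n"))
  }
  variogram_model(family, nugget = max(par[1], 0), psill = max(par[2], 1e-12),
                  range = max(par[3], 1e-8))
}

#' Ordinary-kriging prediction at a target point
#'
#' Solves the standard ordinary-kriging system with a Lagrange multiplier so
#' the weights sum to one: `[Gamma 1; 1' 0] [w; mu] = [g0; 1]` where `Gamma`
#' is the monitor-pair semivariance matrix and `g0` the monitor-to-target
#' semivariances. Co-located monitors are averaged before solving so the
#' system is nonsingular.
#'
#' @param model A `variogram_model`.
#' @param snapshot data.frame with `x_km`, `y_km`, `value`, one row per
#'   monitor (>= 1).
#' @param target Length-2 numeric `c(x_km, y_km)`.
#' @return List: `prediction`, `variance` (kriging variance, clamped at 0 with
#'   a warning if negative by round-off), `weights` (after deduplication),
#'   `lagrange`.
#' @export
krige_point <- function(model, snapshot, target) {
  stopifnot(inherits(model, "variogram_model"), nrow(snapshot) >= 1,
            length(target) == 2, all(is.finite(target)))
  snap <- dedupe_monitors(snapshot)
  m <- nrow(snap)
  if (m == 1) {
    return(list(prediction = snap$value, variance = max(
      2 * semivariance(sqrt(sum((c(snap$x_km, snap$y_km) - target)^2)),
                       model$family, model$nugget, model$psill, model$range), 0),
      weights = 1, lagrange = NA_real_))
  }
  coords <- as.matrix(snap[, c("x_km", "y_km")])
  D <- as.matrix(stats::dist(coords))
  G <- semivariance(D, model$family, model$nugget, model$psill, model$range)
  diag(G) <- 0  # gamma(0) = 0 for a point with itself in the kriging system
  d0 <- sqrt(colSums((t(coords) - target)^2))
  g0 <- semivariance(d0, model$family, model$nugget, model$psill, model$range)
  g0[d0 == 0] <- 0  # exact interpolation at a monitor site (nugget excluded)
  A <- rbind(cbind(G, 1), c(rep(1, m), 0))
  b <- c(g0, 1)
  sol <- tryCatch(solve(A, b), error = function(e) {
    stop("singular ordinary-kriging system after deduplication: ",
         conditionMessage(e))
  })
  w <- unname(sol[seq_len(m)])
  mu <- unname(sol[m + 1])
  pred <- sum(w * snap$value)
  kvar <- sum(w * g0) + mu
  if (kvar < 0) {
    if (kvar < -1e-6) warning("kriging variance ", kvar, " clamped to 0")
    kvar <- 0
  }
  list(prediction = pred, variance = kvar, weights = w, lagrange = mu)
}

# Average co-located monitors (exact coordinate ties) into single records.
dedupe_monitors <- function(snapshot) {
  key <- paste(snapshot$x_km, snapshot$y_km, sep = "|")
  if (!anyDuplicated(key)) return(snapshot)
  agg <- stats::aggregate(snapshot$value, by = list(key = key), FUN = mean)
  first <- snapshot[!duplicated(key), c("x_km", "y_km")]
  first <- first[match(agg$key, unique(key)), , drop = FALSE]
  data.frame(x_km = first$x_km, y_km = first$y_km, value = agg$x)
}

#' Krige one snapshot to many target points
#'
#' @param model A `variogram_model`.
#' @param snapshot Monitor snapshot as in [krige_point()].
#' @param targets data.frame/matrix with columns `x_km`, `y_km`.
#' @return data.frame with `x_km`, `y_km`, `prediction`, `variance`.
#' @export
krige_to_points <- function(model, snapshot, targets) {
  targets <- as.data.frame(targets)
  res <- lapply(seq_len(nrow(targets)), function(i) {
    kp <- krige_point(model, snapshot, c(targets$x_km[i], targets$y_km[i]))
    data.frame(x_km = targets$x_km[i], y_km = targets$y_km[i],
               prediction = kp$prediction, variance = kp$variance)
  })
  do.call(rbind, res)
}
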