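# Simulated air-monitor networks: daily values at fixed planar locations
# drawn from a stationary Gaussian random field, the input to the kriging
# exposure-assignment stage.

#' Simulate a daily monitor series from a stationary Gaussian random field
#'
#' Places `n_monitors` uniformly in a planar bounding box (projected km) and
#' draws `n_days` independent daily realizations of a stationary Gaussian
#' random field with the given semivariogram family. Day-to-day independence
#' keeps the spatial covariance exactly the stated one; the kriging stage
#' operates on one day (or one biweekly aggregate) at a time.
#'
#' @param n_monitors Number of monitors (>= 1).
#' @param region Bounding box `c(xmin, xmax, ymin, ymax)` in km; must have
#'   positive width and height.
#' @param field_spec List: `family` (`"exponential"` or `"spherical"`),
#'   `sill` (partial sill, variance units, >= 0), `range` (km, > 0), `nugget`
#'   (>= 0), `mean` (field mean, native units).
#' @param n_days Number of daily realizations.
#' @param seed Integer seed.
#' @param start_date First date of the series (default `"2009-01-01"`).
#' @return A `monitor_series`: long data.frame with columns `monitor_id`,
#'   `x_km`, `y_km`, `date`, `value`, plus attributes `locations` and
#'   `field_spec`.
#' @examples
#' ms <- simulate_monitors(5, c(0, 50, 0, 50),
#'   list(family = "exponential", sill = 1, range = 10, nugget = 0, mean = 48),
#'   n_days = 14, seed = 1)
#' head(ms)
#' @export
simulate_monitors <- function(n_monitors, region, field_spec, n_days,
                              seed = 1L, start_date = as.Date("2009-01-01")) {
  stopifnot(n_monitors >= 1, n_days >= 1, length(region) == 4)
  if (region[2] <= region[1] || region[4] <= region[3]) {
    stop("degenerate bounding box: need xmax > xmin and ymax > ymin")
  }
  fs <- field_spec
  stopifnot(fs$sill >= 0, fs$range > 0, fs$nugget >= 0)
  if (is.null(fs$mean)) fs$mean <- 0
  with_seed(seed, {
    x <- stats::runif(n_monitors, region[1], region[2])
    y <- stats::runif(n_monitors, region[3], region[4])
    D <- as.matrix(stats::dist(cbind(x, y)))
    # Covariance C(h) = sill + nugget - gamma(h); nugget on the diagonal only.
    C <- (fs$sill + fs$nugget) -
      semivariance(D, fs$family, fs$nugget, fs$sill, fs$range)
    diag(C) <- fs$sill + fs$nugget
    if (fs$sill + fs$nugget == 0) {
      vals <- matrix(0, n_monitors, n_days)
    } else {
      L <- chol(C + diag(1e-10 * max(1, fs$sill + fs$nugget), n_monitors))
      vals <- t(L) %*% matrix(stats::rnorm(n_monitors * n_days), n_monitors, n_days)
    }
    vals <- vals + fs$mean
    out <- data.frame(
      monitor_id = rep(sprintf("mon_%02d", seq_len(n_monitors)), times = n_days),
      x_km = rep(x, times = n_days),
      y_km = rep(y, times = n_days),
      date = rep(start_date + seq_len(n_days) - 1, each = n_monitors),
      value = as.vector(vals),
      stringsAsFactors = FALSE
    )
    attr(out, "locations") <- data.frame(
      monitor_id = sprintf("mon_%02d", seq_len(n_monitors)), x_km = x, y_km = y,
      stringsAsFactors = FALSE
    )
    attr(out, "field_spec") <- fs
    class(out) <- c("monitor_series", "data.frame")
    out
  })
}
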