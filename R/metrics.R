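# Temporal exposure metrics: daily 8-hour maxima for ozone, biweekly
# aggregation of daily values, the biweekly calendar, and pregnancy-duration
# averaging of biweekly predictions.

#' Daily maximum 8-hour mean
#'
#' The ozone daily metric: the maximum over all 17 contiguous 8-hour window
#' means in a 24-hour day. A day needs at least `min_hours` non-missing hours
#' to be valid; a window needs at least `min_window_hours` non-missing hours
#' to contribute. Returns `NA` (a missing-value sentinel, not an error) when
#' the completeness rule fails.
#'
#' @param hourly_values Numeric vector of 24 ordered hourly values (may
#'   contain `NA`).
#' @param min_hours Minimum valid hours per day (default 18).
#' @param min_window_hours Minimum valid hours per 8-hour window (default 6).
#' @return The daily 8-h max, or `NA_real_`.
#' @examples
#' daily_8h_max(1:24)  # 20.5, achieved by hours 17-24
#' @export
daily_8h_max <- function(hourly_values, min_hours = 18L, min_window_hours = 6L) {
  stopifnot(length(hourly_values) == 24)
  if (sum(!is.na(hourly_values)) < min_hours) return(NA_real_)
  means <- vapply(1:17, function(s) {
    w <- hourly_values[s:(s + 7)]
    if (sum(!is.na(w)) < min_window_hours) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
  if (all(is.na(means))) return(NA_real_)
  max(means, na.rm = TRUE)
}

#' Aggregate daily values to a biweekly metric
#'
#' Mean of the available daily metric values within a 14-day window. For
#' PM2.5 and temperature the daily values are 24-hour means (`mean24h`); for
#' ozone they are daily 8-hour maxima (`mean_of_daily_8h_max`) — the metric
#' label records the convention, the arithmetic is the same once the daily
#' series is on the right metric. At least one valid day is required;
#' otherwise `NA`.
#'
#' @param daily_values Numeric vector of 14 daily values (may contain `NA`).
#' @param metric `"mean24h"` or `"mean_of_daily_8h_max"`.
#' @return Biweekly value, or `NA_real_` when no day is available.
#' @export
biweekly_aggregate <- function(daily_values,
                               metric = c("mean24h", "mean_of_daily_8h_max")) {
  match.arg(metric)
  stopifnot(length(daily_values) == 14)
  if (all(is.na(daily_values))) return(NA_real_)
  mean(daily_values, na.rm = TRUE)
}

#' Biweekly calendar
#'
#' Consecutive 14-day blocks anchored at `anchor` (default 2009-01-01),
#' covering `[from, to]`.
#'
#' @param from,to Dates delimiting the span to cover.
#' @param anchor Anchor date for period boundaries.
#' @return data.frame with `period`, `start`, `end` (inclusive).
#' @export
biweekly_calendar <- function(from, to, anchor = as.Date("2009-01-01")) {
  from <- as.Date(from); to <- as.Date(to); anchor <- as.Date(anchor)
  stopifnot(to >= from)
  k0 <- floor(as.numeric(from - anchor) / 14)
  k1 <- floor(as.numeric(to - anchor) / 14)
  ks <- k0:k1
  data.frame(period = ks - k0 + 1L,
             start = anchor + 14 * ks,
             end = anchor + 14 * ks + 13)
}

#' Pregnancy-duration average of biweekly predictions
#'
#' Averages the biweekly predictions whose periods overlap
#' `[conception_date, delivery_date]`, weighting each by its days of overlap
#' (inclusive day counts). Returns `NA` when no period overlaps. `NA`
#' predictions in overlapping periods are dropped (their weight is excluded).
#'
#' @param biweekly data.frame with columns `start`, `end` (Dates, inclusive)
#'   and `value`.
#' @param conception_date,delivery_date Pregnancy span (Dates,
#'   delivery > conception).
#' @return Day-weighted average, or `NA_real_`.
#' @examples
#' bw <- data.frame(start = as.Date(c("2010-01-01", "2010-01-15")),
#'                  end = as.Date(c("2010-01-14", "2010-01-28")),
#'                  value = c(10, 16))
#' pregnancy_average(bw, as.Date("2010-01-01"), as.Date("2010-01-21"))  # 12
#' @export
pregnancy_average <- function(biweekly, conception_date, delivery_date) {
  conception_date <- as.Date(conception_date)
  delivery_date <- as.Date(delivery_date)
  stopifnot(delivery_date > conception_date)
  ov <- pmax(0, as.numeric(pmin(as.Date(biweekly$end), delivery_date) -
                           pmax(as.Date(biweekly$start), conception_date)) + 1)
  keep <- ov > 0 & !is.na(biweekly$value)
  if (!any(keep)) return(NA_real_)
  sum(biweekly$value[keep] * ov[keep]) / sum(ov[keep])
}

#' Assign kriged pregnancy-average exposures to dyads
#'
#' The full exposure-assessment chain for one pollutant: aggregate the daily
#' monitor series to biweekly values per monitor, fit a variogram per biweek
#' (pooled-fit option: one variogram fitted to the first biweek is reused when
#' `refit_each = FALSE`), krige each biweekly surface to each dyad's location,
#' and average the biweekly predictions over each pregnancy.
#'
#' @param monitors A `monitor_series` (daily values).
#' @param dyads data.frame with `dyad_id`, `x_km`, `y_km`, `conception_date`,
#'   `delivery_date`.
#' @param metric Daily-to-biweekly metric label (see [biweekly_aggregate()]).
#' @param family Variogram family.
#' @param bins Lag-bin edges (km) for the empirical semivariogram; default 8
#'   equal bins to half the maximum inter-monitor distance.
#' @param anchor Biweekly calendar anchor.
#' @param refit_each Refit the variogram for every biweek (default FALSE).
#' @return data.frame keyed by `dyad_id` with `pregnancy_avg`, `n_periods`
#'   (periods contributing), plus attribute `biweekly` holding the per-period
#'   predictions per dyad.
#' @export
assign_exposures <- function(monitors, dyads,
                             metric = c("mean24h", "mean_of_daily_8h_max"),
                             family = "exponential", bins = NULL,
                             anchor = as.Date("2009-01-01"),
                             refit_each = FALSE) {
  metric <- match.arg(metric)
  locs <- attr(monitors, "locations")
  if (is.null(locs)) {
    locs <- unique(monitors[, c("monitor_id", "x_km", "y_km")])
  }
  cal <- biweekly_calendar(min(monitors$date), max(monitors$date), anchor)
  # biweekly value per monitor per period
  per <- findInterval(as.numeric(as.Date(monitors$date) - cal$start[1]),
                      seq(0, by = 14, length.out = nrow(cal) + 1),
                      left.open = FALSE, rightmost.closed = FALSE)
  biwk <- lapply(seq_len(nrow(cal)), function(b) {
    sub <- monitors[per == b, , drop = FALSE]
    v <- vapply(locs$monitor_id, function(id) {
      dv <- sub$value[sub$monitor_id == id]
      if (!length(dv)) NA_real_ else mean(dv, na.rm = TRUE)
    }, numeric(1))
    data.frame(x_km = locs$x_km, y_km = locs$y_km, value = v)
  })

  if (is.null(bins)) {
    dmax <- max(stats::dist(locs[, c("x_km", "y_km")]))
    bins <- seq(0, dmax * 1.001, length.out = 7)
  }
  model <- NULL
  preds <- matrix(NA_real_, nrow(dyads), nrow(cal))
  for (b in seq_len(nrow(cal))) {
    snap <- biwk[[b]][!is.na(biwk[[b]]$value), , drop = FALSE]
    if (nrow(snap) < 2) next
    if (is.null(model) || refit_each) {
      emp <- empirical_semivariogram(snap, bins)
      model <- tryCatch(fit_variogram(emp, family), error = function(e) {
        # sparse networks can leave too few occupied lag bins for a fit;
        # fall back to a moment-based model rather than dropping the period
        message("variogram fit fell back to moments for period ", b, ": ",
                conditionMessage(e))
        dmax <- max(stats::dist(snap[, c("x_km", "y_km")]))
        variogram_model(family, nugget = 0,
                        psill = max(stats::var(snap$value), 1e-12),
                        range = dmax / 3)
      })
    }
    kp <- krige_to_points(model, snap,
                          data.frame(x_km = dyads$x_km, y_km = dyads$y_km))
    preds[, b] <- kp$prediction
  }

  avg <- numeric(nrow(dyads)); npd <- integer(nrow(dyads))
  for (i in seq_len(nrow(dyads))) {
    bi <- data.frame(start = cal$start, end = cal$end, value = preds[i, ])
    avg[i] <- pregnancy_average(bi, dyads$conception_date[i],
                                dyads$delivery_date[i])
    ov <- pmax(0, as.numeric(pmin(cal$end, as.Date(dyads$delivery_date[i])) -
                             pmax(cal$start, as.Date(dyads$conception_date[i]))) + 1)
    npd[i] <- sum(ov > 0 & !is.na(preds[i, ]))
  }
  out <- data.frame(dyad_id = dyads$dyad_id, pregnancy_avg = avg,
                    n_periods = npd, stringsAsFactors = FALSE)
  attr(out, "biweekly") <- preds
  attr(out, "calendar") <- cal
  attr(out, "model") <- model
  out
}
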