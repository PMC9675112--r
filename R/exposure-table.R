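#' Default census-tract exposure panel
#'
#' Returns the 21 neighborhood-level exposures used throughout the package:
#' twelve environmental variables (air pollutants, temperature, built
#' environment, distances to hazardous land uses) and nine social variables
#' (hospitalization rates, crime rates, census socioeconomic indicators), each
#' with its unit, marginal mean and standard deviation, and domain group.
#' These marginals drive the synthetic-cohort generator and fix the canonical
#' exposure ordering used by design matrices and result tables.
#'
#' @return A data.frame with columns `name`, `label`, `unit`, `mean`, `sd`,
#'   and `group` (`"environmental"` or `"social"`), one row per exposure.
#' @examples
#' exposure_panel()
#' @export
exposure_panel <- function() {
  out <- data.frame(
    name = c(
      "pm25", "ozone", "temperature", "tree_cover", "impervious", "aadt",
      "dist_tri", "dist_npl", "dist_waste", "dist_emitters", "dist_cafos",
      "dist_mines_wells",
      "cvd_hosp", "resp_hosp", "violent_crime", "property_crime",
      "less_than_hs", "unemployment", "poverty", "limited_english",
      "persons_of_color"
    ),
    label = c(
      "Mean PM2.5", "Mean O3", "Mean temperature", "Tree cover",
      "Impervious surfaces", "AADT", "Distance to TRI sites",
      "Distance to NPL sites", "Distance to waste management sites",
      "Distance to major emitters", "Distance to CAFOs",
      "Distance to mines or wells",
      "CVD hospitalizations", "Respiratory hospitalizations",
      "Violent crimes", "Property crimes", "Less than HS diploma",
      "Unemployment", "Households in poverty",
      "Households speaking limited English", "Percent persons of color"
    ),
    unit = c(
      "ug/m3", "ppb", "degF", "%", "%", "vehicles/d-km2",
      "km", "km", "km", "km", "km", "km",
      "n/10,000", "n/10,000", "n/1,000", "n/1,000", "%", "%", "%", "%", "%"
    ),
    mean = c(
      7.5, 48.0, 52.2, 6.3, 40.5, 10344,
      3.9, 5.5, 5.2, 8.3, 36.8, 3.4,
      244.0, 165.2, 12.8, 55.4, 16.5, 9.7, 15.3, 8.3, 54.3
    ),
    sd = c(
      0.6, 3.1, 4.8, 3.1, 13.3, 8203,
      2.6, 3.3, 2.3, 3.2, 6.8, 2.1,
      45.2, 33.0, 6.3, 36.0, 12.7, 5.0, 10.9, 8.3, 22.9
    ),
    group = rep(c("environmental", "social"), c(12L, 9L)),
    stringsAsFactors = FALSE
  )
  out
}

#' Coefficient of variation, in whole percent
#'
#' `100 * sd / |mean|`, rounded to the nearest whole percent — the dispersion
#' measure used in exposure summary tables.
#'
#' @param mean Mean of the variable (native units); must be nonzero.
#' @param sd Standard deviation (same units).
#' @return Integer percent.
#' @examples
#' coefficient_of_variation(7.5, 0.6)   # 8
#' coefficient_of_variation(10344, 8203) # 79
#' @export
coefficient_of_variation <- function(mean, sd) {
  stopifnot(is.numeric(mean), is.numeric(sd), length(mean) == length(sd))
  if (any(mean == 0)) stop("coefficient of variation undefined for zero mean")
  as.integer(round(100 * sd / abs(mean)))
}

#' Table of exposure summary statistics
#'
#' Computes a publication-style exposure summary (mean, SD, min, median, max,
#' CV) from a cohort table, in the canonical exposure order.
#'
#' @param cohort A `cohort_table` (see [simulate_cohort()]).
#' @return data.frame with one row per exposure.
#' @export
summarize_exposures <- function(cohort) {
  panel <- attr(cohort, "exposure_spec")
  if (is.null(panel)) panel <- exposure_panel()
  rows <- lapply(panel$name, function(nm) {
    v <- cohort[[nm]]
    data.frame(
      name = nm, mean = mean(v), sd = stats::sd(v), min = min(v),
      median = stats::median(v), max = max(v),
      cv = coefficient_of_variation(mean(v), stats::sd(v)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
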