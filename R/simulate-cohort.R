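# Synthetic cohort generator: a Gaussian-copula emulation of a pregnancy
# cohort with census-tract exposures, individual covariates, and a sparse
# linear outcome model (including planted exposure-by-exposure interactions).

#' Default covariate frequencies and moments for the synthetic cohort
#'
#' Category frequencies and continuous moments for maternal and infant
#' covariates: race/ethnicity, education, smoking, second-hand smoke, infant
#' sex, maternal age, perceived stress (CPSS), depressive symptoms (EPDS),
#' pre-pregnancy BMI, residential longitude/latitude, days from delivery to
#' body-composition measurement, gestation length, and conception dates.
#'
#' @return Named list of category probability vectors and `c(mean, sd)` (or
#'   `c(mean, sd, lower, upper)` for truncated normals) moment vectors.
#' @export
default_covariate_spec <- function() {
  list(
    race = c(hispanic = 238, nhw = 445, african_american = 154, other = 60) / 897,
    education = c(less_than_hs = 137, hs_ged = 166, some_college = 208,
                  bachelors = 196, graduate = 190) / 897,
    smoking = c(no = 819, yes = 78) / 897,
    shs = c(no = 666, yes = 231) / 897,
    infant_sex = c(female = 438, male = 459) / 897,
    maternal_age = c(27.6, 6.2, 16, 50),
    cpss = c(18.6, 3.1, 0, 40),
    epds = c(4.3, 3.3, 0, 30),
    bmi = c(25.7, 5.5, 15, 55),
    longitude = c(-104.9, 0.11),
    latitude = c(39.7, 0.09),
    days_to_peapod = c(1.6, 2.5, 0, 14),
    gestation_days = c(275, 13, 196, 301),
    conception_years = 2009:2014,
    adiposity = c(9.0, 4.0, 0, 100)
  )
}

#' Build a validated simulation configuration
#'
#' Assembles every input the synthetic-cohort generator needs: sample size,
#' exposure marginals, the block correlation structure, covariate frequencies,
#' the sparse true-effect map (in outcome units per 1 SD of each standardized
#' predictor, with `"a:b"` naming a product of two standardized exposures),
#' residual SD, outcome mean, and the seed.
#'
#' The exposure correlation matrix is either supplied directly (`corr_matrix`)
#' or drawn once from the block ranges in `correlation_spec` (uniform entries
#' within each block) and projected to the nearest positive-definite
#' correlation matrix.
#'
#' @param n_dyads Number of mother-child dyads (>= 2).
#' @param exposure_spec data.frame as from [exposure_panel()].
#' @param correlation_spec List with elements `env`, `social`, `cross`, each a
#'   length-2 range of pairwise correlations for the within-environmental,
#'   within-social, and cross-block entries.
#' @param corr_matrix Optional fixed exposure correlation matrix (overrides
#'   `correlation_spec`).
#' @param covariate_spec As from [default_covariate_spec()].
#' @param true_effects Named numeric vector; names are exposure names or
#'   `"a:b"` interaction terms, values in grams per SD (per SD x SD for
#'   interactions).
#' @param residual_sd Residual SD of the outcome, grams.
#' @param outcome_mean Mean birth weight, grams.
#' @param seed Integer seed controlling all randomness.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_dyads = 897,
                              exposure_spec = exposure_panel(),
                              correlation_spec = list(env = c(-0.5, 0.7),
                                                      social = c(-0.1, 0.9),
                                                      cross = c(-0.3, 0.5)),
                              corr_matrix = NULL,
                              covariate_spec = default_covariate_spec(),
                              true_effects = c(ozone = -6.4,
                                               temperature = 13.1,
                                               "ozone:temperature" = -162),
                              residual_sd = 450,
                              outcome_mean = 3208,
                              seed = 1L) {
  stopifnot(n_dyads >= 2, residual_sd >= 0)
  if (any(exposure_spec$sd <= 0)) {
    stop("all exposure sds must be > 0: ",
         paste(exposure_spec$name[exposure_spec$sd <= 0], collapse = ", "))
  }
  for (blk in c("env", "social", "cross")) {
    rng <- correlation_spec[[blk]]
    if (is.null(rng) || length(rng) != 2 || any(abs(rng) > 1) || rng[1] > rng[2]) {
      stop("correlation_spec block '", blk, "' must be an ordered range in [-1, 1]")
    }
  }
  if (!is.null(corr_matrix)) {
    p <- nrow(exposure_spec)
    stopifnot(is.matrix(corr_matrix), nrow(corr_matrix) == p, ncol(corr_matrix) == p)
  }
  te <- true_effects
  if (length(te) && is.null(names(te))) stop("true_effects must be named")
  structure(
    list(n_dyads = as.integer(n_dyads), exposure_spec = exposure_spec,
         correlation_spec = correlation_spec, corr_matrix = corr_matrix,
         covariate_spec = covariate_spec, true_effects = te,
         residual_sd = residual_sd, outcome_mean = outcome_mean,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("simulation_config: n_dyads =", x$n_dyads,
      "| exposures =", nrow(x$exposure_spec),
      "| planted effects =", length(x$true_effects),
      "| residual_sd =", x$residual_sd, "| seed =", x$seed, "\n")
  invisible(x)
}

# Evaluate code under a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Draw a block-structured exposure correlation matrix from the configured
# ranges and repair it to the nearest positive-definite correlation matrix.
draw_block_correlation <- function(exposure_spec, correlation_spec) {
  p <- nrow(exposure_spec)
  env <- exposure_spec$group == "environmental"
  R <- diag(p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      rng <- if (env[i] && env[j]) correlation_spec$env
             else if (!env[i] && !env[j]) correlation_spec$social
             else correlation_spec$cross
      R[i, j] <- R[j, i] <- stats::runif(1, rng[1], rng[2])
    }
  }
  repair_correlation(R, "block correlation draw")
}

repair_correlation <- function(R, what) {
  ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-8) {
    R <- as.matrix(Matrix::nearPD(R, corr = TRUE, maxit = 200)$mat)
    ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 1e-10) {
      stop("correlation matrix for '", what,
           "' is not positive definite after nearest-PD repair")
    }
  }
  R
}

rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
  }
  x
}

draw_moments <- function(n, spec) {
  if (length(spec) >= 4) rtnorm(n, spec[1], spec[2], spec[3], spec[4])
  else stats::rnorm(n, spec[1], spec[2])
}

#' Simulate a synthetic cohort
#'
#' Draws exposures from a Gaussian copula with the configured marginal
#' means/SDs and block correlation structure, covariates from the configured
#' category frequencies and moments, and the outcome from the sparse linear
#' model `outcome_mean + sum(true_effects * standardized predictors) + noise`.
#' Interaction terms named `"a:b"` contribute their effect times the product
#' of the two standardized exposures. Fully deterministic given the seed.
#'
#' @param config A [simulation_config()].
#' @return A data.frame of class `cohort_table`, one row per dyad, with the
#'   21 exposure columns in native units, covariate columns, conception and
#'   delivery dates, `stratum` (`"nhw"` vs `"other"`), and outcomes
#'   `birth_weight` (g) and `adiposity` (% fat mass). The realized exposure
#'   correlation matrix is attached as attribute `corr_matrix`, the exposure
#'   spec as `exposure_spec`, and the seed as `seed`.
#' @examples
#' cfg <- simulation_config(n_dyads = 100, seed = 7)
#' cohort <- simulate_cohort(cfg)
#' dim(cohort)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    n <- config$n_dyads
    spec <- config$exposure_spec
    p <- nrow(spec)

    R <- if (!is.null(config$corr_matrix)) {
      repair_correlation(config$corr_matrix, "corr_matrix")
    } else {
      draw_block_correlation(spec, config$correlation_spec)
    }
    L <- chol(R)
    zz <- matrix(stats::rnorm(n * p), n, p) %*% L  # standardized latent exposures
    colnames(zz) <- spec$name
    expo <- sweep(sweep(zz, 2, spec$sd, `*`), 2, spec$mean, `+`)

    cs <- config$covariate_spec
    draw_cat <- function(probs) {
      factor(sample(names(probs), n, replace = TRUE, prob = probs),
             levels = names(probs))
    }
    race <- draw_cat(cs$race)
    cohort <- data.frame(
      dyad_id = sprintf("dyad_%04d", seq_len(n)),
      as.data.frame(expo),
      race = race,
      education = draw_cat(cs$education),
      smoking = draw_cat(cs$smoking),
      shs = draw_cat(cs$shs),
      infant_sex = draw_cat(cs$infant_sex),
      maternal_age = draw_moments(n, cs$maternal_age),
      cpss = draw_moments(n, cs$cpss),
      epds = draw_moments(n, cs$epds),
      bmi = draw_moments(n, cs$bmi),
      longitude = draw_moments(n, cs$longitude),
      latitude = draw_moments(n, cs$latitude),
      days_to_peapod = draw_moments(n, cs$days_to_peapod),
      stringsAsFactors = FALSE
    )

    start <- as.Date(paste0(min(cs$conception_years), "-01-01"))
    end <- as.Date(paste0(max(cs$conception_years), "-12-31"))
    conception <- start + floor(stats::runif(n, 0, as.numeric(end - start) + 1))
    gest <- round(draw_moments(n, cs$gestation_days))
    cohort$conception_date <- conception
    cohort$delivery_date <- conception + gest
    month <- as.integer(format(conception, "%m"))
    cohort$season <- factor(
      c("winter", "winter", "spring", "spring", "spring", "summer", "summer",
        "summer", "fall", "fall", "fall", "winter")[month],
      levels = c("winter", "spring", "summer", "fall")
    )
    cohort$conception_year <- factor(format(conception, "%Y"),
                                     levels = as.character(cs$conception_years))
    cohort$stratum <- ifelse(race == "nhw", "nhw", "other")

    # Outcome: linear in the *standardized* exposures (the copula normals),
    # so planted per-SD effects are exact by construction.
    lin <- rep(config$outcome_mean, n)
    for (term in names(config$true_effects)) {
      parts <- strsplit(term, ":", fixed = TRUE)[[1]]
      if (!all(parts %in% spec$name)) {
        stop("true_effects term '", term, "' names unknown exposures")
      }
      pred <- if (length(parts) == 1) {
        zz[, parts]
      } else {
        # centered product: E[z_a z_b] = rho, so outcome_mean stays the mean
        i1 <- match(parts[1], spec$name); i2 <- match(parts[2], spec$name)
        zz[, parts[1]] * zz[, parts[2]] - R[i1, i2]
      }
      lin <- lin + config$true_effects[[term]] * pred
    }
    noise <- if (config$residual_sd > 0) stats::rnorm(n, 0, config$residual_sd) else 0
    cohort$birth_weight <- lin + noise
    cohort$adiposity <- draw_moments(n, cs$adiposity)

    stopifnot(!anyNA(cohort), all(cohort$delivery_date > cohort$conception_date))
    attr(cohort, "corr_matrix") <- R
    attr(cohort, "exposure_spec") <- spec
    attr(cohort, "seed") <- config$seed
    class(cohort) <- c("cohort_table", "data.frame")
    cohort
  })
}

#' Write / read a cohort table as CSV
#'
#' The CSV stores native-unit columns with a one-line `# seed:` metadata
#' header so a written cohort records its provenance.
#'
#' @param cohort A `cohort_table`.
#' @param path File path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns a
#'   `cohort_table` (without the correlation-matrix attribute).
#' @export
write_cohort <- function(cohort, path) {
  con <- file(path, "w")
  on.exit(close(con))
  seed <- attr(cohort, "seed")
  writeLines(paste0("# seed: ", if (is.null(seed)) NA else seed), con)
  utils::write.csv(as.data.frame(cohort), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  first <- readLines(path, n = 1)
  skip <- if (startsWith(first, "#")) 1L else 0L
  df <- utils::read.csv(path, skip = skip, stringsAsFactors = FALSE)
  for (col in c("race", "education", "smoking", "shs", "infant_sex",
                "season", "conception_year")) {
    if (col %in% names(df)) df[[col]] <- factor(df[[col]])
  }
  for (col in c("conception_date", "delivery_date")) {
    if (col %in% names(df)) df[[col]] <- as.Date(df[[col]])
  }
  if (skip) {
    seed <- suppressWarnings(as.integer(sub("# seed: ", "", first, fixed = TRUE)))
    attr(df, "seed") <- seed
  }
  attr(df, "exposure_spec") <- exposure_panel()
  class(df) <- c("cohort_table", "data.frame")
  df
}
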