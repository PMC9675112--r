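# Single-exposure adjusted linear regressions (the comparison models) and
# the stratified-analysis driver shared with the NPB engine.

#' Single-exposure adjusted OLS fit
#'
#' Ordinary least squares of the outcome on one standardized exposure plus
#' the covariate block, via QR factorization. The reported estimate is the
#' exposure coefficient (outcome units per 1 SD), with the usual unbiased
#' residual-variance standard error and a Wald 95% interval using the normal
#' 1.96 quantile.
#'
#' @param exposure Standardized exposure column.
#' @param W Covariate block (including intercept).
#' @param y Outcome vector (native units).
#' @param name Exposure name for the result row.
#' @return One-row data.frame: `exposure`, `estimate`, `se`, `lower`,
#'   `upper`, `n`.
#' @export
fit_single_exposure <- function(exposure, W, y, name = "exposure") {
  A <- cbind(exposure = exposure, W)
  n <- length(y)
  qrA <- qr(A)
  if (qrA$rank < ncol(A)) {
    drop <- colnames(A)[qrA$pivot[seq(qrA$rank + 1, ncol(A))]]
    stop("rank-deficient design for '", name, "': collinear columns ",
         paste(drop, collapse = ", "))
  }
  coefs <- qr.coef(qrA, y)
  res <- y - A %*% coefs
  df <- n - ncol(A)
  s2 <- sum(res^2) / df
  XtX_inv_11 <- chol2inv(qr.R(qrA))[1, 1]
  se <- sqrt(s2 * XtX_inv_11)
  est <- coefs[["exposure"]]
  data.frame(exposure = name, estimate = est, se = se,
             lower = est - 1.96 * se, upper = est + 1.96 * se, n = n,
             stringsAsFactors = FALSE)
}

#' All single-exposure regressions for a cohort
#'
#' One adjusted OLS fit per exposure, sharing the covariate block, in the
#' canonical exposure order. A rank failure in one exposure's fit is recorded
#' in that row (`error` column) without affecting the others.
#'
#' @param cohort A `cohort_table`.
#' @param outcome_choice `"birth_weight"` or `"adiposity"`.
#' @param ... Passed to [encode_covariates()].
#' @return data.frame with one row per exposure (columns as in
#'   [fit_single_exposure()], plus `error`).
#' @export
run_all_single_exposure <- function(cohort,
                                    outcome_choice = c("birth_weight", "adiposity"),
                                    ...) {
  outcome_choice <- match.arg(outcome_choice)
  panel <- attr(cohort, "exposure_spec")
  if (is.null(panel)) panel <- exposure_panel()
  W <- encode_covariates(cohort, outcome_choice, ...)
  y <- cohort[[outcome_choice]]
  rows <- lapply(panel$name, function(nm) {
    st <- standardize(cohort[[nm]], nm)
    out <- tryCatch(
      cbind(fit_single_exposure(st$values, W, y, nm), error = NA_character_),
      error = function(e) data.frame(exposure = nm, estimate = NA_real_,
                                     se = NA_real_, lower = NA_real_,
                                     upper = NA_real_, n = length(y),
                                     error = conditionMessage(e),
                                     stringsAsFactors = FALSE)
    )
    out
  })
  do.call(rbind, rows)
}

#' Stratified analysis driver
#'
#' Splits the cohort by a stratifying covariate, drops that covariate (and
#' its indicator columns) from the adjustment set, and refits the chosen
#' engine in each stratum. Strata below the minimum size are skipped with a
#' warning.
#'
#' @param cohort A `cohort_table`.
#' @param stratifier `"stratum"` (the NHW vs all-other race/ethnicity split),
#'   `"race"`, or `"infant_sex"`.
#' @param engine `"single_exposure"` or `"npb"`.
#' @param outcome_choice Outcome column.
#' @param config An [npb_config()] (npb engine only).
#' @param min_n Minimum stratum size (default 30).
#' @param interactions Interaction structure for the npb engine (see
#'   [build_design()]).
#' @param include_geography Keep longitude/latitude terms in stratified fits
#'   (default TRUE).
#' @return Named list, one element per retained stratum: the engine's result
#'   table (single-exposure data.frame, or a list with `chain` and `summary`
#'   for the npb engine), plus attribute `stratum_n`.
#' @export
stratified_run <- function(cohort, stratifier = "stratum",
                           engine = c("single_exposure", "npb"),
                           outcome_choice = c("birth_weight", "adiposity"),
                           config = npb_config(), min_n = 30L,
                           interactions = "full", include_geography = TRUE) {
  engine <- match.arg(engine)
  outcome_choice <- match.arg(outcome_choice)
  if (!stratifier %in% names(cohort)) stop("unknown stratifier '", stratifier, "'")
  drop_args <- switch(stratifier,
    stratum = , race = list(include_race = FALSE),
    infant_sex = list(include_sex = FALSE),
    stop("stratifier '", stratifier, "' is not a supported covariate")
  )
  labels <- unique(as.character(cohort[[stratifier]]))
  out <- list()
  ns <- integer(0)
  for (lab in labels) {
    sub <- cohort[as.character(cohort[[stratifier]]) == lab, , drop = FALSE]
    if (nrow(sub) < min_n) {
      if (nrow(sub) > 0) {
        warning("stratum '", lab, "' has n = ", nrow(sub), " < ", min_n,
                "; skipped")
      }
      next
    }
    attr(sub, "exposure_spec") <- attr(cohort, "exposure_spec")
    class(sub) <- class(cohort)
    res <- if (engine == "single_exposure") {
      do.call(run_all_single_exposure,
              c(list(sub, outcome_choice, include_geography = include_geography),
                drop_args))
    } else {
      design <- do.call(build_design,
                        c(list(sub, outcome_choice, interactions = interactions,
                               include_geography = include_geography),
                          drop_args))
      chain <- npb_fit(design, config)
      list(chain = chain, summary = summarize_posterior(chain))
    }
    out[[lab]] <- res
    ns[lab] <- nrow(sub)
  }
  attr(out, "stratum_n") <- ns
  out
}
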