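# Design construction: standardization with scale records, reference-coded
# covariate blocks, and full pairwise interaction expansion.

#' Standardize a continuous column
#'
#' Centers and scales by the sample SD (n-1 denominator), recording the
#' center/scale pair so reported per-SD effects can be mapped back to native
#' units.
#'
#' @param column Numeric vector with >= 2 distinct values.
#' @param name Column name used in the scale record (and error messages).
#' @return List: `values` (standardized vector), `record` (data.frame with
#'   `name`, `center`, `scale`).
#' @examples
#' standardize(c(-1, 1))$values  # -1/sqrt(2), +1/sqrt(2)
#' @export
standardize <- function(column, name = "column") {
  stopifnot(is.numeric(column), !anyNA(column))
  s <- stats::sd(column)
  if (!is.finite(s) || s == 0) {
    stop("cannot standardize constant column '", name, "'")
  }
  m <- mean(column)
  list(values = (column - m) / s,
       record = data.frame(name = name, center = m, scale = s,
                           stringsAsFactors = FALSE))
}

#' Invert a standardization
#'
#' @param values Standardized vector.
#' @param record One-row scale record from [standardize()].
#' @return Native-unit vector.
#' @export
unstandardize <- function(values, record) {
  values * record$scale + record$center
}

#' Encode the covariate block
#'
#' Builds the adjustment block W: an intercept; reference-coded indicator
#' columns for race/ethnicity (reference non-Hispanic White), education,
#' smoking, second-hand smoke, infant sex, season of conception, and year of
#' conception; standardized continuous covariates (maternal age, CPSS, EPDS,
#' pre-pregnancy BMI, longitude, latitude); the product of the standardized
#' longitude and latitude columns; and, for the adiposity outcome only, the
#' standardized days from delivery to the body-composition measurement.
#'
#' @param cohort A `cohort_table`.
#' @param outcome_choice `"birth_weight"` or `"adiposity"`.
#' @param include_sex Include infant sex (default TRUE).
#' @param include_geography Include longitude/latitude and their product
#'   (default TRUE; stratified fits may switch this off).
#' @param include_race Include race/ethnicity indicators (default TRUE;
#'   switched off when stratifying on race).
#' @return Numeric matrix W with named columns, plus attributes
#'   `scale_records` (data.frame) and `interaction_eligible` (covariate
#'   columns that interact with exposures: everything except the intercept
#'   and the longitude x latitude product).
#' @export
encode_covariates <- function(cohort,
                              outcome_choice = c("birth_weight", "adiposity"),
                              include_sex = TRUE, include_geography = TRUE,
                              include_race = TRUE) {
  outcome_choice <- match.arg(outcome_choice)
  n <- nrow(cohort)
  cols <- list(intercept = rep(1, n))
  records <- list()

  indicators <- function(f, ref, prefix) {
    f <- stats::relevel(factor(f), ref = ref)
    lv <- levels(f)[-1]
    out <- lapply(lv, function(l) as.numeric(f == l))
    names(out) <- paste0(prefix, "_", lv)
    out
  }
  if (include_race) cols <- c(cols, indicators(cohort$race, "nhw", "race"))
  cols <- c(cols,
            indicators(cohort$education, "less_than_hs", "edu"),
            indicators(cohort$smoking, "no", "smoking"),
            indicators(cohort$shs, "no", "shs"))
  if (include_sex) cols <- c(cols, indicators(cohort$infant_sex, "female", "sex"))
  cols <- c(cols,
            indicators(cohort$season, "winter", "season"),
            indicators(droplevels(factor(cohort$conception_year)),
                       levels(droplevels(factor(cohort$conception_year)))[1],
                       "year"))

  cont <- c("maternal_age", "cpss", "epds", "bmi")
  if (include_geography) cont <- c(cont, "longitude", "latitude")
  if (outcome_choice == "adiposity") cont <- c(cont, "days_to_peapod")
  for (nm in cont) {
    st <- standardize(cohort[[nm]], nm)
    cols[[nm]] <- st$values
    records[[nm]] <- st$record
  }
  if (include_geography) {
    cols[["longitude:latitude"]] <- cols[["longitude"]] * cols[["latitude"]]
  }

  W <- do.call(cbind, cols)
  colnames(W) <- names(cols)
  keep <- colnames(W) == "intercept" | apply(W, 2, function(v) stats::sd(v) > 0)
  if (any(!keep)) W <- W[, keep, drop = FALSE]
  attr(W, "scale_records") <- if (length(records)) do.call(rbind, records) else NULL
  attr(W, "interaction_eligible") <-
    setdiff(colnames(W), c("intercept", "longitude:latitude"))
  W
}

#' Expand pairwise interactions
#'
#' Builds the interaction block Z: the elementwise product of every unordered
#' pair of exposure columns (each pair exactly once, no self-products), then
#' every exposure-by-covariate-column product, in deterministic order (pairs
#' by canonical exposure order, then exposures crossed with covariate columns
#' in W order). Column names are `"a:b"`.
#'
#' @param X Standardized exposure matrix with column names.
#' @param W_int Interaction-eligible covariate columns (matrix, possibly with
#'   0 columns), or NULL.
#' @return Matrix Z with named columns; attribute `pair_count` holds the
#'   number of exposure-pair columns.
#' @export
expand_interactions <- function(X, W_int = NULL) {
  stopifnot(is.matrix(X), !is.null(colnames(X)))
  p <- ncol(X)
  cols <- list()
  if (p >= 2) {
    for (i in seq_len(p - 1)) {
      for (j in (i + 1):p) {
        cols[[paste0(colnames(X)[i], ":", colnames(X)[j])]] <- X[, i] * X[, j]
      }
    }
  }
  n_pairs <- length(cols)
  if (!is.null(W_int) && ncol(W_int) > 0) {
    for (i in seq_len(p)) {
      for (k in seq_len(ncol(W_int))) {
        cols[[paste0(colnames(X)[i], ":", colnames(W_int)[k])]] <-
          X[, i] * W_int[, k]
      }
    }
  }
  Z <- if (length(cols)) do.call(cbind, cols) else
    matrix(numeric(0), nrow = nrow(X), ncol = 0)
  if (length(cols)) colnames(Z) <- names(cols)
  if (anyDuplicated(colnames(Z))) stop("duplicate interaction term names")
  attr(Z, "pair_count") <- n_pairs
  Z
}

#' Build model-ready design matrices from a cohort
#'
#' The full design stage: standardizes each exposure (recording centers and
#' scales), encodes the covariate block, and expands the interaction block
#' (all exposure pairs, plus exposure-by-covariate products when
#' `interactions = "full"`).
#'
#' @param cohort A `cohort_table`.
#' @param outcome_choice `"birth_weight"` or `"adiposity"`.
#' @param interactions `"full"` (exposure pairs + exposure x covariate),
#'   `"pairs"` (exposure pairs only), or `"none"`.
#' @param ... Passed to [encode_covariates()].
#' @return Object of class `design_matrices`: list with `y` (native units),
#'   `X` (n x p standardized exposures), `Z` (interaction block), `W`
#'   (covariate block incl. intercept), `term_names` (list per block),
#'   `scale_records`, `outcome_choice`.
#' @export
build_design <- function(cohort,
                         outcome_choice = c("birth_weight", "adiposity"),
                         interactions = c("full", "pairs", "none"), ...) {
  outcome_choice <- match.arg(outcome_choice)
  interactions <- match.arg(interactions)
  panel <- attr(cohort, "exposure_spec")
  if (is.null(panel)) panel <- exposure_panel()

  stl <- lapply(panel$name, function(nm) standardize(cohort[[nm]], nm))
  X <- do.call(cbind, lapply(stl, `[[`, "values"))
  colnames(X) <- panel$name
  exp_records <- do.call(rbind, lapply(stl, `[[`, "record"))

  W <- encode_covariates(cohort, outcome_choice, ...)
  W_int <- W[, attr(W, "interaction_eligible"), drop = FALSE]
  Z <- switch(interactions,
    full = expand_interactions(X, W_int),
    pairs = expand_interactions(X, NULL),
    none = matrix(numeric(0), nrow = nrow(X), ncol = 0)
  )

  structure(
    list(
      y = cohort[[outcome_choice]],
      X = X, Z = Z, W = W,
      term_names = list(main = colnames(X), interaction = colnames(Z),
                        covariate = colnames(W)),
      scale_records = rbind(exp_records, attr(W, "scale_records")),
      outcome_choice = outcome_choice
    ),
    class = "design_matrices"
  )
}

#' @export
print.design_matrices <- function(x, ...) {
  cat("design_matrices:", length(x$y), "rows |",
      ncol(x$X), "exposures |", ncol(x$Z), "interactions |",
      ncol(x$W), "covariate columns | outcome:", x$outcome_choice, "\n")
  invisible(x)
}

#' Assemble design matrices directly (for small validation problems)
#'
#' @param y Outcome vector.
#' @param X Exposure matrix (named columns).
#' @param Z Interaction matrix (may have 0 columns).
#' @param W Covariate matrix (may be NULL for covariate-free problems).
#' @return A `design_matrices` object.
#' @export
design_matrices <- function(y, X, Z = NULL, W = NULL) {
  n <- length(y)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(Z)) Z <- matrix(numeric(0), nrow = n, ncol = 0)
  if (ncol(Z) > 0 && is.null(colnames(Z))) colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  if (!is.null(W) && is.null(colnames(W))) colnames(W) <- paste0("w", seq_len(ncol(W)))
  structure(
    list(y = y, X = X, Z = Z, W = W,
         term_names = list(main = colnames(X), interaction = colnames(Z),
                           covariate = if (is.null(W)) character(0) else colnames(W)),
         scale_records = NULL, outcome_choice = "custom"),
    class = "design_matrices"
  )
}

#' Write design matrices as a directory of CSVs
#'
#' One CSV per block (`y.csv`, `X.csv`, `Z.csv`, `W.csv`), a term-name
#' manifest (`terms.csv`), and the scale records (`scale_records.csv`).
#'
#' @param design A `design_matrices` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_design <- function(design, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(y = design$y),
                   file.path(dir, "y.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(design$X), file.path(dir, "X.csv"),
                   row.names = FALSE)
  if (ncol(design$Z)) {
    utils::write.csv(as.data.frame(design$Z), file.path(dir, "Z.csv"),
                     row.names = FALSE)
  }
  if (!is.null(design$W)) {
    utils::write.csv(as.data.frame(design$W), file.path(dir, "W.csv"),
                     row.names = FALSE)
  }
  terms <- data.frame(
    term = c(design$term_names$main, design$term_names$interaction,
             design$term_names$covariate),
    block = rep(c("main", "interaction", "covariate"),
                c(length(design$term_names$main),
                  length(design$term_names$interaction),
                  length(design$term_names$covariate)))
  )
  utils::write.csv(terms, file.path(dir, "terms.csv"), row.names = FALSE)
  if (!is.null(design$scale_records)) {
    utils::write.csv(design$scale_records, file.path(dir, "scale_records.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
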