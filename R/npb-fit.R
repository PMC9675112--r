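# Non-parametric Bayes shrinkage: configuration, fitting, posterior
# inclusion probabilities, summaries, the exact enumeration oracle, the
# hyperparameter sensitivity sweep, and convergence diagnostics.

#' Configuration for the NPB Gibbs sampler
#'
#' Priors (per selection block): a zero-spiked Dirichlet process whose base
#' measure is `pi0 * delta_0 + (1 - pi0) * N(0, slab_sd^2)` on the
#' standardized-outcome scale; `Gamma(a1, b1)` / `Gamma(a2, b2)` on the
#' concentration parameters of the main-effect and interaction DPs (updated
#' by the Escobar-West auxiliary-variable step); `Beta(a_pi, b_pi)` on each
#' block's zero mass `pi0`; `N(0, covariate_prior_sd^2)` on covariate
#' coefficients and intercept; inverse-gamma `(a_sigma, b_sigma)` on the
#' error variance. The outcome is centered and scaled internally for sampling
#' (so the defaults are scale-free) and summaries are back-transformed to
#' native units.
#'
#' @param n_iter,n_burn,thin MCMC length, burn-in, thinning.
#' @param a1,b1 Gamma shape/rate for the main-effect DP concentration.
#' @param a2,b2 Gamma shape/rate for the interaction DP concentration.
#' @param slab_sd Prior SD of nonzero atoms (standardized-outcome units).
#' @param a_pi,b_pi Beta prior on the zero mass per block.
#' @param covariate_prior_sd Prior SD for covariate coefficients/intercept.
#' @param a_sigma,b_sigma Inverse-gamma prior on the error variance (on the
#'   standardized-outcome scale, where the marginal outcome variance is 1).
#' @param seed Integer seed.
#' @param mode `"npb"` (clustering DP prior) or `"independent_spike_slab"`
#'   (the cluster-free limit used for oracle validation).
#' @param fixed_sigma2,fixed_pi0 Optional fixed values (NA = sample); used in
#'   validation mode. `fixed_sigma2` is on the scale of the outcome actually
#'   passed to the sampler (see `standardize_outcome`).
#' @param standardize_outcome Center/scale the outcome internally (default
#'   TRUE; switch off for fixed-variance validation problems).
#' @return Object of class `npb_config`.
#' @export
npb_config <- function(n_iter = 25000L, n_burn = 5000L, thin = 4L,
                       a1 = 1, b1 = 1, a2 = 1, b2 = 1,
                       slab_sd = 1, a_pi = 1, b_pi = 1,
                       covariate_prior_sd = 10,
                       a_sigma = 0.5, b_sigma = 0.5,
                       seed = 1L, mode = c("npb", "independent_spike_slab"),
                       fixed_sigma2 = NA_real_, fixed_pi0 = NA_real_,
                       standardize_outcome = TRUE) {
  mode <- match.arg(mode)
  stopifnot(n_iter > n_burn, thin >= 1,
            a1 > 0, b1 > 0, a2 > 0, b2 > 0, slab_sd > 0,
            a_pi > 0, b_pi > 0, covariate_prior_sd > 0,
            a_sigma > 0, b_sigma > 0)
  structure(
    list(n_iter = as.integer(n_iter), n_burn = as.integer(n_burn),
         thin = as.integer(thin), a1 = a1, b1 = b1, a2 = a2, b2 = b2,
         slab_sd = slab_sd, a_pi = a_pi, b_pi = b_pi,
         covariate_prior_sd = covariate_prior_sd,
         a_sigma = a_sigma, b_sigma = b_sigma, seed = as.integer(seed),
         mode = mode, fixed_sigma2 = fixed_sigma2, fixed_pi0 = fixed_pi0,
         standardize_outcome = isTRUE(standardize_outcome)),
    class = "npb_config"
  )
}

#' Fit the NPB model
#'
#' Runs the Gibbs sampler for
#' `y_i ~ N(y0 + x_i' beta + z_i' zeta + w_i' gamma, sigma^2)`
#' with zero-spiked DP priors on `beta` (exposure main effects) and `zeta`
#' (pairwise interactions). Each sweep: (1) Polya-urn cluster assignment per
#' selection coefficient (conjugate, marginalized over the base measure);
#' (2) Normal full-conditional refresh of non-spike cluster atoms; (3) joint
#' Normal update of covariate coefficients and intercept; (4) inverse-gamma
#' update of the error variance; (5) Escobar-West update of both DP
#' concentrations; (6) Beta update of each block's zero mass. Spike-cluster
#' coefficients are exact zeros in every draw.
#'
#' @param design A `design_matrices` object (see [build_design()]).
#' @param config An [npb_config()].
#' @return Object of class `npb_chain` holding the retained draws (native
#'   outcome units), term names, config echo, and seed.
#' @export
npb_fit <- function(design, config = npb_config()) {
  stopifnot(inherits(design, "design_matrices"), inherits(config, "npb_config"))
  n <- length(design$y)
  if (n < 10) stop("need n >= 10 rows")
  nkeep <- (config$n_iter - config$n_burn) %/% config$thin
  if (nkeep < 100) {
    stop("n_iter/n_burn/thin retain only ", nkeep, " draws; need >= 100")
  }
  y <- design$y
  if (config$standardize_outcome) {
    y_center <- mean(y); y_scale <- stats::sd(y)
    if (!is.finite(y_scale) || y_scale == 0) stop("constant outcome")
    ys <- (y - y_center) / y_scale
  } else {
    y_center <- 0; y_scale <- 1
    ys <- y
  }
  W <- design$W
  if (is.null(W)) W <- matrix(numeric(0), nrow = n, ncol = 0)
  Z <- design$Z
  if (is.null(Z)) Z <- matrix(numeric(0), nrow = n, ncol = 0)

  cc <- config
  cc$fixed_sigma2 <- if (is.na(config$fixed_sigma2)) -1 else config$fixed_sigma2
  cc$fixed_pi0 <- if (is.na(config$fixed_pi0)) -1 else config$fixed_pi0

  raw <- with_seed(config$seed,
                   .npb_gibbs(design$X, Z, W, ys, unclass(cc)))

  draws <- list(
    beta = raw$beta * y_scale,
    zeta = raw$zeta * y_scale,
    gamma = raw$gamma * y_scale,
    sigma2 = as.vector(raw$sigma2) * y_scale^2,
    alpha1 = as.vector(raw$alpha1), alpha2 = as.vector(raw$alpha2),
    pi0_main = as.vector(raw$pi0_main),
    pi0_interaction = as.vector(raw$pi0_interaction),
    k_main = as.vector(raw$k_main), k_interaction = as.vector(raw$k_interaction)
  )
  colnames(draws$beta) <- design$term_names$main
  if (ncol(draws$zeta)) colnames(draws$zeta) <- design$term_names$interaction
  if (ncol(draws$gamma)) colnames(draws$gamma) <- design$term_names$covariate
  # the intercept column absorbs the outcome centering
  if ("intercept" %in% colnames(draws$gamma)) {
    draws$gamma[, "intercept"] <- draws$gamma[, "intercept"] + y_center
  }
  structure(
    list(draws = draws, term_names = design$term_names,
         scale_records = design$scale_records, config = config,
         seed = config$seed, n = n, n_retained = nrow(raw$beta),
         outcome_choice = design$outcome_choice),
    class = "npb_chain"
  )
}

#' @export
print.npb_chain <- function(x, ...) {
  cat("npb_chain:", x$n_retained, "retained draws |",
      ncol(x$draws$beta), "main effects |", ncol(x$draws$zeta),
      "interactions | mode:", x$config$mode, "| seed:", x$seed, "\n")
  invisible(x)
}

# Draw matrix for a selection term (main or interaction), by name.
selection_draws <- function(chain, term) {
  if (term %in% colnames(chain$draws$beta)) return(chain$draws$beta[, term])
  if (ncol(chain$draws$zeta) && term %in% colnames(chain$draws$zeta)) {
    return(chain$draws$zeta[, term])
  }
  stop("unknown selection term '", term, "'")
}

#' Posterior inclusion probability of a selection term
#'
#' Fraction of retained draws in which the coefficient is exactly nonzero
#' (spike membership is an exact zero by construction, so no thresholding is
#' involved).
#'
#' @param chain An `npb_chain`.
#' @param term A main-effect or interaction term name.
#' @return Probability in `[0, 1]`.
#' @export
compute_pip <- function(chain, term) {
  mean(selection_draws(chain, term) != 0)
}

#' Posterior summary table
#'
#' Per-term posterior mean and equal-tailed 95% credible interval (empirical
#' 2.5/97.5% quantiles over retained draws, zeros included, so selection-term
#' rows read as model-averaged effects), with the PIP attached for selection
#' terms and the native SD used for per-SD scaling where a scale record
#' exists.
#'
#' @param chain An `npb_chain` with >= 100 retained draws.
#' @return data.frame of class `posterior_summary` with columns `term`,
#'   `block`, `mean`, `lower`, `upper`, `pip`, `sd_native`, `units`.
#' @export
summarize_posterior <- function(chain) {
  stopifnot(inherits(chain, "npb_chain"), chain$n_retained >= 100)
  unit_out <- if (identical(chain$outcome_choice, "adiposity")) "% fat mass" else "g"
  one_block <- function(mat, block) {
    if (!ncol(mat)) return(NULL)
    data.frame(
      term = colnames(mat), block = block,
      mean = colMeans(mat),
      lower = apply(mat, 2, stats::quantile, 0.025),
      upper = apply(mat, 2, stats::quantile, 0.975),
      pip = if (block %in% c("main", "interaction")) {
        colMeans(mat != 0)
      } else NA_real_,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  out <- rbind(one_block(chain$draws$beta, "main"),
               one_block(chain$draws$zeta, "interaction"),
               one_block(chain$draws$gamma, "covariate"))
  sr <- chain$scale_records
  out$sd_native <- if (!is.null(sr)) sr$scale[match(out$term, sr$name)] else NA_real_
  out$units <- ifelse(out$block == "main", paste(unit_out, "per 1 SD"),
                      ifelse(out$block == "interaction",
                             paste(unit_out, "per SD.SD"), unit_out))
  class(out) <- c("posterior_summary", "data.frame")
  out
}

#' Exact spike-and-slab PIPs by pattern enumeration
#'
#' Independent validation oracle for the cluster-free limit of the NPB prior:
#' with fixed error variance, zero mass, and slab SD, enumerates every
#' zero/nonzero pattern of the selection coefficients. A pattern's weight is
#' `pi0^(#zeros) * (1-pi0)^(#nonzeros)` times the closed-form Gaussian
#' marginal likelihood `N(y; 0, sigma2 I + tau^2 C_S C_S')` with the nonzero
#' coefficients integrated against `N(0, tau^2)`. The PIP of term j is the
#' normalized weight of patterns in which j is nonzero.
#'
#' @param design A `design_matrices` with at most 12 selection columns and no
#'   covariate block (covariates must be absorbed or absent).
#' @param sigma2 Fixed error variance.
#' @param pi0 Fixed zero mass.
#' @param tau Fixed slab SD.
#' @return Named vector of exact PIPs for every selection term.
#' @export
exact_spike_slab_pip <- function(design, sigma2, pi0, tau) {
  C <- cbind(design$X, design$Z)
  m <- ncol(C)
  if (m > 12) stop("enumeration bound exceeded: ", m, " selection terms > 12")
  if (!is.null(design$W) && ncol(design$W) > 0) {
    stop("covariates must be absorbed or absent for exact enumeration")
  }
  y <- design$y
  n <- length(y)
  logw <- numeric(2^m)
  nz_mask <- matrix(FALSE, 2^m, m)
  for (k in 0:(2^m - 1)) {
    nz <- as.logical(bitwAnd(k, 2^(0:(m - 1))))
    nz_mask[k + 1, ] <- nz
    Sig <- diag(sigma2, n)
    if (any(nz)) {
      Cs <- C[, nz, drop = FALSE]
      Sig <- Sig + tau^2 * tcrossprod(Cs)
    }
    ch <- chol(Sig)
    logdet <- 2 * sum(log(diag(ch)))
    quad <- sum(backsolve(ch, y, transpose = TRUE)^2)
    loglik <- -0.5 * (n * log(2 * pi) + logdet + quad)
    logw[k + 1] <- sum(nz) * log(1 - pi0) + (m - sum(nz)) * log(pi0) + loglik
  }
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  pips <- colSums(w * nz_mask)
  names(pips) <- c(design$term_names$main, design$term_names$interaction)
  pips
}

#' Hyperparameter sensitivity sweep
#'
#' Refits the model once per grid value `g`, setting the Gamma shape and rate
#' of both DP concentration priors to `a = b = g`, and compares the selected
#' sets (terms with PIP > `threshold`) across settings via a Jaccard
#' agreement matrix (Jaccard of two empty sets is defined as 1).
#'
#' @param design A `design_matrices`.
#' @param base_config An [npb_config()]; all non-concentration settings are
#'   inherited.
#' @param grid Numeric grid of Gamma shape/rate values (default
#'   `c(0.5, 1, 2, 4)`).
#' @param threshold PIP selection threshold (default 0.5, strict).
#' @return List: `selected` (named list of selected term sets), `agreement`
#'   (Jaccard matrix), `pips` (matrix of PIPs, terms x settings).
#' @export
sensitivity_sweep <- function(design, base_config = npb_config(),
                              grid = c(0.5, 1, 2, 4), threshold = 0.5) {
  stopifnot(length(grid) >= 1)
  runs <- lapply(grid, function(g) {
    cfg <- base_config
    cfg$a1 <- cfg$b1 <- cfg$a2 <- cfg$b2 <- g
    npb_fit(design, cfg)
  })
  labels <- paste0("a=b=", grid)
  pip_of <- function(chain) {
    c(colMeans(chain$draws$beta != 0),
      if (ncol(chain$draws$zeta)) colMeans(chain$draws$zeta != 0))
  }
  pips <- vapply(runs, pip_of, numeric(ncol(design$X) + ncol(design$Z)))
  colnames(pips) <- labels
  selected <- lapply(seq_along(grid), function(i) {
    names(which(pips[, i] > threshold))
  })
  names(selected) <- labels
  k <- length(grid)
  agreement <- matrix(1, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      u <- union(selected[[i]], selected[[j]])
      agreement[i, j] <- if (!length(u)) 1 else
        length(intersect(selected[[i]], selected[[j]])) / length(u)
    }
  }
  list(selected = selected, agreement = agreement, pips = pips)
}

# Effective sample size via Geyer's initial positive sequence estimator.
ess_scalar <- function(x) {
  n <- length(x)
  if (stats::sd(x) == 0) return(1)
  ac <- stats::acf(x, lag.max = min(n - 1, 500), plot = FALSE)$acf[-1]
  # sum adjacent pairs; truncate at the first nonpositive pair sum
  s <- 0
  k <- 1
  while (k <= length(ac)) {
    pair <- ac[k] + if (k + 1 <= length(ac)) ac[k + 1] else 0
    if (pair <= 0) break
    s <- s + pair
    k <- k + 2
  }
  max(1, min(n, n / (1 + 2 * s)))
}

# Split-chain potential scale reduction factor (rank-free classic form).
psrf_scalar <- function(chains) {
  chains <- lapply(chains, function(x) {
    h <- length(x) %/% 2
    list(x[seq_len(h)], x[h + seq_len(h)])
  })
  chains <- unlist(chains, recursive = FALSE)
  m <- length(chains)
  n <- length(chains[[1]])
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Convergence diagnostics for an NPB chain
#'
#' Effective sample size per monitored scalar, and split-chain potential
#' scale reduction when two or more chains are supplied. Monitored scalars:
#' the error variance, both DP concentrations, and each requested selection
#' term (default: all main effects).
#'
#' @param chain An `npb_chain` (>= 100 retained draws).
#' @param more_chains Optional list of additional `npb_chain`s from other
#'   seeds.
#' @param terms Selection terms to monitor (default main effects).
#' @param ess_warn Flag scalars with ESS below this fraction of the retained
#'   draw count (default 0.1).
#' @return data.frame with `scalar`, `ess`, `psrf` (NA with a single chain),
#'   `flagged`.
#' @export
convergence_report <- function(chain, more_chains = NULL, terms = NULL,
                               ess_warn = 0.1) {
  stopifnot(chain$n_retained >= 100)
  if (is.null(terms)) terms <- colnames(chain$draws$beta)
  pull <- function(ch, scalar) {
    switch(scalar,
           sigma2 = ch$draws$sigma2,
           alpha1 = ch$draws$alpha1,
           alpha2 = ch$draws$alpha2,
           selection_draws(ch, scalar))
  }
  scalars <- c("sigma2", "alpha1", "alpha2", terms)
  all_chains <- c(list(chain), if (is.null(more_chains)) list() else more_chains)
  rows <- lapply(scalars, function(sc) {
    series <- lapply(all_chains, pull, scalar = sc)
    data.frame(
      scalar = sc,
      ess = ess_scalar(series[[1]]),
      psrf = if (length(series) >= 2) psrf_scalar(series) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$flagged <- out$ess < ess_warn * chain$n_retained |
    (!is.na(out$psrf) & out$psrf > 1.1)
  out
}

#' Persist a chain as plain-text CSVs with a JSON metadata sidecar
#'
#' @param chain An `npb_chain`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_chain <- function(chain, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(chain$draws$beta),
                   file.path(dir, "beta.csv"), row.names = FALSE)
  if (ncol(chain$draws$zeta)) {
    utils::write.csv(as.data.frame(chain$draws$zeta),
                     file.path(dir, "zeta.csv"), row.names = FALSE)
  }
  if (ncol(chain$draws$gamma)) {
    utils::write.csv(as.data.frame(chain$draws$gamma),
                     file.path(dir, "gamma.csv"), row.names = FALSE)
  }
  scal <- data.frame(sigma2 = chain$draws$sigma2, alpha1 = chain$draws$alpha1,
                     alpha2 = chain$draws$alpha2,
                     pi0_main = chain$draws$pi0_main,
                     pi0_interaction = chain$draws$pi0_interaction,
                     k_main = chain$draws$k_main,
                     k_interaction = chain$draws$k_interaction)
  utils::write.csv(scal, file.path(dir, "scalars.csv"), row.names = FALSE)
  meta <- list(seed = chain$seed, n = chain$n, n_retained = chain$n_retained,
               outcome_choice = chain$outcome_choice,
               config = unclass(chain$config), term_names = chain$term_names)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
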