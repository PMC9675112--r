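# Shared fixtures: small cohorts, tiny validation designs, and a hand-built
# chain object for summary/diagnostic unit tests.

small_cohort <- function(n = 120, seed = 11, effects = NULL) {
  cfg <- simulation_config(n_dyads = n, seed = seed,
                           true_effects = if (is.null(effects)) {
                             stats::setNames(numeric(0), character(0))
                           } else effects)
  simulate_cohort(cfg)
}

# A covariate-free selection problem small enough for exact enumeration.
tiny_design <- function(n = 30, seed = 42, rho = 0.6,
                        beta = c(0.9, 0), inter = 0.5, sigma = 1) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * 2), n, 2)
  X[, 2] <- rho * X[, 1] + sqrt(1 - rho^2) * X[, 2]
  colnames(X) <- c("x1", "x2")
  Z <- matrix(X[, 1] * X[, 2], n, 1)
  colnames(Z) <- "x1:x2"
  y <- as.vector(X %*% beta + inter * Z[, 1] + stats::rnorm(n, 0, sigma))
  design_matrices(y, X, Z, W = NULL)
}

# Minimal npb_chain with injected draws, for testing summaries/diagnostics
# independently of the sampler.
fake_chain <- function(beta, zeta = NULL, sigma2 = NULL) {
  nk <- nrow(beta)
  if (is.null(zeta)) zeta <- matrix(numeric(0), nk, 0)
  if (is.null(sigma2)) sigma2 <- rep(1, nk)
  structure(list(
    draws = list(beta = beta, zeta = zeta,
                 gamma = matrix(numeric(0), nk, 0),
                 sigma2 = sigma2,
                 alpha1 = rep(1, nk), alpha2 = rep(1, nk),
                 pi0_main = rep(0.5, nk), pi0_interaction = rep(0.5, nk),
                 k_main = rep(1L, nk), k_interaction = rep(1L, nk)),
    term_names = list(main = colnames(beta), interaction = colnames(zeta),
                      covariate = character(0)),
    scale_records = NULL, config = npb_config(seed = 1), seed = 1L,
    n = 100L, n_retained = nk, outcome_choice = "birth_weight"),
    class = "npb_chain")
}

monitor_snapshot <- function(x, y, v) {
  data.frame(x_km = x, y_km = y, value = v)
}
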