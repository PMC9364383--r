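#' Log Cox partial likelihood
#'
#' Computed in log space: for each event, the linear predictor minus a
#' log-sum-exp over the risk set.
#'
#' @param data a [survival_dataset()].
#' @param beta numeric coefficient vector of length `p`.
#' @param risk optional [build_risk_sets()] result (recomputed otherwise).
#' @return The log partial likelihood (scalar).
#' @export
cox_log_plik <- function(data, beta, risk = NULL) {
  stopifnot(inherits(data, "survival_dataset"), length(beta) == ncol(data$X))
  risk <- risk %||% build_risk_sets(data)
  eta <- drop(data$X %*% beta)
  terms <- mapply(function(i, members) eta[i] - logsumexp_(eta[members]),
                  risk$event_order, risk$risk_members)
  sum(terms)
}

#' Log of the Normal-slab moment generating term
#'
#' `log M(x; mu, sigma) = mu * x + sigma^2 * x^2 / 2`, the log moment
#' generating function of `N(mu, sigma^2)` evaluated at `x`. Kept in log
#' form throughout the package since the exponent can be far beyond
#' floating-point range for expression-scale covariates.
#'
#' @param x,mu numeric (vectorized).
#' @param sigma positive numeric.
#' @return `mu * x + sigma^2 * x^2 / 2`.
#' @export
log_mgf_term <- function(x, mu, sigma) {
  stopifnot(all(sigma > 0))
  mu * x + 0.5 * sigma^2 * x^2
}

#' Laplace-slab expectation term
#'
#' `lam * E|beta|` for `beta ~ N(mu, sigma^2)` (folded-normal mean), the
#' contribution of the Laplace slab prior to the coordinate objectives:
#' `lam * (sigma * sqrt(2/pi) * exp(-mu^2 / (2 sigma^2)) +
#'  mu * (1 - 2 * pnorm(-mu / sigma)))`.
#' Always at least `lam * |mu|`, with equality only as `sigma -> 0`.
#'
#' @param mu numeric (vectorized).
#' @param sigma,lam positive numeric.
#' @return Numeric of the same length as `mu`.
#' @export
laplace_slab_expectation <- function(mu, sigma, lam) {
  stopifnot(all(sigma > 0), all(lam > 0))
  lam * (sigma * sqrt(2 / pi) * exp(-mu^2 / (2 * sigma^2)) +
           mu * (1 - 2 * pnorm(-mu / sigma)))
}

#' Per-coefficient log factors of the variational MGF product
#'
#' For each subject r and coefficient k, the factor
#' `gamma_k M(x_rk; mu_k, sigma_k) + (1 - gamma_k)` is the MGF of the
#' variational spike-and-slab marginal at `x_rk`. The cache stores the
#' factors and their per-subject row sums in log space; excluding one
#' coordinate from the row sum gives `log P_j`, the product over `k != j`.
#'
#' @param X numeric covariate matrix (n x p).
#' @param mu,sigma,gamma variational parameter vectors of length p.
#' @return List with `log_factor` (n x p) and `log_row_product` (length n).
#' @export
log_factor_cache <- function(X, mu, sigma, gamma) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == length(mu), length(mu) == length(sigma),
            length(mu) == length(gamma))
  g <- pmin(pmax(gamma, 1e-12), 1 - 1e-12)
  lm <- sweep(X, 2, mu, "*") + 0.5 * sweep(X^2, 2, sigma^2, "*")
  a <- sweep(lm, 2, log(g), "+")
  b <- matrix(log1p(-g), nrow(X), ncol(X), byrow = TRUE)
  m <- pmax(a, b)
  lf <- m + log(exp(a - m) + exp(b - m))
  list(log_factor = lf, log_row_product = rowSums(lf))
}

#' Log excluded product for one subject and coordinate
#'
#' `log P_j(x_r)`: the cached row log-product minus the subject's j-th log
#' factor. The cache is checked for internal consistency before use.
#'
#' @param cache a [log_factor_cache()].
#' @param subject row index.
#' @param j coordinate to exclude.
#' @return Scalar `log P_j`.
#' @export
log_excluded_product <- function(cache, subject, j) {
  rows <- rowSums(cache$log_factor)
  if (max(abs(rows - cache$log_row_product)) > 1e-8)
    stop("internal error: stale log-factor cache (row products inconsistent)")
  cache$log_row_product[subject] - cache$log_factor[subject, j]
}

# internal: log partial likelihood for many coefficient draws at once.
# prep is svb_prepare() output; B is p x n_draws.
log_plik_draws <- function(prep, B) {
  eta <- prep$X %*% B                       # n x D, sorted subject order
  m <- apply(eta, 2, max)
  E <- exp(sweep(eta, 2, m))
  S <- apply(E, 2, function(col) rev(cumsum(rev(col))))
  lse <- sweep(log(S), 2, m, "+")
  colSums(eta[prep$ev + 1L, , drop = FALSE]) -
    colSums(lse[prep$rs + 1L, , drop = FALSE])
}

#' Monte-Carlo expected log partial likelihood under the variational posterior
#'
#' Averages the log partial likelihood over coefficient draws from the fitted
#' spike-and-slab variational distribution.
#'
#' @param data a [survival_dataset()].
#' @param params list/fit with `mu`, `sigma`, `gamma` (e.g. an [svb_fit()]).
#' @param n_draws number of Monte-Carlo draws.
#' @param seed optional integer seed (the global RNG state is restored).
#' @return List with `value` (the MC mean) and `se` (its standard error).
#' @export
expected_log_plik <- function(data, params, n_draws = 1e4, seed = NULL) {
  stopifnot(n_draws >= 1)
  prep <- svb_prepare(data)
  B <- svb_sample_params(params$mu, params$sigma, params$gamma, n_draws, seed)
  v <- log_plik_draws(prep, B)
  list(value = mean(v), se = if (n_draws > 1) sd(v) / sqrt(n_draws) else 0)
}

# internal: draw coefficient vectors from a spike-and-slab variational
# distribution; returns p x n_draws
svb_sample_params <- function(mu, sigma, gamma, n_draws, seed = NULL) {
  p <- length(mu)
  with_seed_(seed, {
    z <- matrix(runif(p * n_draws), p, n_draws) < gamma
    slab <- matrix(rnorm(p * n_draws, mean = mu, sd = sigma), p, n_draws)
    slab * z
  })
}
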