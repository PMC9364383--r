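#' Posterior mean coefficients
#'
#' Under the spike-and-slab variational posterior the posterior mean of each
#' coefficient is `gamma_j * mu_j`.
#'
#' @param params list/fit with `mu` and `gamma`.
#' @return Numeric vector of posterior means.
#' @export
posterior_mean <- function(params) {
  out <- params$gamma * params$mu
  names(out) <- params$feature_names
  out
}

#' Select coefficients by posterior inclusion probability
#'
#' @param params list/fit with `gamma`.
#' @param threshold inclusion threshold; selection is `gamma_j >= threshold`
#'   (inclusive).
#' @return Integer vector of selected coordinate indices.
#' @export
select_at_half <- function(params, threshold = 0.5) {
  which(params$gamma >= threshold)
}

# internal: three-case credible set for a single coordinate
credible_set_one <- function(g, mu, sigma, level) {
  if (g > level) {
    m <- level / g
    z <- qnorm((1 + m) / 2)
    list(kind = "interval", lower = mu - z * sigma, upper = mu + z * sigma,
         level = level, size = 2 * z * sigma)
  } else if (g < 1 - level) {
    list(kind = "spike_only", lower = NA_real_, upper = NA_real_,
         level = level, size = 0)
  } else {
    m <- (level - (1 - g)) / g    # slab mass needed once the spike counts
    z <- qnorm((1 + m) / 2)
    list(kind = "interval_plus_spike", lower = mu - z * sigma,
         upper = mu + z * sigma, level = level, size = 2 * z * sigma)
  }
}

#' Marginal credible set for one coefficient
#'
#' Three-case rule at credibility `level`: the set is an interval of the
#' Normal slab when the inclusion probability exceeds `level`, the spike
#' `{0}` alone when it is below `1 - level`, and the union of both
#' otherwise. The interval is symmetric about `mu_j` and sized so that the
#' total variational mass of the set (slab mass times `gamma_j`, plus
#' `1 - gamma_j` when the spike belongs to the set) reaches `level`.
#'
#' @param params list/fit with `mu`, `sigma`, `gamma`.
#' @param j coordinate index.
#' @param level target credibility in (0, 1).
#' @return A list of class `credible_set` with `kind`
#'   (`"interval"`, `"spike_only"` or `"interval_plus_spike"`), `lower`,
#'   `upper`, `level` and `size` (Lebesgue measure).
#' @export
credible_set <- function(params, j, level = 0.95) {
  stopifnot(level > 0, level < 1)
  out <- credible_set_one(params$gamma[j], params$mu[j], params$sigma[j], level)
  structure(out, class = "credible_set")
}

#' Marginal credible sets for all coefficients
#'
#' @inheritParams credible_set
#' @return A data frame with one row per coefficient: `kind`, `lower`,
#'   `upper`, `size`.
#' @export
credible_sets <- function(params, level = 0.95) {
  stopifnot(level > 0, level < 1)
  rows <- lapply(seq_along(params$gamma), function(j)
    credible_set_one(params$gamma[j], params$mu[j], params$sigma[j], level))
  data.frame(kind = vapply(rows, `[[`, "", "kind"),
             lower = vapply(rows, `[[`, 0, "lower"),
             upper = vapply(rows, `[[`, 0, "upper"),
             size = vapply(rows, `[[`, 0, "size"))
}

# internal: does a three-case set contain `value`?
set_contains_ <- function(kind, lower, upper, value) {
  has_spike <- kind %in% c("spike_only", "interval_plus_spike")
  has_int <- kind %in% c("interval", "interval_plus_spike")
  (has_spike & value == 0) |
    (has_int & !is.na(lower) & lower <= value & value <= upper)
}

#' Empirical coverage and size of credible sets against a known truth
#'
#' @param sets a [credible_sets()] data frame.
#' @param beta0 the true coefficient vector.
#' @return List with coverage and mean Lebesgue size, split by zero and
#'   nonzero entries of `beta0` (`NaN` when a group is empty).
#' @export
coverage_and_size <- function(sets, beta0) {
  stopifnot(nrow(sets) == length(beta0))
  covered <- set_contains_(sets$kind, sets$lower, sets$upper, beta0)
  nz <- beta0 != 0
  list(coverage_nonzero = mean(covered[nz]),
       size_nonzero = mean(sets$size[nz]),
       coverage_zero = mean(covered[!nz]),
       size_zero = mean(sets$size[!nz]))
}

#' Bayesian false discovery rate selection threshold
#'
#' Scans the distinct inclusion probabilities as candidate thresholds `k`
#' and returns the smallest one whose selected set `{j : gamma_j > k}` has
#' Bayesian FDR `sum((1 - gamma_j) 1{gamma_j > k}) / sum(1{gamma_j > k})`
#' below `alpha` — i.e. the largest admissible selected set.
#'
#' @param gamma inclusion probability vector in `[0, 1]`.
#' @param alpha target Bayesian FDR level in (0, 1).
#' @return List of class `selection_report`: `selected` (indices),
#'   `threshold_used`, `inclusion_probs`, `bayes_fdr_at_threshold`, and
#'   `empty` flag when no threshold qualifies.
#' @export
bayesian_fdr_threshold <- function(gamma, alpha = 0.1) {
  stopifnot(alpha > 0, alpha < 1, all(gamma >= 0), all(gamma <= 1))
  ks <- sort(unique(c(0, gamma)))   # k = 0 admits the full selection
  best <- NULL
  for (k in ks) {
    sel <- gamma > k
    if (!any(sel)) next
    fdr <- sum(1 - gamma[sel]) / sum(sel)
    if (fdr < alpha) { best <- list(k = k, fdr = fdr); break }  # smallest admissible k
  }
  if (is.null(best)) {
    return(structure(list(selected = integer(0), threshold_used = 1,
                          inclusion_probs = gamma,
                          bayes_fdr_at_threshold = NA_real_, empty = TRUE),
                     class = "selection_report"))
  }
  structure(list(selected = which(gamma > best$k), threshold_used = best$k,
                 inclusion_probs = gamma,
                 bayes_fdr_at_threshold = best$fdr, empty = FALSE),
            class = "selection_report")
}

#' Monte-Carlo evidence lower bound
#'
#' `ELBO = E_Q[log L_p] - KL(Q || prior)`. The expected log partial
#' likelihood is estimated by Monte Carlo ([expected_log_plik()]); the KL
#' term is closed form: per coordinate, a Bernoulli KL between `gamma_j`
#' and the marginal prior inclusion `a0 / (a0 + b0)` (exact here, since the
#' Beta hyperpriors are independent across coordinates) plus
#' `gamma_j * KL(N(mu_j, sigma_j^2) || Laplace(lam))`.
#'
#' @param data a [survival_dataset()].
#' @param params list/fit with `mu`, `sigma`, `gamma`.
#' @param prior an [svb_prior()] with `b0` set.
#' @param n_draws Monte-Carlo draws for the likelihood term.
#' @param seed optional integer seed.
#' @return List with `elbo`, `ell`, `ell_se` and `kl`.
#' @export
elbo_mc <- function(data, params, prior, n_draws = 1e4, seed = NULL) {
  ell <- expected_log_plik(data, params, n_draws = n_draws, seed = seed)
  kl <- kl_variational_prior(params, prior)
  list(elbo = ell$value - kl, ell = ell$value, ell_se = ell$se, kl = kl)
}

#' Kullback-Leibler divergence between the variational posterior and prior
#'
#' @inheritParams elbo_mc
#' @return Scalar KL (nonnegative).
#' @export
kl_variational_prior <- function(params, prior) {
  stopifnot(!is.null(prior$b0))
  g <- pmin(pmax(params$gamma, 1e-12), 1 - 1e-12)
  wbar <- prior$a0 / (prior$a0 + prior$b0)
  kl_bern <- g * log(g / wbar) + (1 - g) * log((1 - g) / (1 - wbar))
  # KL(N(mu, s^2) || Laplace(lam)) = -log(sqrt(2 pi) s) - 1/2 - log(lam/2) + lam E|beta|
  kl_slab <- -log(sqrt(2 * pi) * params$sigma) - 0.5 - log(prior$lam / 2) +
    laplace_slab_expectation(params$mu, params$sigma, prior$lam)
  sum(kl_bern + g * kl_slab)
}

#' Prognostic index (linear predictor)
#'
#' @param data a [survival_dataset()].
#' @param beta_hat coefficient vector (e.g. [posterior_mean()]).
#' @return Per-subject linear predictors `beta_hat' x_i`.
#' @export
prognostic_index <- function(data, beta_hat) {
  stopifnot(inherits(data, "survival_dataset"),
            length(beta_hat) == ncol(data$X))
  drop(data$X %*% beta_hat)
}

#' Harrell's concordance index
#'
#' Among usable pairs (the shorter observed time belongs to an event), the
#' fraction in which the higher prognostic index has the shorter time, with
#' ties in the index counting 1/2.
#'
#' @param time,status observed times and event indicators.
#' @param eta prognostic indices (higher = more at risk).
#' @return Scalar in `[0, 1]`; `NA` with a warning when no pair is usable.
#' @export
concordance_index <- function(time, status, eta) {
  n <- length(time)
  stopifnot(length(status) == n, length(eta) == n)
  shorter <- outer(time, time, "<")                 # t_i < t_j
  usable <- shorter & (status == 1)                 # event at the shorter time
  if (!any(usable)) {
    warning("no usable pairs: concordance undefined")
    return(NA_real_)
  }
  higher <- outer(eta, eta, ">")
  tied <- outer(eta, eta, "==")
  (sum(higher & usable) + 0.5 * sum(tied & usable)) / sum(usable)
}

#' Posterior probability that one subject is at greater risk than another
#'
#' Monte-Carlo estimate of `Q(beta' x_i >= beta' x_j)` under the fitted
#' variational posterior.
#'
#' @param params list/fit with `mu`, `sigma`, `gamma`.
#' @param x_i,x_j covariate vectors of the two subjects.
#' @param n_draws Monte-Carlo draws.
#' @param seed optional integer seed.
#' @return Scalar probability.
#' @export
risk_comparison_prob <- function(params, x_i, x_j, n_draws = 1e4, seed = NULL) {
  stopifnot(n_draws >= 1, length(x_i) == length(params$mu),
            length(x_j) == length(params$mu))
  B <- svb_sample_params(params$mu, params$sigma, params$gamma, n_draws, seed)
  mean(drop(crossprod(B, x_i - x_j)) >= 0)
}

#' Pairwise risk-comparison matrix
#'
#' Entry (i, j) is the posterior probability that subject `i` is at greater
#' risk than subject `j`, computed from a common set of posterior draws.
#'
#' @param params list/fit with `mu`, `sigma`, `gamma`.
#' @param X covariate matrix (one row per subject to compare).
#' @param n_draws Monte-Carlo draws.
#' @param seed optional integer seed.
#' @return A square matrix of probabilities.
#' @export
risk_comparison_matrix <- function(params, X, n_draws = 1e4, seed = NULL) {
  X <- as.matrix(X)
  B <- svb_sample_params(params$mu, params$sigma, params$gamma, n_draws, seed)
  eta <- X %*% B                                    # m x n_draws
  m <- nrow(X)
  out <- matrix(0, m, m, dimnames = list(rownames(X), rownames(X)))
  for (i in seq_len(m)) out[i, ] <- colMeans(t(eta) <= eta[i, ])
  out
}

#' Write a pairwise risk-comparison matrix as TSV
#'
#' @param M a matrix from [risk_comparison_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_risk_matrix <- function(M, path) {
  write.table(M, path, sep = "\t", quote = FALSE,
              row.names = !is.null(rownames(M)),
              col.names = if (is.null(colnames(M))) FALSE else NA)
  invisible(path)
}

#' Write a selection report as TSV
#'
#' One row per feature: inclusion probability, posterior mean, credible-set
#' kind and bounds.
#'
#' @param fit an [svb_fit()].
#' @param path output path.
#' @param level credible level.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(fit, path, level = 0.95) {
  cs <- credible_sets(fit, level)
  df <- data.frame(feature = fit$feature_names %||% seq_along(fit$gamma),
                   gamma = fit$gamma, beta_hat = fit$gamma * fit$mu,
                   kind = cs$kind, lower = cs$lower, upper = cs$upper,
                   size = cs$size)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
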