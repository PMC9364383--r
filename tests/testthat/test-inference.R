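test_that("posterior mean and threshold selection follow their definitions", {
  pars <- list(mu = c(1.3, 2.0, -0.4), gamma = c(1, 0.5, 0))
  expect_equal(unname(posterior_mean(pars)), c(1.3, 1.0, 0))
  expect_equal(select_at_half(list(gamma = c(0.6, 0.4, 0.5))), c(1L, 3L))
  expect_equal(select_at_half(list(gamma = c(0.1, 0.49))), integer(0))
  expect_equal(select_at_half(list(gamma = c(0.5, 0.5))), c(1L, 2L))
})

test_that("credible sets implement the three-case mass rule", {
  # low inclusion: spike only
  s <- credible_set(list(gamma = 0.02, mu = 1, sigma = 0.5), 1)
  expect_equal(s$kind, "spike_only")
  expect_equal(s$size, 0)
  # high inclusion: pure interval, z solves gamma * (2 Phi(z) - 1) = level
  g <- 0.99; sig <- 0.1
  s2 <- credible_set(list(gamma = g, mu = 1, sigma = sig), 1)
  z <- uniroot(function(z) g * (2 * pnorm(z) - 1) - 0.95, c(1, 5),
               tol = 1e-12)$root
  expect_equal(s2$kind, "interval")
  expect_equal(s2$size, 2 * z * sig, tolerance = 1e-8)
  expect_equal(c(s2$lower, s2$upper), c(1 - z * sig, 1 + z * sig),
               tolerance = 1e-8)
  # middle case: spike contributes 1 - gamma, slab needs mass 0.9
  s3 <- credible_set(list(gamma = 0.5, mu = 0, sigma = 1), 1)
  expect_equal(s3$kind, "interval_plus_spike")
  expect_equal(s3$upper, qnorm(0.95), tolerance = 1e-10)
  expect_equal(s3$size, 2 * qnorm(0.95), tolerance = 1e-10)
})

test_that("credible sets always hold at least the target variational mass", {
  # numeric integration of the slab density, independent of the quantile math
  set.seed(202)
  for (k in 1:200) {
    g <- runif(1); mu <- rnorm(1); sig <- runif(1, 0.01, 2)
    lev <- sample(c(0.8, 0.9, 0.95, 0.99), 1)
    s <- credible_set(list(gamma = g, mu = mu, sigma = sig), 1, level = lev)
    mass <- 0
    if (s$kind %in% c("spike_only", "interval_plus_spike")) mass <- 1 - g
    if (s$kind %in% c("interval", "interval_plus_spike")) {
      slab <- integrate(dnorm, s$lower, s$upper, mean = mu, sd = sig,
                        rel.tol = 1e-10)$value
      mass <- mass + g * slab
    }
    expect_gte(mass, lev - 1e-6)
    if (s$kind != "spike_only") {
      expect_true(s$lower <= mu && mu <= s$upper)
    }
  }
})

test_that("coverage and size are split by the true support", {
  sets <- data.frame(kind = c("spike_only", "interval", "interval_plus_spike"),
                     lower = c(NA, 0.8, -0.1), upper = c(NA, 1.2, 0.1),
                     size = c(0, 0.4, 0.2))
  truth <- c(0, 1.0, 0.5)
  out <- coverage_and_size(sets, truth)
  expect_equal(out$coverage_zero, 1)       # {0} covers the zero coefficient
  expect_equal(out$size_zero, 0)
  expect_equal(out$coverage_nonzero, 0.5)  # 1.0 in [0.8,1.2]; 0.5 not in set 3
  expect_equal(out$size_nonzero, 0.3)
})

test_that("Bayesian FDR threshold picks the largest admissible selected set", {
  r <- bayesian_fdr_threshold(c(0.99, 0.98, 0.6, 0.1), alpha = 0.1)
  expect_equal(r$selected, c(1L, 2L))
  expect_equal(r$bayes_fdr_at_threshold, 0.015)
  r2 <- bayesian_fdr_threshold(c(0.99, 0.99), alpha = 0.1)
  expect_equal(r2$selected, c(1L, 2L))
  expect_equal(r2$bayes_fdr_at_threshold, 0.01)
  r3 <- bayesian_fdr_threshold(c(0.5, 0.5), alpha = 0.1)
  expect_true(r3$empty)
  expect_equal(r3$selected, integer(0))
  expect_true(bayesian_fdr_threshold(rep(0, 4), 0.1)$empty)
})

test_that("FDR thresholding agrees with exhaustive enumeration", {
  # over all thresholds, the admissible set maximizing the selection count
  # must equal what the scan returns
  # among ALL subsets, the minimal-FDR set of each size is the top-k by
  # gamma, so the scan must recover the largest admissible subset
  set.seed(77)
  for (k in 1:15) {
    p <- sample(3:10, 1)
    gam <- round(runif(p), 3)
    alpha <- runif(1, 0.05, 0.3)
    r <- bayesian_fdr_threshold(gam, alpha)
    subsets <- expand.grid(rep(list(c(FALSE, TRUE)), p))
    best_size <- 0
    for (m in seq_len(nrow(subsets))) {
      sel <- which(unlist(subsets[m, ]))
      if (length(sel) == 0) next
      if (sum(1 - gam[sel]) / length(sel) < alpha)
        best_size <- max(best_size, length(sel))
    }
    expect_equal(length(r$selected), best_size)
    if (length(r$selected) > 0) {
      expect_lt(sum(1 - gam[r$selected]) / length(r$selected), alpha)
    }
  }
})

test_that("the ELBO decomposes correctly in the spike-only case", {
  d <- toy_data(n = 20, p = 3, seed = 44)
  prior <- svb_prior(lam = 1, a0 = 1, b0 = 9)
  pars <- list(mu = rep(0.5, 3), sigma = rep(0.2, 3), gamma = rep(0, 3))
  e <- elbo_mc(d, pars, prior, n_draws = 10, seed = 1)
  # Q is a point mass at zero: ELL = log L_p(0), KL = -p * log P(z = 0)
  wbar <- 1 / 10
  expect_equal(e$ell, cox_log_plik(d, rep(0, 3)))
  expect_equal(e$kl, -3 * log(1 - wbar), tolerance = 1e-6)
  expect_equal(e$elbo, cox_log_plik(d, rep(0, 3)) + 3 * log(1 - wbar),
               tolerance = 1e-6)
})

test_that("the variational-prior KL is nonnegative on random parameters", {
  set.seed(55)
  for (k in 1:50) {
    p <- sample(1:6, 1)
    pars <- list(mu = rnorm(p), sigma = runif(p, 0.01, 2),
                 gamma = runif(p))
    prior <- svb_prior(lam = runif(1, 0.2, 3), a0 = runif(1, 0.5, 5),
                       b0 = runif(1, 1, 50))
    expect_gte(kl_variational_prior(pars, prior), 0)
  }
})

test_that("prognostic indices and median split behave as linear predictors", {
  d <- survival_dataset(c(1, 2), c(1, 1), matrix(c(1, -1), 2, 1))
  expect_equal(prognostic_index(d, 2), c(2, -2))
  expect_equal(prognostic_index(d, 0), c(0, 0))
  set.seed(3)
  n <- 31
  dd <- toy_data(n = n, p = 2, seed = 3)
  eta <- prognostic_index(dd, c(1, 0.5))
  hi <- eta >= median(eta)
  expect_equal(sort(c(sum(hi), sum(!hi))), c(floor(n / 2), ceiling(n / 2)))
})

test_that("concordance matches pairwise enumeration and survival::concordance", {
  # perfect ranking, all events
  d <- survival_dataset(c(1, 2, 3), c(1, 1, 1), matrix(0, 3, 1))
  expect_equal(concordance_index(d$time, d$status, c(3, 2, 1)), 1)
  # constant index: all ties -> 1/2
  expect_equal(concordance_index(d$time, d$status, c(0, 0, 0)), 0.5)
  # censored instance against survival's estimator
  dd <- toy_data(n = 40, p = 2, seed = 21, censor = 0.35)
  eta <- prognostic_index(dd, c(0.8, -0.3))
  ours <- concordance_index(dd$time, dd$status, eta)
  ref <- survival::concordance(survival::Surv(dd$time, dd$status) ~ eta,
                               reverse = TRUE)$concordance
  expect_equal(ours, unname(ref), tolerance = 1e-12)
  # invariant under strictly increasing transforms
  expect_equal(concordance_index(dd$time, dd$status, exp(eta / 2)), ours)
  # no usable pairs
  expect_warning(
    cc <- concordance_index(c(1, 2), c(0, 1), c(1, 2)), "no usable pairs")
  expect_true(is.na(cc))
})

test_that("risk-comparison probabilities respect their limits", {
  pars <- list(mu = c(0.5, -1), sigma = c(0.2, 0.3), gamma = c(0.9, 0.8))
  x <- c(1, 2)
  expect_equal(risk_comparison_prob(pars, x, x, n_draws = 100, seed = 1), 1)
  # point-mass posterior reduces to an indicator
  pm <- list(mu = c(0.5, -1), sigma = rep(1e-12, 2), gamma = c(1, 1))
  expect_equal(risk_comparison_prob(pm, c(2, 0), c(0, 0), 100, seed = 1), 1)
  expect_equal(risk_comparison_prob(pm, c(0, 1), c(0, 0), 100, seed = 1), 0)
  # symmetric normal: probability one half
  sym <- list(mu = 0, sigma = 1, gamma = 1)
  expect_equal(risk_comparison_prob(sym, 1, 0, n_draws = 2e4, seed = 2), 0.5,
               tolerance = 0.02)
  # complement inequality: P(i >= j) + P(j >= i) >= 1
  set.seed(9)
  for (k in 1:10) {
    pars2 <- list(mu = rnorm(3), sigma = runif(3, 0.05, 0.5),
                  gamma = runif(3))
    xi <- rnorm(3); xj <- rnorm(3)
    pij <- risk_comparison_prob(pars2, xi, xj, 4000, seed = k)
    pji <- risk_comparison_prob(pars2, xj, xi, 4000, seed = k)
    expect_gte(pij + pji, 1)
  }
})

test_that("the risk-comparison matrix is consistent with pairwise calls", {
  pars <- list(mu = c(0.8, -0.2), sigma = c(0.1, 0.2), gamma = c(1, 0.7))
  X <- rbind(a = c(1, 0), b = c(0, 1), c = c(0.5, 0.5))
  M <- risk_comparison_matrix(pars, X, n_draws = 5e3, seed = 4)
  expect_equal(dim(M), c(3L, 3L))
  expect_equal(unname(diag(M)), rep(1, 3))
  expect_true(all(M >= 0 & M <= 1))
  expect_true(M["a", "b"] > 0.9)   # mu puts subject a at clearly higher risk
})
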