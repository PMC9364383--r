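# Independent brute-force implementations used as oracles. These are written
# directly from the definitions (naive loops, raw products, numeric
# integration) and share no code with the package internals they check.

# small reproducible dataset
toy_data <- function(n = 30, p = 3, seed = 7, censor = 0.3, beta = NULL) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  beta <- beta %||% c(1, rep(0, p - 1))
  tt <- rexp(n, rate = exp(drop(X %*% beta)))
  status <- as.integer(runif(n) > censor)
  if (all(status == 0)) status[1] <- 1L
  survival_dataset(tt, status, X)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# risk set by the raw definition, no sorting tricks
risk_members_naive <- function(data, i) which(data$time >= data$time[i])

# log partial likelihood as a direct product of ratios
log_plik_naive <- function(data, beta) {
  eta <- drop(data$X %*% beta)
  out <- 0
  for (i in which(data$status == 1)) {
    r <- risk_members_naive(data, i)
    out <- out + log(exp(eta[i]) / sum(exp(eta[r])))
  }
  out
}

# analytic score of the log partial likelihood
score_plik_naive <- function(data, beta) {
  eta <- drop(data$X %*% beta)
  g <- rep(0, length(beta))
  for (i in which(data$status == 1)) {
    r <- risk_members_naive(data, i)
    w <- exp(eta[r]) / sum(exp(eta[r]))
    g <- g + data$X[i, ] - colSums(w * data$X[r, , drop = FALSE])
  }
  unname(g)
}

# E|beta| for beta ~ N(mu, s^2) by numeric integration
e_abs_naive <- function(mu, s) {
  integrate(function(b) abs(b) * dnorm(b, mu, s), -Inf, Inf,
            rel.tol = 1e-10)$value
}

# raw-product P_j for one subject (no log-space tricks; small data only)
pj_naive <- function(x_r, mu, sigma, gamma, j) {
  idx <- setdiff(seq_along(mu), j)
  prod(gamma[idx] * exp(mu[idx] * x_r[idx] + 0.5 * sigma[idx]^2 * x_r[idx]^2) +
         (1 - gamma[idx]))
}

# direct implementations of the printed coordinate objectives
f_naive <- function(data, params, prior, j, mu_j) {
  sig_j <- params$sigma[j]
  out <- 0
  for (i in which(data$status == 1)) {
    r <- risk_members_naive(data, i)
    terms <- vapply(r, function(rr) {
      exp(mu_j * data$X[rr, j] + 0.5 * sig_j^2 * data$X[rr, j]^2) *
        pj_naive(data$X[rr, ], params$mu, params$sigma, params$gamma, j)
    }, 0)
    out <- out + log(sum(terms)) - mu_j * data$X[i, j]
  }
  unname(out + prior$lam * e_abs_naive(mu_j, sig_j))
}

g_naive <- function(data, params, prior, j, sig_j) {
  mu_j <- params$mu[j]
  out <- 0
  for (i in which(data$status == 1)) {
    r <- risk_members_naive(data, i)
    terms <- vapply(r, function(rr) {
      exp(mu_j * data$X[rr, j] + 0.5 * sig_j^2 * data$X[rr, j]^2) *
        pj_naive(data$X[rr, ], params$mu, params$sigma, params$gamma, j)
    }, 0)
    out <- out + log(sum(terms))
  }
  out + prior$lam * e_abs_naive(mu_j, sig_j) - log(sig_j)
}

zeta_naive <- function(data, params, prior, j) {
  mu_j <- params$mu[j]; sig_j <- params$sigma[j]
  lik <- 0
  for (i in which(data$status == 1)) {
    r <- risk_members_naive(data, i)
    with_m <- vapply(r, function(rr) {
      exp(mu_j * data$X[rr, j] + 0.5 * sig_j^2 * data$X[rr, j]^2) *
        pj_naive(data$X[rr, ], params$mu, params$sigma, params$gamma, j)
    }, 0)
    without_m <- vapply(r, function(rr) {
      pj_naive(data$X[rr, ], params$mu, params$sigma, params$gamma, j)
    }, 0)
    lik <- lik + log(sum(with_m)) - log(sum(without_m)) - mu_j * data$X[i, j]
  }
  unname(log(prior$a0 / prior$b0) -
    (prior$lam * e_abs_naive(mu_j, sig_j) + lik) +
    log(sqrt(2 * pi) * sig_j / prior$lam) + 0.5)
}

# Exhaustive posterior for the spike-and-slab Cox model at p <= 3:
# enumerate inclusion patterns, integrate the slab coefficients on a grid.
# Returns exact-ish inclusion probabilities and posterior means.
enumerate_posterior <- function(data, prior, grid_half = 8, grid_n = 161) {
  p <- ncol(data$X)
  stopifnot(p <= 3)
  wbar <- prior$a0 / (prior$a0 + prior$b0)
  gr <- seq(-grid_half, grid_half, length.out = grid_n)
  dg <- gr[2] - gr[1]
  patterns <- as.matrix(expand.grid(rep(list(0:1), p)))
  log_mass <- numeric(nrow(patterns))
  mean_acc <- matrix(0, nrow(patterns), p)
  for (m in seq_len(nrow(patterns))) {
    z <- patterns[m, ]
    act <- which(z == 1)
    k <- length(act)
    log_prior_z <- sum(z) * log(wbar) + sum(1 - z) * log(1 - wbar)
    if (k == 0) {
      log_mass[m] <- log_prior_z + log_plik_naive(data, rep(0, p))
      next
    }
    pts <- as.matrix(expand.grid(rep(list(gr), k)))
    lv <- apply(pts, 1, function(b) {
      beta <- rep(0, p); beta[act] <- b
      log_plik_naive(data, beta) +
        sum(log(prior$lam / 2) - prior$lam * abs(b))
    })
    mx <- max(lv)
    wts <- exp(lv - mx)
    log_mass[m] <- log_prior_z + mx + log(sum(wts) * dg^k)
    for (d in seq_len(k)) {
      mean_acc[m, act[d]] <- sum(pts[, d] * wts) / sum(wts)
    }
  }
  post <- exp(log_mass - max(log_mass))
  post <- post / sum(post)
  list(inclusion = colSums(post * patterns),
       mean = colSums(post * mean_acc * patterns),
       model_probs = post, patterns = patterns)
}
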