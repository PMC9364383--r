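#' Simulation configuration
#'
#' Describes one synthetic survival study: exponential event times under a
#' unit baseline hazard, uniform-subsampling right censoring, and one of
#' three covariate designs — independent standard normal, block-equicorrelated
#' normal (blocks of 50 at correlation 0.6 by default), or a user-supplied
#' multivariate normal.
#'
#' @param n,p,s sample size, number of covariates, number of nonzero
#'   coefficients.
#' @param c censoring proportion in `[0, 1)`.
#' @param setting `"independent"`, `"block"` or `"mvn"`.
#' @param block_size,rho block design parameters (setting `"block"`).
#' @param mean,Sigma mean vector and covariance matrix (setting `"mvn"`).
#' @param coef_range magnitude range of the nonzero coefficients; values are
#'   drawn uniformly from `[-hi, -lo] U [lo, hi]`.
#' @param seed integer seed making the whole replicate reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n, p, s, c = 0.25,
                       setting = c("independent", "block", "mvn"),
                       block_size = 50, rho = 0.6,
                       mean = NULL, Sigma = NULL,
                       coef_range = c(0.5, 2.0), seed = NULL) {
  setting <- match.arg(setting)
  stopifnot(n >= 1, p >= 1, s >= 0, s <= p, c >= 0, c < 1,
            length(coef_range) == 2, coef_range[1] > 0,
            coef_range[2] >= coef_range[1])
  if (setting == "mvn") {
    stopifnot(!is.null(Sigma), is.matrix(Sigma), nrow(Sigma) == p,
              ncol(Sigma) == p)
    if (max(abs(Sigma - t(Sigma))) > 1e-8)
      stop("Sigma must be symmetric")
    if (is.null(mean)) mean <- rep(0, p)
    stopifnot(length(mean) == p)
  }
  structure(list(n = n, p = p, s = s, c = c, setting = setting,
                 block_size = block_size, rho = rho, mean = mean,
                 Sigma = Sigma, coef_range = coef_range, seed = seed),
            class = "sim_config")
}

#' Draw a sparse coefficient vector
#'
#' Support indices are uniform without replacement (optionally restricted to
#' `eligible`); magnitudes uniform on `coef_range` with random signs.
#' Consumes the current RNG stream.
#'
#' @param p,s dimension and support size.
#' @param coef_range magnitude range.
#' @param eligible optional candidate support indices.
#' @return List with `beta0` (length p) and `support` (sorted indices).
#' @export
draw_coefficients <- function(p, s, coef_range = c(0.5, 2.0),
                              eligible = NULL) {
  if (s > p) stop("config error: s must not exceed p")
  beta0 <- rep(0, p)
  eligible <- eligible %||% seq_len(p)
  if (s > length(eligible)) stop("config error: fewer eligible features than s")
  support <- sort(sample(eligible, s))
  if (s > 0) {
    mag <- runif(s, coef_range[1], coef_range[2])
    sgn <- sample(c(-1, 1), s, replace = TRUE)
    beta0[support] <- sgn * mag
  }
  list(beta0 = beta0, support = support)
}

#' Generate a covariate design matrix
#'
#' Consumes the current RNG stream. In the block setting the trailing
#' columns form a partial block when `p` is not a multiple of `block_size`
#' (a message is emitted).
#'
#' @param config a [sim_config()].
#' @return An `n x p` matrix.
#' @export
generate_design <- function(config) {
  n <- config$n; p <- config$p
  switch(config$setting,
    independent = matrix(rnorm(n * p), n, p),
    block = {
      if (p %% config$block_size != 0)
        message("p is not a multiple of block_size; trailing partial block")
      X <- matrix(0, n, p)
      starts <- seq(1, p, by = config$block_size)
      for (st in starts) {
        en <- min(st + config$block_size - 1, p)
        b <- en - st + 1
        shared <- rnorm(n)
        X[, st:en] <- sqrt(config$rho) * shared +
          sqrt(1 - config$rho) * matrix(rnorm(n * b), n, b)
      }
      X
    },
    mvn = {
      L <- chol(config$Sigma)
      sweep(matrix(rnorm(n * p), n, p) %*% L, 2, config$mean, "+")
    })
}

#' Simulate survival times under the proportional hazards model
#'
#' With a unit baseline hazard the event-time density given covariates is
#' exponential with rate `exp(beta0' x)`. Consumes the current RNG stream.
#'
#' @param design covariate matrix.
#' @param beta0 true coefficient vector.
#' @return Numeric vector of uncensored event times.
#' @export
simulate_survival <- function(design, beta0) {
  eta <- drop(design %*% beta0)
  stopifnot(all(is.finite(eta)))
  rexp(nrow(design), rate = exp(eta))
}

#' Apply uniform-subsampling right censoring
#'
#' Each subject is independently censored with probability `c`; a censored
#' subject's time is replaced by a uniform draw on `(0, t_i)`. Consumes the
#' current RNG stream (indicator draws first, then censoring times).
#'
#' @param times uncensored event times.
#' @param c censoring proportion in `[0, 1)`.
#' @return List with `time` and `status`.
#' @export
apply_censoring <- function(times, c) {
  stopifnot(c >= 0, c < 1)
  n <- length(times)
  d <- runif(n)
  status <- as.integer(d > c)
  cen <- status == 0L
  times[cen] <- runif(sum(cen), 0, times[cen])
  list(time = times, status = status)
}

#' Simulate a complete survival dataset with known truth
#'
#' Runs coefficient drawing, design generation, survival simulation and
#' censoring under the configuration's seed. In the `"mvn"` setting the
#' support is drawn among features with marginal variance at least 1.
#'
#' @param config a [sim_config()].
#' @return Object of class `svb_simulation`: `data` (a
#'   [survival_dataset()]), `beta0`, `support` and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_(config$seed, {
    eligible <- if (config$setting == "mvn")
      which(diag(config$Sigma) >= 1.0) else NULL
    coefs <- draw_coefficients(config$p, config$s, config$coef_range,
                               eligible)
    X <- generate_design(config)
    t0 <- simulate_survival(X, coefs$beta0)
    cen <- apply_censoring(t0, config$c)
    structure(list(data = survival_dataset(cen$time, cen$status, X),
                   beta0 = coefs$beta0, support = coefs$support,
                   config = config),
              class = "svb_simulation")
  })
}

# internal: midrank Mann-Whitney AUC of scores against binary labels
auc_midrank_ <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a fit against the simulation truth
#'
#' Point-estimate errors (l2, l1 of `beta0 - gamma * mu`), selection quality
#' at the 0.5 inclusion threshold (TPR, FDR with 0/0 = 0, midrank AUC of
#' `gamma` as a score for the true support), and credible-set coverage/size
#' split by zero and nonzero truth.
#'
#' @param fit an [svb_fit()] (or any list with `mu`, `sigma`, `gamma`).
#' @param truth an `svb_simulation` (or list with `beta0`, `support`).
#' @param level credible level for the set metrics.
#' @return A one-row data frame of metrics.
#' @export
evaluate_fit <- function(fit, truth, level = 0.95) {
  beta0 <- truth$beta0
  stopifnot(length(beta0) == length(fit$mu))
  beta_hat <- fit$gamma * fit$mu
  sel <- select_at_half(fit)
  support <- truth$support
  tpr <- if (length(support) > 0)
    length(intersect(sel, support)) / length(support) else NA_real_
  fdr <- if (length(sel) > 0)
    length(setdiff(sel, support)) / length(sel) else 0
  cs <- credible_sets(fit, level)
  cov <- coverage_and_size(cs, beta0)
  data.frame(l2 = sqrt(sum((beta0 - beta_hat)^2)),
             l1 = sum(abs(beta0 - beta_hat)),
             tpr = tpr, fdr = fdr,
             auc = auc_midrank_(fit$gamma, as.integer(beta0 != 0)),
             coverage_nonzero = cov$coverage_nonzero,
             size_nonzero = cov$size_nonzero,
             coverage_zero = cov$coverage_zero,
             size_zero = cov$size_zero)
}

#' Run a replicate simulation study
#'
#' Per replicate: simulate under `config` with seed `base_seed + replicate`,
#' fit the variational model, evaluate against the truth. Failed replicates
#' are recorded and excluded from the summaries.
#'
#' @param config a [sim_config()] (its `seed` field is overridden per
#'   replicate).
#' @param prior an [svb_prior()]; defaults to `svb_prior(1, 1, p)`.
#' @param n_reps number of replicates.
#' @param base_seed integer; replicate r uses seed `base_seed + r`.
#' @param control an [svb_control()].
#' @param level credible level for set metrics.
#' @return List of class `svb_replicate_study`: `metrics` (one row per
#'   successful replicate), `summary` (median and 5%/95% quantiles per
#'   error/selection metric; mean and sd per coverage/size metric),
#'   `n_failed`, `failures`.
#' @export
run_replicates <- function(config, prior = NULL, n_reps, base_seed,
                           control = svb_control(), level = 0.95) {
  stopifnot(n_reps >= 1)
  rows <- vector("list", n_reps)
  failures <- character(0)
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- base_seed + r
    out <- tryCatch({
      sim <- simulate_dataset(cfg)
      fit <- svb_fit(sim$data, prior = prior, control = control)
      cbind(replicate = r, seed = cfg$seed, evaluate_fit(fit, sim, level))
    }, error = function(e) {
      failures <<- c(failures,
                     sprintf("replicate %d: %s", r, conditionMessage(e)))
      NULL
    })
    rows[[r]] <- out
  }
  metrics <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  qcols <- c("l2", "l1", "tpr", "fdr", "auc")
  mcols <- c("coverage_nonzero", "size_nonzero", "coverage_zero", "size_zero")
  summary <- rbind(
    do.call(rbind, lapply(qcols, function(cl) {
      q <- quantile(metrics[[cl]], c(0.5, 0.05, 0.95), names = FALSE,
                    na.rm = TRUE)
      data.frame(metric = cl, estimate = q[1], q05 = q[2], q95 = q[3],
                 mean = NA_real_, sd = NA_real_)
    })),
    do.call(rbind, lapply(mcols, function(cl) {
      data.frame(metric = cl, estimate = mean(metrics[[cl]], na.rm = TRUE),
                 q05 = NA_real_, q95 = NA_real_,
                 mean = mean(metrics[[cl]], na.rm = TRUE),
                 sd = sd(metrics[[cl]]))
    })))
  structure(list(metrics = metrics, summary = summary,
                 n_failed = length(failures), failures = failures,
                 config = config, base_seed = base_seed),
            class = "svb_replicate_study")
}

#' @exportS3Method base::print
print.svb_replicate_study <- function(x, ...) {
  cat(sprintf("<svb_replicate_study> %d replicates (%d failed)\n",
              nrow(x$metrics) + x$n_failed, x$n_failed))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
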