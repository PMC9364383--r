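#' Spike-and-slab prior specification
#'
#' The prior places, per coefficient, a Dirac spike at zero or a
#' `Laplace(lam)` slab, with inclusion governed by a `Beta(a0, b0)`
#' hyperprior on the per-coordinate inclusion probability. `lam` controls
#' slab shrinkage (larger = more shrinkage); `a0 / (a0 + b0)` is the prior
#' proportion of nonzero coefficients.
#'
#' @param lam Laplace slab rate (> 0).
#' @param a0,b0 Beta hyperparameters (> 0). `b0 = NULL` defaults to `p`
#'   at fit time.
#' @return A list of class `svb_prior`.
#' @seealso [default_prior()] for the recommended profiles.
#' @export
svb_prior <- function(lam = 1, a0 = 1, b0 = NULL) {
  stopifnot(lam > 0, a0 > 0, is.null(b0) || b0 > 0)
  structure(list(lam = lam, a0 = a0, b0 = b0), class = "svb_prior")
}

#' Control settings for the coordinate-ascent optimizer
#'
#' @param tol convergence tolerance on the total absolute parameter change
#'   per sweep (default `1e-3`).
#' @param max_iter maximum number of full coordinate sweeps.
#' @param brent_tol tolerance of the 1-D Brent minimizations.
#' @param instrument record the largest observed increase of any
#'   per-coordinate objective across updates (diagnostic; small overhead).
#' @param verbose print per-sweep convergence statistics.
#' @return A list of class `svb_control`.
#' @export
svb_control <- function(tol = 1e-3, max_iter = 1000, brent_tol = 1e-6,
                        instrument = FALSE, verbose = FALSE) {
  stopifnot(tol > 0, max_iter >= 1, brent_tol > 0)
  structure(list(tol = tol, max_iter = max_iter, brent_tol = brent_tol,
                 instrument = isTRUE(instrument), verbose = isTRUE(verbose)),
            class = "svb_control")
}

#' Initialize the variational parameters
#'
#' `mu` is taken from an l1-penalized Cox fit with a small penalty (the
#' smallest value on the path keeping at most `min(n/2, 200)` coefficients
#' nonzero), since `mu` plays the role of the unshrunk slab means; `gamma`
#' starts at 0.5 everywhere and `sigma` at 0.05.
#'
#' @param data a [survival_dataset()].
#' @param max_df cap on the number of nonzero initializer coefficients.
#' @return List with `mu`, `sigma`, `gamma`.
#' @export
svb_init <- function(data, max_df = NULL) {
  stopifnot(inherits(data, "survival_dataset"))
  n <- length(data$time)
  p <- ncol(data$X)
  max_df <- max_df %||% min(floor(n / 2), 200)
  mu <- tryCatch({
    fit <- glmnet::glmnet(data$X, survival::Surv(data$time, data$status),
                          family = "cox", nlambda = 50)
    ok <- which(fit$df <= max_df)
    s <- fit$lambda[max(ok)]
    as.numeric(coef(fit, s = s))
  }, error = function(e) {
    warning("l1 initializer failed (", conditionMessage(e),
            "); falling back to mu = 0")
    rep(0, p)
  })
  list(mu = mu, sigma = rep(0.05, p), gamma = rep(0.5, p))
}

#' Fit the sparse variational Bayes proportional hazards model
#'
#' Coordinate-ascent variational inference: sweeps coordinates `j = 1..p`,
#' updating `mu_j` and `sigma_j` by bracketed Brent minimization of their
#' printed surrogate objectives and `gamma_j` by a closed-form sigmoid,
#' stopping when the total absolute parameter change per sweep falls below
#' `control$tol`.
#'
#' @param data a [survival_dataset()] with at least one event.
#' @param prior an [svb_prior()]; defaults to `svb_prior(1, 1, p)`.
#' @param control an [svb_control()].
#' @param init optional initialization list (see [svb_init()]).
#' @return An object of class `svb_fit` with elements `mu`, `sigma`,
#'   `gamma`, `converged`, `n_iter`, `trajectory` (the per-sweep stopping
#'   statistic), `prior`, `control` and, when instrumented, `instrument`.
#' @examples
#' sim <- simulate_dataset(sim_config(n = 60, p = 12, s = 2, c = 0.25, seed = 1))
#' fit <- svb_fit(sim$data)
#' coef(fit)
#' @export
svb_fit <- function(data, prior = NULL, control = svb_control(), init = NULL) {
  stopifnot(inherits(data, "survival_dataset"))
  p <- ncol(data$X)
  prior <- prior %||% svb_prior()
  if (is.null(prior$b0)) prior$b0 <- p
  prep <- svb_prepare(data)
  init <- init %||% svb_init(data)
  stopifnot(length(init$mu) == p, length(init$sigma) == p,
            length(init$gamma) == p, all(init$sigma > 0),
            all(init$gamma >= 0), all(init$gamma <= 1))
  res <- cavi_cpp(prep$X, prep$ev, prep$rs,
                  prior$lam, prior$a0, prior$b0,
                  init$mu, init$sigma, init$gamma,
                  control$tol, control$max_iter, control$brent_tol,
                  control$instrument)
  if (control$verbose) {
    message(sprintf("svb_fit: %d sweeps, final change %.3g, converged: %s",
                    res$n_iter, utils::tail(res$trajectory, 1), res$converged))
  }
  structure(list(
    mu = res$mu, sigma = res$sigma, gamma = res$gamma,
    converged = res$converged, n_iter = res$n_iter,
    trajectory = res$trajectory,
    instrument = if (control$instrument)
      list(max_f_increase = res$max_f_increase,
           max_g_increase = res$max_g_increase,
           n_safeguard = res$n_safeguard),
    prior = prior, control = control, init = init,
    feature_names = colnames(data$X)), class = "svb_fit")
}

#' @exportS3Method base::print
print.svb_fit <- function(x, ...) {
  cat(sprintf("<svb_fit> p = %d, selected (gamma >= 0.5): %d, %s after %d sweeps\n",
              length(x$mu), sum(x$gamma >= 0.5),
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' @export
coef.svb_fit <- function(object, ...) posterior_mean(object)

# internal: shared argument massaging for the exposed coordinate operations
coord_args_ <- function(data, params, prior, j) {
  prep <- svb_prepare(data)
  if (is.null(prior$b0)) prior$b0 <- ncol(data$X)
  stopifnot(j >= 1, j <= ncol(data$X))
  list(prep = prep, prior = prior, j0 = as.integer(j - 1L))
}

#' Evaluate the per-coordinate variational objectives
#'
#' `svb_objective_mu` evaluates the surrogate objective minimized by the
#' `mu_j` update (risk-set log-sum-exp terms plus the Laplace-slab
#' expectation); `svb_objective_sigma` the analogous objective for
#' `sigma_j` (with the `-log sigma_j` entropy barrier); `svb_zeta` the
#' logit of the `gamma_j` update. All other parameters are held at the
#' values in `params`.
#'
#' @param data a [survival_dataset()].
#' @param params list/fit with `mu`, `sigma`, `gamma`.
#' @param prior an [svb_prior()].
#' @param j coordinate index (1-based).
#' @param at numeric vector of candidate values for the coordinate.
#' @return Objective values at `at` (or the scalar zeta).
#' @export
svb_objective_mu <- function(data, params, prior, j, at) {
  a <- coord_args_(data, params, prior, j)
  coord_objective_cpp(a$prep$X, a$prep$ev, a$prep$rs,
                      params$mu, params$sigma, params$gamma,
                      a$prior$lam, a$prior$a0, a$prior$b0,
                      a$j0, 0L, as.numeric(at))
}

#' @rdname svb_objective_mu
#' @export
svb_objective_sigma <- function(data, params, prior, j, at) {
  if (any(at <= 0)) stop("sigma must be strictly positive")
  a <- coord_args_(data, params, prior, j)
  coord_objective_cpp(a$prep$X, a$prep$ev, a$prep$rs,
                      params$mu, params$sigma, params$gamma,
                      a$prior$lam, a$prior$a0, a$prior$b0,
                      a$j0, 1L, as.numeric(at))
}

#' @rdname svb_objective_mu
#' @export
svb_zeta <- function(data, params, prior, j) {
  a <- coord_args_(data, params, prior, j)
  coord_objective_cpp(a$prep$X, a$prep$ev, a$prep$rs,
                      params$mu, params$sigma, params$gamma,
                      a$prior$lam, a$prior$a0, a$prior$b0,
                      a$j0, 2L, numeric(0))
}

#' Single-coordinate variational updates
#'
#' Apply one update of `mu_j`, `sigma_j` or `gamma_j` with every other
#' parameter held fixed, returning the updated parameter set. The 1-D
#' updates never increase their own objective: if the bracketed Brent search
#' fails to improve on the current value, the previous value is kept.
#'
#' @inheritParams svb_objective_mu
#' @param brent_tol tolerance of the 1-D minimization.
#' @return `params` with the single coordinate updated; attributes
#'   `objective_before`/`objective_after` record the printed objective (for
#'   `gamma`, the zeta logit).
#' @export
svb_update_mu <- function(data, params, prior, j, brent_tol = 1e-6) {
  coord_update_(data, params, prior, j, 0L, brent_tol)
}

#' @rdname svb_update_mu
#' @export
svb_update_sigma <- function(data, params, prior, j, brent_tol = 1e-6) {
  coord_update_(data, params, prior, j, 1L, brent_tol)
}

#' @rdname svb_update_mu
#' @export
svb_update_gamma <- function(data, params, prior, j, brent_tol = 1e-6) {
  coord_update_(data, params, prior, j, 2L, brent_tol)
}

coord_update_ <- function(data, params, prior, j, what, brent_tol) {
  a <- coord_args_(data, params, prior, j)
  res <- coord_update_cpp(a$prep$X, a$prep$ev, a$prep$rs,
                          params$mu, params$sigma, params$gamma,
                          a$prior$lam, a$prior$a0, a$prior$b0,
                          a$j0, what, brent_tol)
  if (isTRUE(res$kept_previous))
    warning(sprintf("coordinate %d: optimizer failed to improve; keeping previous value", j))
  out <- params[c("mu", "sigma", "gamma")]
  slot <- c("mu", "sigma", "gamma")[what + 1L]
  out[[slot]][j] <- res$value
  attr(out, "objective_before") <- res$objective_before
  attr(out, "objective_after") <- res$objective_after
  out
}

#' Serialize a fit report to JSON
#'
#' Writes the variational parameters, convergence metadata and prior
#' specification.
#'
#' @param fit an [svb_fit()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_svb_fit <- function(fit, path) {
  stopifnot(inherits(fit, "svb_fit"))
  jsonlite::write_json(list(
    mu = fit$mu, sigma = fit$sigma, gamma = fit$gamma,
    converged = fit$converged, n_iter = fit$n_iter,
    trajectory = fit$trajectory,
    prior = unclass(fit$prior), feature_names = fit$feature_names),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
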