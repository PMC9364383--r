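#' Reference posterior sampler for the spike-and-slab Cox model
#'
#' Metropolis-within-Gibbs targeting the exact partial-likelihood posterior
#' under the Dirac-spike/Laplace-slab prior, with the per-coordinate Beta
#' hyperpriors marginalized analytically to independent
#' `Bernoulli(a0 / (a0 + b0))` inclusions. Per coordinate and iteration the
#' sampler proposes an add move (slab draw from the Laplace prior), a delete
#' move, or a random walk on the active coefficient; random-walk scales are
#' adapted towards 30% acceptance during burn-in and frozen afterwards.
#' Intended as a small-scale correctness oracle, not a production sampler.
#'
#' @param data a [survival_dataset()], or `NULL` to sample the prior alone
#'   (`p` must then be given); a dataset with zero events is an error.
#' @param prior an [svb_prior()] with `b0` set (defaults to `p`).
#' @param n_iter,burn_in chain length and burn-in (defaults 10000 / 1000).
#' @param seed optional integer seed.
#' @param p number of coefficients when `data = NULL`.
#' @param init_scale initial random-walk standard deviation.
#' @return Object of class `svb_mcmc`: `draws` (p x kept matrix of
#'   coefficient draws, zero when excluded), `acceptance` rates per move
#'   type, `burn_in`, `seed`, `prior`, `rw_log_scale`.
#' @export
svb_mcmc <- function(data = NULL, prior = NULL, n_iter = 10000,
                     burn_in = 1000, seed = NULL, p = NULL,
                     init_scale = 0.5) {
  stopifnot(n_iter > burn_in, burn_in >= 0)
  if (is.null(data)) {
    stopifnot(!is.null(p), p >= 1)
    X <- matrix(0, 1, p)
    ev <- integer(0); rs <- integer(0)
  } else {
    stopifnot(inherits(data, "survival_dataset"))
    p <- ncol(data$X)
    if (p > 2000)
      warning("p > 2000: the reference sampler is intended for small problems")
    prep <- svb_prepare(data)   # errors when there are no events
    X <- prep$X; ev <- prep$ev; rs <- prep$rs
  }
  prior <- prior %||% svb_prior()
  if (is.null(prior$b0)) prior$b0 <- p
  res <- with_seed_(seed,
    mcmc_cpp(X, ev, rs, prior$lam, log(prior$a0 / prior$b0),
             as.integer(n_iter), as.integer(burn_in), init_scale, 0.3))
  structure(list(draws = res$draws, acceptance = res$acceptance,
                 n_iter = n_iter, burn_in = burn_in, seed = seed,
                 prior = prior, rw_log_scale = res$rw_scale),
            class = "svb_mcmc")
}

#' @exportS3Method base::print
print.svb_mcmc <- function(x, ...) {
  cat(sprintf("<svb_mcmc> p = %d, %d kept draws (burn-in %d)\n",
              nrow(x$draws), ncol(x$draws), x$burn_in))
  cat("acceptance:", paste(sprintf("%s %.2f", names(x$acceptance),
                                   x$acceptance), collapse = ", "), "\n")
  invisible(x)
}

# internal: batch-means Monte-Carlo standard error of a chain mean
batch_means_se <- function(x, n_batch = 30) {
  m <- length(x)
  n_batch <- min(n_batch, m)
  bs <- floor(m / n_batch)
  means <- vapply(seq_len(n_batch),
                  function(b) mean(x[((b - 1) * bs + 1):(b * bs)]), 0)
  sd(means) / sqrt(n_batch)
}

#' Summaries of a reference MCMC chain
#'
#' Posterior means, inclusion probabilities (fraction of kept draws with a
#' nonzero coefficient), batch-means standard errors for both, and
#' empirical marginal credible sets built by the same three-case rule as the
#' variational sets, with equal-tailed empirical quantiles of the slab draws
#' for the interval part.
#'
#' @param chain an [svb_mcmc()] object.
#' @param level credible level.
#' @return List with `mean`, `mean_se`, `inclusion`, `inclusion_se` and
#'   `sets` (a data frame as in [credible_sets()]).
#' @export
chain_summaries <- function(chain, level = 0.95) {
  stopifnot(inherits(chain, "svb_mcmc"), level > 0, level < 1)
  draws <- chain$draws
  p <- nrow(draws)
  incl <- rowMeans(draws != 0)
  means <- rowMeans(draws)
  mean_se <- apply(draws, 1, batch_means_se)
  incl_se <- apply(draws != 0, 1, batch_means_se)
  sets <- lapply(seq_len(p), function(j) {
    g <- incl[j]
    slab <- draws[j, draws[j, ] != 0]
    if (g > level) {
      q <- quantile(slab, c((1 - level / g) / 2, (1 + level / g) / 2),
                    names = FALSE)
      list(kind = "interval", lower = q[1], upper = q[2], size = diff(q))
    } else if (g < 1 - level) {
      list(kind = "spike_only", lower = NA_real_, upper = NA_real_, size = 0)
    } else {
      m <- (level - (1 - g)) / g
      q <- quantile(slab, c((1 - m) / 2, (1 + m) / 2), names = FALSE)
      list(kind = "interval_plus_spike", lower = q[1], upper = q[2],
           size = diff(q))
    }
  })
  list(mean = means, mean_se = mean_se,
       inclusion = incl, inclusion_se = incl_se,
       sets = data.frame(kind = vapply(sets, `[[`, "", "kind"),
                         lower = vapply(sets, `[[`, 0, "lower"),
                         upper = vapply(sets, `[[`, 0, "upper"),
                         size = vapply(sets, `[[`, 0, "size")))
}

#' Write an MCMC chain as a TSV table with a JSON manifest
#'
#' @param chain an [svb_mcmc()].
#' @param path output TSV path (one column per coefficient, one row per
#'   kept draw).
#' @param manifest optional JSON manifest path (seed, moves, acceptance).
#' @return `path`, invisibly.
#' @export
write_chain <- function(chain, path, manifest = NULL) {
  stopifnot(inherits(chain, "svb_mcmc"))
  write.table(t(chain$draws), path, sep = "\t", row.names = FALSE,
              col.names = paste0("beta", seq_len(nrow(chain$draws))),
              quote = FALSE)
  if (!is.null(manifest)) {
    jsonlite::write_json(list(n_iter = chain$n_iter, burn_in = chain$burn_in,
                              seed = chain$seed,
                              acceptance = as.list(chain$acceptance),
                              prior = unclass(chain$prior)),
                         manifest, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(path)
}
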