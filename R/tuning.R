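#' Default prior profiles
#'
#' `"simulation"` uses `lam = 1, a0 = 1, b0 = p`; `"omics"` uses
#' `lam = 1, a0 = p/100, b0 = p` (with a floor of 0.01 on `a0`), reflecting
#' the belief that few features carry signal.
#'
#' @param p number of covariates.
#' @param profile `"simulation"` or `"omics"`.
#' @return An [svb_prior()].
#' @export
default_prior <- function(p, profile = c("simulation", "omics")) {
  stopifnot(p >= 1)
  profile <- tryCatch(match.arg(profile), error = function(e)
    stop("unknown profile; available profiles: simulation, omics"))
  switch(profile,
         simulation = svb_prior(lam = 1, a0 = 1, b0 = p),
         omics = svb_prior(lam = 1, a0 = max(p / 100, 0.01), b0 = p))
}

#' Assign subjects to cross-validation folds
#'
#' Near-equal random partition; errors when any training set (complement of
#' a fold) would contain no events.
#'
#' @param data a [survival_dataset()].
#' @param n_folds number of folds (>= 2).
#' @param seed optional integer seed.
#' @return Integer fold assignment of length n.
#' @export
kfold_split <- function(data, n_folds, seed = NULL) {
  stopifnot(inherits(data, "survival_dataset"), n_folds >= 2,
            length(data$time) >= n_folds)
  n <- length(data$time)
  folds <- with_seed_(seed, sample(rep(seq_len(n_folds), length.out = n)))
  for (f in seq_len(n_folds)) {
    if (sum(data$status[folds != f]) == 0)
      stop(sprintf("training set for fold %d contains no events", f))
  }
  folds
}

# internal: survival_dataset restricted to a subject subset
subset_data_ <- function(data, idx) {
  survival_dataset(data$time[idx], data$status[idx],
                   data$X[idx, , drop = FALSE])
}

#' Cross-validated grid search over prior hyperparameters
#'
#' For each `(lam, a0)` cell and fold: center covariates on the training
#' subjects only, fit the variational model, and evaluate the Monte-Carlo
#' ELBO, the expected log partial likelihood (ELL) and the concordance index
#' on both the training and validation subjects. The best cell maximizes the
#' mean validation criterion, with ties broken towards larger `lam`
#' (sparser fits).
#'
#' @param data a [survival_dataset()] (uncentered; centering is refit per
#'   training fold).
#' @param lambda_values,a0_values grids of positive values.
#' @param b0 fixed second Beta hyperparameter (default `p`).
#' @param n_folds number of folds.
#' @param criterion `"ell"`, `"elbo"` or `"cindex"`; all three are always
#'   reported.
#' @param n_draws Monte-Carlo draws for ELBO/ELL.
#' @param seed integer seed controlling the fold split and MC draws.
#' @param control an [svb_control()].
#' @return List of class `svb_cv`: `table` (one row per cell, fold and
#'   split with all three criteria), `summary` (mean/sd per cell and
#'   split), `best` (the selected cell), `folds`.
#' @export
cv_grid_search <- function(data, lambda_values, a0_values = 1, b0 = NULL,
                           n_folds = 10, criterion = c("ell", "elbo", "cindex"),
                           n_draws = 1000, seed = NULL,
                           control = svb_control()) {
  criterion <- match.arg(criterion)
  stopifnot(length(lambda_values) >= 1, length(a0_values) >= 1,
            all(lambda_values > 0), all(a0_values > 0))
  p <- ncol(data$X)
  b0 <- b0 %||% p
  folds <- kfold_split(data, n_folds, seed)
  grid <- expand.grid(lam = lambda_values, a0 = a0_values)
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    prior <- svb_prior(lam = grid$lam[g], a0 = grid$a0[g], b0 = b0)
    for (f in seq_len(n_folds)) {
      cell <- tryCatch({
        train <- center_covariates(subset_data_(data, folds != f))
        valid <- apply_centering(subset_data_(data, folds == f),
                                 attr(train, "centers"))
        fit <- svb_fit(train, prior = prior, control = control)
        bh <- posterior_mean(fit)
        fold_seed <- if (is.null(seed)) NULL else seed + 1000L * g + f
        eval_split <- function(d) {
          e <- elbo_mc(d, fit, prior, n_draws = n_draws, seed = fold_seed)
          data.frame(elbo = e$elbo, ell = e$ell,
                     cindex = concordance_index(d$time, d$status,
                                                prognostic_index(d, bh)))
        }
        rbind(cbind(lam = prior$lam, a0 = prior$a0, fold = f,
                    split = "train", eval_split(train),
                    fit_seed = fold_seed %||% NA_integer_),
              cbind(lam = prior$lam, a0 = prior$a0, fold = f,
                    split = "validation", eval_split(valid),
                    fit_seed = fold_seed %||% NA_integer_))
      }, error = function(e) {
        warning(sprintf("cell (lam=%g, a0=%g), fold %d failed: %s",
                        prior$lam, prior$a0, f, conditionMessage(e)))
        NULL
      })
      rows[[length(rows) + 1L]] <- cell
    }
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  agg <- aggregate(tab[c("elbo", "ell", "cindex")],
                   by = tab[c("lam", "a0", "split")],
                   FUN = function(v) c(mean = mean(v), sd = sd(v)))
  val <- agg[agg$split == "validation", ]
  score <- val[[criterion]][, "mean"]
  best_rows <- which(score == max(score))
  best <- best_rows[which.max(val$lam[best_rows])]   # ties to larger lambda
  structure(list(table = tab, summary = agg,
                 best = list(lam = val$lam[best], a0 = val$a0[best], b0 = b0,
                             criterion = criterion, value = score[best]),
                 folds = folds, criterion = criterion),
            class = "svb_cv")
}

#' @exportS3Method base::print
print.svb_cv <- function(x, ...) {
  cat(sprintf("<svb_cv> best cell by validation %s: lam = %g, a0 = %g (%.4g)\n",
              x$criterion, x$best$lam, x$best$a0, x$best$value))
  invisible(x)
}
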