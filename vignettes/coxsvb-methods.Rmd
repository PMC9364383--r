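---
title: "Sparse variational Bayes for the proportional hazards model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse variational Bayes for the proportional hazards model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coxsvb)
```

## The inferential problem

We observe right-censored survival data $\mathcal{D} = \{(t_i, \delta_i,
x_i)\}_{i=1}^n$ with $x_i \in \mathbb{R}^p$ and $p$ potentially far larger
than $n$, as in transcriptomic studies where a few genes at most are
expected to influence survival. The goals are simultaneous variable
selection, effect estimation and uncertainty quantification, at a cost that
scales to $p$ in the thousands. Exact Bayesian inference over the $2^p$
inclusion patterns of a spike-and-slab prior is intractable, and MCMC over
that space takes hours where the variational fit below takes seconds.

## Model and prior

The hazard is $h(t; x) = h_0(t)\exp(\beta^\top x)$ and inference uses Cox's
partial likelihood, so $h_0$ is never specified. The prior on each
coefficient is a Dirac-spike/Laplace-slab mixture,
$$\beta_j \mid z_j \sim z_j\,\mathrm{Laplace}(\lambda) + (1 - z_j)\,\delta_0,
\qquad z_j \mid w_j \sim \mathrm{Bernoulli}(w_j), \qquad w_j \sim
\mathrm{Beta}(a_0, b_0).$$
A Laplace rather than Gaussian slab avoids over-shrinking large signals.
Because the $w_j$ are independent across coordinates, marginalizing them is
exact and gives i.i.d. $z_j \sim \mathrm{Bernoulli}(\bar w)$ with $\bar w =
a_0/(a_0 + b_0)$; everywhere the package needs the $z$-prior (the
$\gamma$ update, the KL term of the ELBO, the reference sampler) it uses
this collapsed form, which involves no approximation.

Interpretation and defaults of the hyperparameters:

* $\lambda$ (slab rate, default 1): shrinkage on included coefficients;
  values between 0.5 and 2 are sensible for log-hazard effects of moderate
  size, and `cv_grid_search()` tunes it when no prior choice is available.
* $a_0, b_0$: prior inclusion odds $a_0/b_0$. `default_prior(p,
  "simulation")` gives $(1, p)$; `default_prior(p, "omics")` gives
  $(p/100, p)$, i.e. about 1% of features believed active.

## Variational family and surrogate objectives

The posterior is approximated within the mean-field family
$$Q_{\mu,\sigma,\gamma} = \bigotimes_{j=1}^p \left[\gamma_j\,
\mathcal{N}(\mu_j, \sigma_j^2) + (1 - \gamma_j)\,\delta_0\right],$$
which keeps the discrete selection structure: $\gamma_j = Q(\beta_j \neq
0)$ is a posterior inclusion probability. The KL divergence to the
partial-likelihood posterior is not tractable, so the fit minimizes a
surrogate objective whose per-coordinate pieces are built from risk-set
sums of the slab moment generating function
$M(x; \mu, \sigma) = \exp(\mu x + \sigma^2 x^2/2)$ and the excluded
products $P_j(x_r) = \prod_{k \neq j}\left(\gamma_k M(x_{rk}; \mu_k,
\sigma_k) + 1 - \gamma_k\right)$:

* $f(\mu_j)$: event-sum of $\log \sum_{r \in R(t_i)} M(x_{rj}; \mu_j,
  \sigma_j) P_j(x_r) - \mu_j x_{ij}$, plus the slab penalty
  $\lambda\,\mathbb{E}|\beta_j|$ under $\mathcal{N}(\mu_j, \sigma_j^2)$
  (a folded-normal mean, `laplace_slab_expectation()`).
* $g(\sigma_j)$: the same event-sum plus the slab penalty, minus
  $\log \sigma_j$ — the entropy barrier that prevents slab collapse.
* $\zeta_j$ (logit of the $\gamma_j$ update): prior log-odds
  $\log(a_0/b_0)$, minus the slab penalty and the likelihood gain of
  inclusion (the difference between the event-sum with and without $M$),
  plus $\log(\sqrt{2\pi}\sigma_j/\lambda) + 1/2$.

These three expressions are implemented verbatim; the upper-bound
derivation that produces them is taken as given, and the test suite pins
each one against an independent direct implementation (raw products over
definitional risk sets) to $10^{-8}$.

## The coordinate-ascent loop

Coordinates are swept in fixed ascending order $j = 1, \dots, p$, applying
the $\mu_j$, then $\sigma_j$, then $\gamma_j$ update; deterministic order
makes every fit bit-reproducible. Numerical choices:

* **1-D minimization.** Brent's derivative-free method, tolerance
  $10^{-6}$. The $\mu$ bracket is centred at the current value with width
  10 and expands (up to three times) if the minimizer lands on an edge;
  the $\sigma$ search runs on the log scale over $[10^{-4}, 10]$. If a
  search fails to improve the current value, the previous value is kept —
  so no update can increase its own objective.
* **Log-space risk sums.** Subjects are sorted by time once, so each
  risk-set sum is a suffix log-sum-exp, evaluated with a running-maximum
  recursion; $M$ is never exponentiated in raw form since $\mu_j x_{rj} +
  \sigma_j^2 x_{rj}^2/2$ can exceed floating-point range on
  expression-scale covariates. Ties $t_r = t_i$ are kept in the risk set
  (the literal definition; no Efron-type correction). Tied event times
  contribute separate factors with identical risk sets.
* **Cache.** An $n \times p$ matrix of per-coordinate log factors
  $\log(\gamma_k M + 1 - \gamma_k)$ and its row sums give each $\log P_j$
  in $O(1)$ per subject; after a coordinate update only its column and the
  row sums are refreshed ($O(np)$ per sweep instead of $O(np^2)$), and the
  cache is rebuilt from scratch at the top of every sweep to stop drift.
* **Clamping.** $\gamma_j$ is clamped to $[10^{-12}, 1 - 10^{-12}]$ after
  the sigmoid so the log factors stay finite.
* **Stopping.** Total absolute parameter change per sweep below $10^{-3}$
  (`svb_control(tol =)`), with a 1000-sweep cap; the per-sweep statistic is
  returned as the `trajectory`. The ELBO is deliberately *not* used for
  stopping: it is only available by Monte Carlo here (`elbo_mc()`), and is
  reported for tuning instead.

**Initialization.** $\mu$ starts at an $\ell_1$-penalized Cox fit (glmnet)
with a small penalty — the smallest on the path keeping at most
$\min(n/2, 200)$ coefficients active — because $\mu_j$ plays the role of
the *unshrunk* mean given inclusion; $\gamma$ starts at $0.5$ and $\sigma$
at $0.05$. The coordinate objectives are non-convex, so a good $\mu$ start
matters; the fit is much less sensitive to $\sigma$. Whether $\mu_j$ and
$\sigma_j$ should be re-optimized jointly is open; the sequential order
above is used as specified.

## Posterior summaries

* **Point estimates.** The posterior mean is $\hat\beta_j = \gamma_j\mu_j$.
* **Selection.** `select_at_half()` thresholds $\gamma_j \ge 0.5$.
  `bayesian_fdr_threshold()` instead scans candidate thresholds $k$ (the
  distinct $\gamma$ values, plus 0) and keeps the *smallest* $k$ whose
  selected set $\{j : \gamma_j > k\}$ has Bayesian FDR
  $\sum(1-\gamma_j)\mathbb{1}\{\gamma_j > k\} / \sum\mathbb{1}\{\gamma_j >
  k\}$ below $\alpha$. The printed argmax form of this rule is not
  well-defined as $k \to 1$ (the ratio becomes $0/0$, and large $k$
  trivially satisfies the bound with ever fewer discoveries), so the
  package resolves it toward the largest admissible selected set — the
  reading under which the rule discovers anything at all.
* **Credible sets.** The 95% marginal set is the slab interval $I_j$ when
  $\gamma_j > 0.95$, the spike $\{0\}$ when $\gamma_j < 0.05$, and $I_j
  \cup \{0\}$ otherwise. $I_j$ is symmetric about $\mu_j$ (for a normal
  slab the smallest — highest-density — interval is the symmetric one) and
  sized so the *total* variational mass of the set reaches the level: the
  spike atom counts when $0$ belongs to the set, so in the middle case the
  slab needs mass $(\mathrm{level} - (1-\gamma_j))/\gamma_j$. This makes
  "the set holds 95% of the posterior mass" literally true, which the
  suite verifies by numerical integration over random parameter triples.
* **Risk comparisons.** `risk_comparison_prob()` estimates
  $Q(\beta^\top x_i \ge \beta^\top x_j)$ by Monte Carlo over coefficient
  draws (default $10^4$, seed required for reproducibility);
  `prognostic_index()` and `concordance_index()` (Harrell's pairwise
  estimator, ties in the index counting 1/2) support the usual
  median-split risk grouping.
* **ELBO.** $\mathrm{ELBO} = \mathbb{E}_Q[\log L_p] - \mathrm{KL}(Q \Vert
  \Pi)$ with the likelihood term by Monte Carlo and the KL in closed form:
  per coordinate a Bernoulli KL against $\bar w$ (exact, see above) plus
  $\gamma_j\,\mathrm{KL}(\mathcal{N}(\mu_j,\sigma_j^2) \Vert
  \mathrm{Laplace}(\lambda))$.

## The reference sampler

`svb_mcmc()` targets the exact spike-and-slab partial-likelihood posterior
with Metropolis-within-Gibbs; its role is correctness checking at small
$p$, not production inference. Any correct sampler targets the same
distribution, so the move set is a design choice: per coordinate, an add
move proposing from the Laplace slab (whose density cancels in the
acceptance ratio, leaving the likelihood ratio times the prior inclusion
odds), the mirror delete move, and a Gaussian random walk on active
coefficients whose per-coordinate scale adapts toward 30% acceptance
during burn-in and is frozen afterwards. Defaults are 10,000 iterations
with 1,000 burn-in. `chain_summaries()` reports batch-means Monte-Carlo
standard errors; for coordinates whose draws are almost surely exactly
zero, batch-means SEs degenerate to zero, so comparisons against the
variational means in the test suite floor the SE at $10^{-3}$ on the
log-hazard scale — below that resolution both estimates are simply "zero".
On $p \le 3$ problems the suite checks the sampler against exhaustive
enumeration of inclusion patterns with grid quadrature over the slab.

## The synthetic-data generator

`simulate_dataset()` emulates a sparse survival design: $s$ nonzero
coefficients with magnitudes uniform on $[0.5, 2]$ and random signs at
uniformly chosen positions; covariates from one of three settings —
independent $\mathcal{N}(0, I)$, block-equicorrelated normal (blocks of 50
at correlation 0.6 by default, a moderately hard correlated design), or a
user-supplied multivariate normal (in which case the support is drawn
among features with marginal variance at least 1, so signals are not
hidden in near-constant columns); survival times exponential with rate
$\exp(\beta_0^\top x)$, i.e. a unit baseline hazard; and censoring by
independent coin flips at rate $c$, with censored times resampled
uniformly on $(0, t_i)$. Indicator draws and censoring-time draws are
taken sequentially from one seeded stream, so a replicate is fully
determined by its seed.

What this generator does *not* emulate: heavy-tailed or count-scale
expression distributions, non-normal dependence, time-varying effects,
informative censoring, or a non-constant baseline hazard. Passing the
benchmark studies therefore demonstrates correctness of the machinery
under the stated design, not robustness on real omics data — for real
data, the `cv_filter()`/`center_covariates()` preprocessing and
cross-validated tuning are the intended route.

## Study sizes and reproducibility

The packaged benchmark (`scripts/acceptance.R`, mirrored in the acceptance
tests) runs 20 replicates per censoring level of the independent-design
study at $(n, p, s) = (200, 1000, 10)$ — enough for stable medians while
keeping a full run in the minutes range — and the variational-vs-exact
comparison at $(n, p, s) = (150, 100, 5)$, where the sampler mixes well.
Every stochastic step (simulation, Monte-Carlo summaries, fold splits,
chains) takes an explicit seed, and the coordinate sweep itself is
deterministic, so identical inputs give bit-identical fits.

## Known limitations

* Mean-field factorization discards posterior dependence between
  coefficients (e.g. joint-selection structure among correlated features),
  and variational posteriors underestimate marginal variances — visible in
  the benchmark as credible-set coverage for nonzero coefficients below
  nominal (around 0.7–0.85 at level 0.95) with sets noticeably narrower
  than the exact posterior's.
* The surrogate objective is a bound, not the KL itself; CAVI converges to
  a local optimum and inherits sensitivity to initialization.
* Ties are handled by the literal risk-set definition (adequate for
  continuous times; heavy discrete ties would call for Efron weighting,
  which is out of scope).
* Left truncation, competing risks, time-varying covariates and
  survival-function prediction (which would require a baseline-hazard
  estimate) are out of scope.
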