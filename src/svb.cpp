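// Core numerics for sparse variational Bayes in the proportional hazards
// model: coordinate-ascent updates on the surrogate variational objective,
// and a Metropolis-within-Gibbs reference sampler for the exact posterior.
//
// All risk-set sums are computed as suffix log-sum-exps over subjects sorted
// by increasing time; callers pass 0-based event positions and, per event,
// the first sorted index belonging to its risk set (ties t_r >= t_i kept).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Brent's derivative-free 1-D minimizer on [ax, bx] (golden-section with
// successive parabolic interpolation; Brent 1973)
static double brent_fmin(double ax, double bx,
                         double (*f)(double, void*), void* info, double tol) {
  const double c = (3.0 - std::sqrt(5.0)) * 0.5;
  const double eps = std::sqrt(DBL_EPSILON);
  double a = ax, b = bx;
  double v = a + c * (b - a), w = v, x = v;
  double d = 0.0, e = 0.0;
  double fx = f(x, info), fv = fx, fw = fx;
  const double tol3 = tol / 3.0;
  for (;;) {
    double xm = (a + b) * 0.5;
    double tol1 = eps * std::fabs(x) + tol3;
    double t2 = tol1 * 2.0;
    if (std::fabs(x - xm) <= t2 - (b - a) * 0.5) break;
    double p = 0.0, q = 0.0, r = 0.0;
    if (std::fabs(e) > tol1) {  // fit parabola
      r = (x - w) * (fx - fv);
      q = (x - v) * (fx - fw);
      p = (x - v) * q - (x - w) * r;
      q = (q - r) * 2.0;
      if (q > 0.0) p = -p; else q = -q;
      r = e; e = d;
    }
    if (std::fabs(p) >= std::fabs(q * 0.5 * r) ||
        p <= q * (a - x) || p >= q * (b - x)) {  // golden-section step
      e = (x < xm) ? b - x : a - x;
      d = c * e;
    } else {  // parabolic step
      d = p / q;
      double u = x + d;
      if (u - a < t2 || b - u < t2) d = (x < xm) ? tol1 : -tol1;
    }
    double u = (std::fabs(d) >= tol1) ? x + d
               : (d > 0.0 ? x + tol1 : x - tol1);
    double fu = f(u, info);
    if (fu <= fx) {
      if (u < x) b = x; else a = x;
      v = w; w = x; x = u;
      fv = fw; fw = fx; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu <= fw || w == x) {
        v = w; fv = fw; w = u; fw = fu;
      } else if (fu <= fv || v == x || v == w) {
        v = u; fv = fu;
      }
    }
  }
  return x;
}

static const double GAMMA_EPS = 1e-12;

static inline double logaddexp(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

static inline double clamp_gamma(double g) {
  if (g < GAMMA_EPS) return GAMMA_EPS;
  if (g > 1.0 - GAMMA_EPS) return 1.0 - GAMMA_EPS;
  return g;
}

// log M(x; mu, s) = mu x + s^2 x^2 / 2, the log-MGF of the Normal slab at x
static inline double log_mgf(double x, double mu, double s) {
  return mu * x + 0.5 * s * s * x * x;
}

// E|beta| for beta ~ N(mu, s^2) (folded-normal mean)
static inline double e_abs_norm(double mu, double s) {
  return s * std::sqrt(2.0 / M_PI) * std::exp(-mu * mu / (2.0 * s * s)) +
    mu * (1.0 - 2.0 * R::pnorm(-mu / s, 0.0, 1.0, 1, 0));
}

// log factor gamma * M + (1 - gamma), computed in log space
static inline double log_factor(double x, double mu, double s, double lg, double l1g) {
  return logaddexp(lg + log_mgf(x, mu, s), l1g);
}

struct CoordCtx {
  int n, ne;
  const double* xj;    // covariate column j, sorted by time
  const double* base;  // log P_j per subject (product over k != j)
  const int* rs;       // first risk-set index per event
  double lam;
  double mu_fix, sig_fix;
  double sum_x_ev;     // sum over events of x_ij
  std::vector<double>* suf;
};

// sum over events of log sum_{r in R(t_i)} M(x_rj; mu, s) P_j(x_r);
// mu = s = 0 gives the same sum with M omitted
static double event_lse(const CoordCtx& c, double mu, double s) {
  std::vector<double>& suf = *c.suf;
  double run_max = R_NegInf, run_sum = 0.0;
  for (int r = c.n - 1; r >= 0; --r) {
    double a = log_mgf(c.xj[r], mu, s) + c.base[r];
    if (a > run_max) {
      run_sum = run_sum * std::exp(run_max - a) + 1.0;
      run_max = a;
    } else {
      run_sum += std::exp(a - run_max);
    }
    suf[r] = run_max + std::log(run_sum);
  }
  double tot = 0.0;
  for (int k = 0; k < c.ne; ++k) tot += suf[c.rs[k]];
  return tot;
}

// printed coordinate objective for mu_j (slab forced on)
static double f_obj(double mu, void* p) {
  CoordCtx* c = static_cast<CoordCtx*>(p);
  return event_lse(*c, mu, c->sig_fix) - mu * c->sum_x_ev +
    c->lam * e_abs_norm(mu, c->sig_fix);
}

// printed coordinate objective for sigma_j, parameterized on the log scale
static double g_obj_log(double u, void* p) {
  CoordCtx* c = static_cast<CoordCtx*>(p);
  double s = std::exp(u);
  return event_lse(*c, c->mu_fix, s) + c->lam * e_abs_norm(c->mu_fix, s) -
    std::log(s);
}

// Brent over a bracket centred at the current value (width 10), expanded up
// to three times when the minimizer lands on a bracket edge
static double brent_mu(CoordCtx* c, double mu_cur, double tol) {
  double half = 5.0, centre = mu_cur, res = mu_cur;
  for (int k = 0; k <= 3; ++k) {
    double lo = centre - half, hi = centre + half;
    res = brent_fmin(lo, hi, f_obj, c, tol);
    double edge = 1e-3 * (hi - lo);
    if (res > lo + edge && res < hi - edge) break;
    centre = res;
    half *= 2.0;
  }
  return res;
}

static double brent_sigma(CoordCtx* c, double tol) {
  double u = brent_fmin(std::log(1e-4), std::log(10.0), g_obj_log, c, tol);
  return std::exp(u);
}

static double zeta_value(CoordCtx* c, double mu, double s,
                         double lam, double a0, double b0) {
  double lse_m = event_lse(*c, mu, s);
  double lse_0 = event_lse(*c, 0.0, 0.0);
  return std::log(a0 / b0) -
    (lam * e_abs_norm(mu, s) + (lse_m - lse_0 - mu * c->sum_x_ev)) +
    std::log(std::sqrt(2.0 * M_PI) * s / lam) + 0.5;
}

// fill W (row log-products) and the full log-factor matrix LF (column-major)
static void fill_cache(const NumericMatrix& X,
                       const std::vector<double>& mu,
                       const std::vector<double>& sig,
                       const std::vector<double>& gam,
                       std::vector<double>& LF, std::vector<double>& W) {
  int n = X.nrow(), p = X.ncol();
  std::fill(W.begin(), W.end(), 0.0);
  for (int j = 0; j < p; ++j) {
    double* col = &LF[static_cast<size_t>(j) * n];
    const double* xj = &X(0, j);
    double lg = std::log(gam[j]), l1g = std::log1p(-gam[j]);
    for (int r = 0; r < n; ++r) {
      col[r] = log_factor(xj[r], mu[j], sig[j], lg, l1g);
      W[r] += col[r];
    }
  }
}

// [[Rcpp::export]]
List cavi_cpp(NumericMatrix X, IntegerVector ev, IntegerVector rs,
              double lam, double a0, double b0,
              NumericVector mu0, NumericVector sigma0, NumericVector gamma0,
              double tol, int max_iter, double brent_tol, bool instrument) {
  int n = X.nrow(), p = X.ncol(), ne = ev.size();
  std::vector<double> mu(mu0.begin(), mu0.end());
  std::vector<double> sig(sigma0.begin(), sigma0.end());
  std::vector<double> gam(gamma0.begin(), gamma0.end());
  for (int j = 0; j < p; ++j) gam[j] = clamp_gamma(gam[j]);

  std::vector<double> LF(static_cast<size_t>(n) * p), W(n), base(n), suf(n);
  std::vector<double> traj;
  double max_f_inc = 0.0, max_g_inc = 0.0;
  int n_safeguard = 0;
  bool converged = false;

  for (int it = 1; it <= max_iter; ++it) {
    // full cache recomputation every sweep guards against drift from the
    // incremental column refreshes below
    fill_cache(X, mu, sig, gam, LF, W);
    double delta = 0.0;
    for (int j = 0; j < p; ++j) {
      double* col = &LF[static_cast<size_t>(j) * n];
      const double* xj = &X(0, j);
      double sx = 0.0;
      for (int k = 0; k < ne; ++k) sx += xj[ev[k]];
      for (int r = 0; r < n; ++r) base[r] = W[r] - col[r];
      CoordCtx c = {n, ne, xj, base.data(), rs.begin(), lam,
                    mu[j], sig[j], sx, &suf};

      double f_old = f_obj(mu[j], &c);
      double mu_new = brent_mu(&c, mu[j], brent_tol);
      double f_new = f_obj(mu_new, &c);
      if (instrument && f_new - f_old > max_f_inc) max_f_inc = f_new - f_old;
      if (f_new > f_old) { mu_new = mu[j]; ++n_safeguard; }
      delta += std::fabs(mu_new - mu[j]);
      mu[j] = mu_new;
      c.mu_fix = mu_new;

      double g_old = g_obj_log(std::log(sig[j]), &c);
      double sig_new = brent_sigma(&c, brent_tol);
      double g_new = g_obj_log(std::log(sig_new), &c);
      if (instrument && g_new - g_old > max_g_inc) max_g_inc = g_new - g_old;
      if (g_new > g_old) { sig_new = sig[j]; ++n_safeguard; }
      delta += std::fabs(sig_new - sig[j]);
      sig[j] = sig_new;
      c.sig_fix = sig_new;

      double zeta = zeta_value(&c, mu[j], sig[j], lam, a0, b0);
      double gam_new = clamp_gamma(1.0 / (1.0 + std::exp(-zeta)));
      delta += std::fabs(gam_new - gam[j]);
      gam[j] = gam_new;

      // refresh column j and the row products
      double lg = std::log(gam[j]), l1g = std::log1p(-gam[j]);
      for (int r = 0; r < n; ++r) {
        double lf = log_factor(xj[r], mu[j], sig[j], lg, l1g);
        W[r] += lf - col[r];
        col[r] = lf;
      }
    }
    traj.push_back(delta);
    if (delta < tol) { converged = true; break; }
  }

  return List::create(
    _["mu"] = NumericVector(mu.begin(), mu.end()),
    _["sigma"] = NumericVector(sig.begin(), sig.end()),
    _["gamma"] = NumericVector(gam.begin(), gam.end()),
    _["converged"] = converged,
    _["n_iter"] = static_cast<int>(traj.size()),
    _["trajectory"] = NumericVector(traj.begin(), traj.end()),
    _["max_f_increase"] = max_f_inc,
    _["max_g_increase"] = max_g_inc,
    _["n_safeguard"] = n_safeguard);
}

// Evaluate the printed per-coordinate quantities at given points.
// what: 0 -> f(mu_j = at), 1 -> g(sigma_j = at), 2 -> zeta (at ignored).
// [[Rcpp::export]]
NumericVector coord_objective_cpp(NumericMatrix X, IntegerVector ev,
                                  IntegerVector rs,
                                  NumericVector mu, NumericVector sigma,
                                  NumericVector gamma,
                                  double lam, double a0, double b0,
                                  int j, int what, NumericVector at) {
  int n = X.nrow(), p = X.ncol(), ne = ev.size();
  std::vector<double> muv(mu.begin(), mu.end());
  std::vector<double> sgv(sigma.begin(), sigma.end());
  std::vector<double> gmv(gamma.begin(), gamma.end());
  for (int k = 0; k < p; ++k) gmv[k] = clamp_gamma(gmv[k]);
  std::vector<double> LF(static_cast<size_t>(n) * p), W(n), base(n), suf(n);
  fill_cache(X, muv, sgv, gmv, LF, W);
  const double* col = &LF[static_cast<size_t>(j) * n];
  const double* xj = &X(0, j);
  double sx = 0.0;
  for (int k = 0; k < ne; ++k) sx += xj[ev[k]];
  for (int r = 0; r < n; ++r) base[r] = W[r] - col[r];
  CoordCtx c = {n, ne, xj, base.data(), rs.begin(), lam,
                muv[j], sgv[j], sx, &suf};
  if (what == 2) {
    return NumericVector::create(zeta_value(&c, muv[j], sgv[j], lam, a0, b0));
  }
  int m = at.size();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    out[i] = (what == 0) ? f_obj(at[i], &c) : g_obj_log(std::log(at[i]), &c);
  }
  return out;
}

// Single-coordinate update (what: 0 mu, 1 sigma, 2 gamma); returns the
// updated value together with the objective before/after for the 1-D moves.
// [[Rcpp::export]]
List coord_update_cpp(NumericMatrix X, IntegerVector ev, IntegerVector rs,
                      NumericVector mu, NumericVector sigma,
                      NumericVector gamma,
                      double lam, double a0, double b0,
                      int j, int what, double brent_tol) {
  int n = X.nrow(), p = X.ncol(), ne = ev.size();
  std::vector<double> muv(mu.begin(), mu.end());
  std::vector<double> sgv(sigma.begin(), sigma.end());
  std::vector<double> gmv(gamma.begin(), gamma.end());
  for (int k = 0; k < p; ++k) gmv[k] = clamp_gamma(gmv[k]);
  std::vector<double> LF(static_cast<size_t>(n) * p), W(n), base(n), suf(n);
  fill_cache(X, muv, sgv, gmv, LF, W);
  const double* col = &LF[static_cast<size_t>(j) * n];
  const double* xj = &X(0, j);
  double sx = 0.0;
  for (int k = 0; k < ne; ++k) sx += xj[ev[k]];
  for (int r = 0; r < n; ++r) base[r] = W[r] - col[r];
  CoordCtx c = {n, ne, xj, base.data(), rs.begin(), lam,
                muv[j], sgv[j], sx, &suf};
  double value = NA_REAL, obj_old = NA_REAL, obj_new = NA_REAL;
  bool kept_previous = false;
  if (what == 0) {
    obj_old = f_obj(muv[j], &c);
    value = brent_mu(&c, muv[j], brent_tol);
    obj_new = f_obj(value, &c);
    if (obj_new > obj_old) { value = muv[j]; obj_new = obj_old; kept_previous = true; }
  } else if (what == 1) {
    obj_old = g_obj_log(std::log(sgv[j]), &c);
    value = brent_sigma(&c, brent_tol);
    obj_new = g_obj_log(std::log(value), &c);
    if (obj_new > obj_old) { value = sgv[j]; obj_new = obj_old; kept_previous = true; }
  } else {
    double zeta = zeta_value(&c, muv[j], sgv[j], lam, a0, b0);
    value = clamp_gamma(1.0 / (1.0 + std::exp(-zeta)));
    obj_old = zeta;  // report zeta for the gamma move
    obj_new = zeta;
  }
  return List::create(_["value"] = value, _["objective_before"] = obj_old,
                      _["objective_after"] = obj_new,
                      _["kept_previous"] = kept_previous);
}

// log Cox partial likelihood from a linear predictor over sorted subjects
static double lp_from_eta(const std::vector<double>& eta, const int* ev,
                          const int* rs, int ne, int n,
                          std::vector<double>& suf) {
  if (ne == 0) return 0.0;
  double run_max = R_NegInf, run_sum = 0.0;
  for (int r = n - 1; r >= 0; --r) {
    double a = eta[r];
    if (a > run_max) {
      run_sum = run_sum * std::exp(run_max - a) + 1.0;
      run_max = a;
    } else {
      run_sum += std::exp(a - run_max);
    }
    suf[r] = run_max + std::log(run_sum);
  }
  double v = 0.0;
  for (int k = 0; k < ne; ++k) v += eta[ev[k]] - suf[rs[k]];
  return v;
}

// Metropolis-within-Gibbs for the exact spike-and-slab posterior with the
// per-coordinate Beta hyperpriors marginalized to Bernoulli(a0/(a0+b0)).
// Moves per coordinate: add (Laplace-slab proposal), delete, random walk.
// [[Rcpp::export]]
List mcmc_cpp(NumericMatrix X, IntegerVector ev, IntegerVector rs,
              double lam, double log_prior_odds,
              int n_iter, int burn_in, double init_scale, double target_acc) {
  int n = X.nrow(), p = X.ncol(), ne = ev.size();
  std::vector<double> beta(p, 0.0), eta(n, 0.0), eta_prop(n), suf(n);
  std::vector<int> z(p, 0);
  std::vector<double> ls(p, std::log(init_scale));
  int keep = n_iter - burn_in;
  NumericMatrix draws(p, keep);
  double lp = lp_from_eta(eta, ev.begin(), rs.begin(), ne, n, suf);
  long acc_add = 0, try_add = 0, acc_del = 0, try_del = 0;
  long acc_rw = 0, try_rw = 0;

  for (int t = 1; t <= n_iter; ++t) {
    for (int j = 0; j < p; ++j) {
      const double* xj = &X(0, j);
      double u = unif_rand();
      if (z[j] == 0) {
        if (u < 0.5) {  // add move, proposal = Laplace slab
          double v = unif_rand() - 0.5;
          double sgn = (v > 0) - (v < 0);
          double b = -sgn * std::log(1.0 - 2.0 * std::fabs(v)) / lam;
          for (int r = 0; r < n; ++r) eta_prop[r] = eta[r] + b * xj[r];
          double lp_new = lp_from_eta(eta_prop, ev.begin(), rs.begin(), ne, n, suf);
          double la = lp_new - lp + log_prior_odds;
          if (t > burn_in) ++try_add;
          if (std::log(unif_rand()) < la) {
            z[j] = 1; beta[j] = b; eta.swap(eta_prop); lp = lp_new;
            if (t > burn_in) ++acc_add;
          }
        }
      } else if (u < 0.5) {  // delete move
        for (int r = 0; r < n; ++r) eta_prop[r] = eta[r] - beta[j] * xj[r];
        double lp_new = lp_from_eta(eta_prop, ev.begin(), rs.begin(), ne, n, suf);
        double la = lp_new - lp - log_prior_odds;
        if (t > burn_in) ++try_del;
        if (std::log(unif_rand()) < la) {
          z[j] = 0; beta[j] = 0.0; eta.swap(eta_prop); lp = lp_new;
          if (t > burn_in) ++acc_del;
        }
      } else {  // random walk on the active coefficient
        double step = std::exp(ls[j]) * norm_rand();
        double b = beta[j] + step;
        for (int r = 0; r < n; ++r) eta_prop[r] = eta[r] + step * xj[r];
        double lp_new = lp_from_eta(eta_prop, ev.begin(), rs.begin(), ne, n, suf);
        double la = lp_new - lp - lam * (std::fabs(b) - std::fabs(beta[j]));
        double alpha = la >= 0 ? 1.0 : std::exp(la);
        if (t > burn_in) ++try_rw;
        if (std::log(unif_rand()) < la) {
          beta[j] = b; eta.swap(eta_prop); lp = lp_new;
          if (t > burn_in) ++acc_rw;
        }
        if (t <= burn_in) {  // adaptation frozen after burn-in
          double gain = std::min(0.5, 2.0 / std::sqrt(static_cast<double>(t)));
          ls[j] += gain * (alpha - target_acc);
        }
      }
    }
    if (t > burn_in) {
      for (int j = 0; j < p; ++j) draws(j, t - burn_in - 1) = beta[j];
    }
  }

  return List::create(
    _["draws"] = draws,
    _["acceptance"] = NumericVector::create(
      _["add"] = try_add > 0 ? static_cast<double>(acc_add) / try_add : NA_REAL,
      _["delete"] = try_del > 0 ? static_cast<double>(acc_del) / try_del : NA_REAL,
      _["rw"] = try_rw > 0 ? static_cast<double>(acc_rw) / try_rw : NA_REAL),
    _["rw_scale"] = NumericVector(ls.begin(), ls.end()));
}
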