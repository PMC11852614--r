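#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <limits>

using namespace Rcpp;

// Sentinel returned when a candidate weight vector yields a non-finite loss;
// large but far from overflow so the simplex can still rank such points.
static const double LOSS_SENTINEL = 1e300;
// Floor applied to action probabilities before taking logs.
static const double PROB_FLOOR = 1e-300;

struct LossSpec {
  std::vector<double> hs;  // remembered stimuli
  std::vector<int> ha;     // remembered actions (1..na)
  std::vector<double> hr;  // remembered rewards (sampled reward-loss variant)
  int na;
  double sigma_a;
  double alpha, beta;
  double lambda;
  int reward_form;     // 0 = product alpha*(a-beta)*s, 1 = additive alpha*a+beta*s
  int reward_agg;      // 0 = mean over history, 1 = sum
  int reward_sampled;  // 0 = analytic expected reward, 1 = recorded rewards
};

static inline double reward_mean_c(const LossSpec& sp, int a, double s) {
  if (sp.reward_form == 0) return sp.alpha * (a - sp.beta) * s;
  return sp.alpha * a + sp.beta * s;
}

// Action pmf at stimulus s under weights w: the unnormalized mixture
// density evaluated at the integer action locations, renormalized.
// Returns false (policy collapse) when the density underflows at every
// action or a component mean is non-finite; the caller turns that into a
// sentinel loss so the simplex can retreat. The underflow boundary is a
// real part of the model's dynamics: it caps how deterministic the
// policy can become over the remembered stimuli.
static bool action_pmf_c(const double* w, int nw, double s, double sigma_a,
                         int na, std::vector<double>& p) {
  const double inv2s2 = 1.0 / (2.0 * sigma_a * sigma_a);
  double norm = 0.0;
  for (int a = 1; a <= na; ++a) {
    double d = 0.0;
    for (int i = 0; i < nw; ++i) {
      double m = w[2 * i] + w[2 * i + 1] * s;
      if (!std::isfinite(m)) return false;
      d += std::exp(-(a - m) * (a - m) * inv2s2);
    }
    p[a - 1] = d;
    norm += d;
  }
  if (norm == 0.0 || !std::isfinite(norm)) return false;
  for (int a = 0; a < na; ++a) p[a] /= norm;
  return true;
}

// Full loss breakdown; out = {l_a, l_r, l_lambda}.
static bool loss_eval(const LossSpec& sp, const double* w, int nw,
                      double* out) {
  const int n = (int)sp.hs.size();
  std::vector<double> p(sp.na);
  double la = 0.0, lr_acc = 0.0;
  for (int j = 0; j < n; ++j) {
    if (!action_pmf_c(w, nw, sp.hs[j], sp.sigma_a, sp.na, p)) return false;
    double pa = p[sp.ha[j] - 1];
    if (pa < PROB_FLOOR) pa = PROB_FLOOR;
    la += -std::log(pa);
    if (sp.reward_sampled) {
      lr_acc += p[sp.ha[j] - 1] * sp.hr[j];
    } else {
      double er = 0.0;
      for (int a = 1; a <= sp.na; ++a)
        er += p[a - 1] * reward_mean_c(sp, a, sp.hs[j]);
      lr_acc += er;
    }
  }
  double lr = -(sp.reward_agg == 0 ? lr_acc / n : lr_acc);
  double ll = sp.lambda * lr + (1.0 - sp.lambda) * la;
  if (!std::isfinite(la) || !std::isfinite(lr) || !std::isfinite(ll))
    return false;
  out[0] = la;
  out[1] = lr;
  out[2] = ll;
  return true;
}

static double objective(const LossSpec& sp, const double* w, int nw) {
  double out[3];
  if (!loss_eval(sp, w, nw, out)) return LOSS_SENTINEL;
  return out[2];
}

static LossSpec make_spec(const NumericVector& hs, const IntegerVector& ha,
                          const NumericVector& hr, int na, double sigma_a,
                          double alpha, double beta, double lambda,
                          int reward_form, int reward_agg, int reward_sampled) {
  LossSpec sp;
  sp.hs = as<std::vector<double> >(hs);
  sp.ha = as<std::vector<int> >(ha);
  sp.hr = as<std::vector<double> >(hr);
  sp.na = na;
  sp.sigma_a = sigma_a;
  sp.alpha = alpha;
  sp.beta = beta;
  sp.lambda = lambda;
  sp.reward_form = reward_form;
  sp.reward_agg = reward_agg;
  sp.reward_sampled = reward_sampled;
  return sp;
}

// [[Rcpp::export]]
NumericVector cpp_loss(NumericVector w, NumericVector hs, IntegerVector ha,
                       NumericVector hr, int na, double sigma_a, double alpha,
                       double beta, double lambda, int reward_form,
                       int reward_agg, int reward_sampled) {
  LossSpec sp = make_spec(hs, ha, hr, na, sigma_a, alpha, beta, lambda,
                          reward_form, reward_agg, reward_sampled);
  int nw = w.size() / 2;
  double out[3];
  if (!loss_eval(sp, &w[0], nw, out)) {
    return NumericVector::create(LOSS_SENTINEL, LOSS_SENTINEL, LOSS_SENTINEL);
  }
  return NumericVector::create(out[0], out[1], out[2]);
}

// Nelder-Mead with the Lagarias et al. coefficients (reflection 1,
// expansion 2, contraction 0.5, shrink 0.5), the dual termination test on
// simplex f-spread and x-spread, and an initial simplex that perturbs each
// coordinate by 5% (zero coordinates by an absolute zero_delta: a
// near-degenerate perturbation there elongates the simplex along the other
// coordinates and can permanently stall the zeroed direction).
struct NMResult {
  std::vector<double> x;
  double f;
  int iter;
  bool converged;
};

static NMResult nelder_mead(const LossSpec& sp, const std::vector<double>& x0,
                            int maxit, double xtol, double ftol,
                            double zero_delta) {
  const int n = (int)x0.size();
  const int nw = n / 2;
  const double rho = 1.0, chi = 2.0, psi = 0.5, sigma = 0.5;

  std::vector<std::vector<double> > X(n + 1, x0);
  std::vector<double> F(n + 1);
  for (int i = 0; i < n; ++i) {
    if (X[i + 1][i] != 0.0)
      X[i + 1][i] *= 1.05;
    else
      X[i + 1][i] = zero_delta;
  }
  for (int i = 0; i <= n; ++i) F[i] = objective(sp, X[i].data(), nw);

  std::vector<int> ord(n + 1);
  std::vector<double> c(n), xr(n), xe(n), xc(n);
  int iter = 0;
  bool converged = false;

  while (iter < maxit) {
    for (int i = 0; i <= n; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(),
              [&F](int a, int b) { return F[a] < F[b]; });
    {
      std::vector<std::vector<double> > X2(n + 1);
      std::vector<double> F2(n + 1);
      for (int i = 0; i <= n; ++i) {
        X2[i] = X[ord[i]];
        F2[i] = F[ord[i]];
      }
      X.swap(X2);
      F.swap(F2);
    }

    double fspread = 0.0, xspread = 0.0;
    for (int i = 1; i <= n; ++i) {
      fspread = std::max(fspread, std::fabs(F[i] - F[0]));
      for (int k = 0; k < n; ++k)
        xspread = std::max(xspread, std::fabs(X[i][k] - X[0][k]));
    }
    if (fspread <= ftol && xspread <= xtol) {
      converged = true;
      break;
    }

    ++iter;
    for (int k = 0; k < n; ++k) {
      double acc = 0.0;
      for (int i = 0; i < n; ++i) acc += X[i][k];
      c[k] = acc / n;
    }
    for (int k = 0; k < n; ++k) xr[k] = c[k] + rho * (c[k] - X[n][k]);
    double fr = objective(sp, xr.data(), nw);

    if (fr < F[0]) {
      for (int k = 0; k < n; ++k) xe[k] = c[k] + rho * chi * (c[k] - X[n][k]);
      double fe = objective(sp, xe.data(), nw);
      if (fe < fr) {
        X[n] = xe;
        F[n] = fe;
      } else {
        X[n] = xr;
        F[n] = fr;
      }
    } else if (fr < F[n - 1]) {
      X[n] = xr;
      F[n] = fr;
    } else {
      bool shrink = false;
      if (fr < F[n]) {
        for (int k = 0; k < n; ++k)
          xc[k] = c[k] + psi * rho * (c[k] - X[n][k]);
        double fc = objective(sp, xc.data(), nw);
        if (fc <= fr) {
          X[n] = xc;
          F[n] = fc;
        } else {
          shrink = true;
        }
      } else {
        for (int k = 0; k < n; ++k) xc[k] = c[k] - psi * (c[k] - X[n][k]);
        double fc = objective(sp, xc.data(), nw);
        if (fc < F[n]) {
          X[n] = xc;
          F[n] = fc;
        } else {
          shrink = true;
        }
      }
      if (shrink) {
        for (int i = 1; i <= n; ++i) {
          for (int k = 0; k < n; ++k)
            X[i][k] = X[0][k] + sigma * (X[i][k] - X[0][k]);
          F[i] = objective(sp, X[i].data(), nw);
        }
      }
    }
  }

  int best = 0;
  for (int i = 1; i <= n; ++i)
    if (F[i] < F[best]) best = i;
  NMResult res;
  res.x = X[best];
  res.f = F[best];
  res.iter = iter;
  res.converged = converged;
  return res;
}

// [[Rcpp::export]]
List cpp_minimize(NumericVector w0, NumericVector hs, IntegerVector ha,
                  NumericVector hr, int na, double sigma_a, double alpha,
                  double beta, double lambda, int reward_form, int reward_agg,
                  int reward_sampled, int maxit, double xtol, double ftol,
                  int restarts, double zero_delta) {
  LossSpec sp = make_spec(hs, ha, hr, na, sigma_a, alpha, beta, lambda,
                          reward_form, reward_agg, reward_sampled);
  const int n = w0.size();
  const int nw = n / 2;
  std::vector<double> x0 = as<std::vector<double> >(w0);

  double f_init = objective(sp, x0.data(), nw);
  if (f_init >= LOSS_SENTINEL) {
    // non-finite landscape at the warm start: report and leave weights alone
    return List::create(_["weights"] = w0, _["value"] = f_init,
                        _["iterations"] = 0, _["converged"] = false,
                        _["failed"] = true);
  }

  NMResult best = nelder_mead(sp, x0, maxit, xtol, ftol, zero_delta);
  int total_iter = best.iter;
  for (int r = 0; r < restarts; ++r) {
    NMResult again = nelder_mead(sp, best.x, maxit, xtol, ftol, zero_delta);
    total_iter += again.iter;
    if (again.f < best.f) best = again;
  }
  // never return a point worse than the warm start
  if (f_init < best.f) {
    best.x = x0;
    best.f = f_init;
  }

  double out[3] = {NA_REAL, NA_REAL, NA_REAL};
  loss_eval(sp, best.x.data(), nw, out);
  return List::create(
      _["weights"] = NumericVector(best.x.begin(), best.x.end()),
      _["value"] = best.f, _["l_a"] = out[0], _["l_r"] = out[1],
      _["l_lambda"] = out[2], _["iterations"] = total_iter,
      _["converged"] = best.converged, _["failed"] = false);
}
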