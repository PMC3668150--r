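// Stochastic simulation engines for mass-action reaction networks:
//  - exact Gillespie direct-method SSA
//  - explicit tau-leaping with highest-order-of-reaction step control and
//    critical-reaction partitioning (near-exhausted channels fire one at a
//    time), falling back to SSA steps when the leap would be smaller than a
//    few SSA steps.
//
// All randomness comes from R's RNG (set.seed() on the R side controls
// reproducibility). Counts are carried as doubles but remain exact integers.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Net {
  int S, R;
  const int *stoich;      // S x R, column-major net change
  std::vector<int> r1_idx, r1_mult, r2_idx; // reactant encoding (0-based, r2_idx<0 if none)
  const double *c;
};

inline double propensity(const Net &net, const std::vector<double> &x, int j) {
  const double cj = net.c[j];
  const int i1 = net.r1_idx[j];
  if (net.r2_idx[j] >= 0) {
    return cj * x[i1] * x[net.r2_idx[j]];
  }
  if (net.r1_mult[j] == 2) {
    return cj * x[i1] * (x[i1] - 1.0) / 2.0;
  }
  return cj * x[i1];
}

inline void fire(const Net &net, std::vector<double> &x, int j, double k = 1.0) {
  const int *col = net.stoich + (std::size_t)j * net.S;
  for (int i = 0; i < net.S; ++i) {
    if (col[i] != 0) x[i] += k * col[i];
  }
}

// Record the current state for every sample time strictly before t_next
// (piecewise-constant, last-value-before-t interpolation).
inline void record_until(NumericMatrix &out, const std::vector<double> &x,
                         const NumericVector &times, int &k, double t_next) {
  const int K = times.size();
  while (k < K && times[k] < t_next) {
    for (int i = 0; i < (int)x.size(); ++i) out(i, k) = x[i];
    ++k;
  }
}

inline void record_rest(NumericMatrix &out, const std::vector<double> &x,
                        const NumericVector &times, int &k) {
  record_until(out, x, times, k, R_PosInf);
}

// One exact SSA step, allocation-free. Samples falling inside the waiting
// interval are recorded with the pre-event state before the event fires.
// Returns: 1 event fired, 0 system exhausted (a0 <= 0), -1 next event falls
// beyond t_end (state unchanged, t untouched).
inline int ssa_step(const Net &net, std::vector<double> &x, double &t,
                    std::vector<double> &a, double t_end,
                    NumericMatrix &out, const NumericVector &times, int &k) {
  double a0 = 0.0;
  for (int j = 0; j < net.R; ++j) {
    a[j] = propensity(net, x, j);
    a0 += a[j];
  }
  if (a0 <= 0.0) return 0;
  double t_next = t + exp_rand() / a0;
  record_until(out, x, times, k, t_next);
  if (t_next > t_end) return -1;
  double u = unif_rand() * a0;
  int j = 0;
  double cum = a[0];
  while (u > cum && j < net.R - 1) cum += a[++j];
  fire(net, x, j);
  t = t_next;
  return 1;
}

Net make_net(const IntegerMatrix &stoich, const IntegerVector &r1_idx,
             const IntegerVector &r1_mult, const IntegerVector &r2_idx,
             const NumericVector &cvec) {
  Net net;
  net.S = stoich.nrow();
  net.R = stoich.ncol();
  net.stoich = stoich.begin();
  net.r1_idx.assign(r1_idx.begin(), r1_idx.end());
  net.r1_mult.assign(r1_mult.begin(), r1_mult.end());
  net.r2_idx.assign(r2_idx.begin(), r2_idx.end());
  net.c = cvec.begin();
  return net;
}

} // namespace

// [[Rcpp::export]]
NumericMatrix cpp_ssa(NumericVector init, IntegerMatrix stoich,
                      IntegerVector r1_idx, IntegerVector r1_mult,
                      IntegerVector r2_idx, NumericVector cvec,
                      NumericVector sample_times, double t_end,
                      double max_steps) {
  Net net = make_net(stoich, r1_idx, r1_mult, r2_idx, cvec);
  const int S = net.S, R = net.R;
  std::vector<double> x(init.begin(), init.end());
  std::vector<double> a(R);
  NumericMatrix out(S, sample_times.size());

  // sparse firing lists and reaction-dependency graph: after firing j only
  // reactions sharing a changed species need their propensity refreshed
  std::vector<std::vector<int> > fire_idx(R), dep(R);
  std::vector<std::vector<double> > fire_delta(R);
  for (int j = 0; j < R; ++j) {
    const int *col = net.stoich + (std::size_t)j * S;
    for (int i = 0; i < S; ++i) {
      if (col[i] != 0) {
        fire_idx[j].push_back(i);
        fire_delta[j].push_back((double)col[i]);
      }
    }
    for (int jj = 0; jj < R; ++jj) {
      bool uses = false;
      for (std::size_t q = 0; q < fire_idx[j].size() && !uses; ++q) {
        int i = fire_idx[j][q];
        if (net.r1_idx[jj] == i ||
            (net.r2_idx[jj] >= 0 && net.r2_idx[jj] == i)) uses = true;
      }
      if (uses) dep[j].push_back(jj);
    }
  }

  double a0 = 0.0;
  for (int j = 0; j < R; ++j) { a[j] = propensity(net, x, j); a0 += a[j]; }

  double t = 0.0;
  int k = 0;
  double steps = 0.0;
  const double refresh_every = 1048576.0;
  double since_refresh = 0.0;

  while (true) {
    if (a0 <= 1e-300) {
      // confirm exhaustion against drift-free propensities
      a0 = 0.0;
      for (int j = 0; j < R; ++j) { a[j] = propensity(net, x, j); a0 += a[j]; }
      if (a0 <= 0.0) {
        record_rest(out, x, sample_times, k);
        break;
      }
      continue;
    }
    double t_next = t + exp_rand() / a0;
    record_until(out, x, sample_times, k, t_next);
    if (t_next > t_end) {
      record_rest(out, x, sample_times, k);
      break;
    }
    double u = unif_rand() * a0;
    int j = -1;
    double cum = 0.0;
    for (int jj = 0; jj < R; ++jj) {
      if (a[jj] <= 0.0) continue;
      cum += a[jj];
      j = jj;
      if (u <= cum) break;
    }
    if (j < 0) { a0 = 0.0; continue; }  // all cached propensities zero: refresh
    const std::vector<int> &fi = fire_idx[j];
    const std::vector<double> &fd = fire_delta[j];
    for (std::size_t q = 0; q < fi.size(); ++q) x[fi[q]] += fd[q];
    const std::vector<int> &dj = dep[j];
    for (std::size_t q = 0; q < dj.size(); ++q) {
      int jj = dj[q];
      a0 -= a[jj];
      a[jj] = propensity(net, x, jj);
      a0 += a[jj];
    }
    t = t_next;
    if (++steps > max_steps) stop("SSA exceeded max_steps before t_end.");
    if (++since_refresh >= refresh_every) {
      since_refresh = 0.0;
      a0 = 0.0;
      for (int jj = 0; jj < R; ++jj) {
        a[jj] = propensity(net, x, jj);
        a0 += a[jj];
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_tau_leap(NumericVector init, IntegerMatrix stoich,
                  IntegerVector r1_idx, IntegerVector r1_mult,
                  IntegerVector r2_idx, NumericVector cvec,
                  NumericVector sample_times, double t_end,
                  double eps, double n_critical, int ssa_fallback_steps,
                  double fallback_mult, double max_steps) {
  Net net = make_net(stoich, r1_idx, r1_mult, r2_idx, cvec);
  const int S = net.S, R = net.R;
  std::vector<double> x(init.begin(), init.end());
  std::vector<double> a(R), Kfire(R);
  std::vector<bool> critical(R);
  NumericMatrix out(S, sample_times.size());

  // highest order of reaction per species: 1 first-order, 2 second-order
  // distinct, 3 homodimer (g_i = 2 + 1/(x_i - 1))
  std::vector<int> hor(S, 0);
  for (int j = 0; j < R; ++j) {
    int i1 = net.r1_idx[j];
    if (net.r2_idx[j] >= 0) {
      int i2 = net.r2_idx[j];
      if (hor[i1] < 2) hor[i1] = 2;
      if (hor[i2] < 2) hor[i2] = 2;
    } else if (net.r1_mult[j] == 2) {
      hor[i1] = 3;
    } else if (hor[i1] < 1) {
      hor[i1] = 1;
    }
  }

  double t = 0.0;
  int k = 0;
  double steps = 0.0, n_leaps = 0.0, n_ssa = 0.0;

  while (t < t_end) {
    if (++steps > max_steps) stop("tau-leaping exceeded max_steps before t_end.");
    double a0 = 0.0;
    for (int j = 0; j < R; ++j) {
      a[j] = propensity(net, x, j);
      a0 += a[j];
    }
    if (a0 <= 0.0) break;

    // critical partition: reactions within n_critical firings of exhausting
    // one of their reactants
    double a0c = 0.0;
    for (int j = 0; j < R; ++j) {
      critical[j] = false;
      if (a[j] <= 0.0) continue;
      int i1 = net.r1_idx[j];
      double L;
      if (net.r2_idx[j] >= 0) {
        L = std::min(x[i1], x[net.r2_idx[j]]);
      } else if (net.r1_mult[j] == 2) {
        L = std::floor(x[i1] / 2.0);
      } else {
        L = x[i1];
      }
      if (L < n_critical) {
        critical[j] = true;
        a0c += a[j];
      }
    }

    // Cao-Gillespie-Petzold step-size selection over non-critical reactions
    double tau1 = R_PosInf;
    for (int i = 0; i < S; ++i) {
      if (hor[i] == 0) continue;
      double mu = 0.0, sig2 = 0.0;
      for (int j = 0; j < R; ++j) {
        if (critical[j] || a[j] <= 0.0) continue;
        int v = net.stoich[(std::size_t)j * S + i];
        if (v != 0) {
          mu += v * a[j];
          sig2 += (double)v * v * a[j];
        }
      }
      if (mu == 0.0 && sig2 == 0.0) continue;
      double g;
      if (hor[i] == 1) g = 1.0;
      else if (hor[i] == 2) g = 2.0;
      else g = (x[i] > 1.0) ? 2.0 + 1.0 / (x[i] - 1.0) : 3.0;
      double bound = std::max(eps * x[i] / g, 1.0);
      if (mu != 0.0) tau1 = std::min(tau1, bound / std::fabs(mu));
      if (sig2 > 0.0) tau1 = std::min(tau1, bound * bound / sig2);
    }

    // leap smaller than a few SSA steps: take exact steps instead (the
    // expected time to the next critical event counts as part of the leap)
    double crit_mean = (a0c > 0.0) ? 1.0 / a0c : R_PosInf;
    if (!(std::min(tau1, crit_mean) > fallback_mult / a0)) {
      for (int s = 0; s < ssa_fallback_steps && t < t_end; ++s) {
        int rc = ssa_step(net, x, t, a, t_end, out, sample_times, k);
        if (rc <= 0) { t = t_end; break; }
        n_ssa += 1.0;
      }
      continue;
    }

    double tau2 = (a0c > 0.0) ? exp_rand() / a0c : R_PosInf;
    bool fire_critical = (tau2 <= tau1);
    double tau = std::min(fire_critical ? tau2 : tau1, t_end - t);
    if (tau >= t_end - t) fire_critical = fire_critical && (tau2 <= t_end - t);

    int crit_j = -1;
    if (fire_critical) {
      double u = unif_rand() * a0c, cum = 0.0;
      for (int j = 0; j < R; ++j) {
        if (!critical[j]) continue;
        cum += a[j];
        crit_j = j;
        if (u <= cum) break;
      }
    }

    // draw firings; halve tau on a would-be-negative leap
    bool ok = false;
    std::vector<double> x_new;
    for (int attempt = 0; attempt < 30 && !ok; ++attempt) {
      x_new = x;
      for (int j = 0; j < R; ++j) {
        if (critical[j] || a[j] <= 0.0) { Kfire[j] = 0.0; continue; }
        Kfire[j] = R::rpois(a[j] * tau);
        if (Kfire[j] > 0.0) fire(net, x_new, j, Kfire[j]);
      }
      if (fire_critical && crit_j >= 0) fire(net, x_new, crit_j);
      ok = true;
      for (int i = 0; i < S; ++i) {
        if (x_new[i] < 0.0) { ok = false; break; }
      }
      if (!ok) {
        tau /= 2.0;
        fire_critical = false; // critical event no longer falls inside the leap
      }
    }
    if (!ok) {
      // pathological: resolve exactly
      int rc = ssa_step(net, x, t, a, t_end, out, sample_times, k);
      if (rc <= 0) break;
      n_ssa += 1.0;
      continue;
    }

    record_until(out, x, sample_times, k, t + tau);
    t += tau;
    x = x_new;
    n_leaps += 1.0;
  }
  record_rest(out, x, sample_times, k);
  return List::create(_["counts"] = out, _["n_leaps"] = n_leaps,
                      _["n_ssa_steps"] = n_ssa);
}
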