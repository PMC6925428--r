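#include <Rcpp.h>
using namespace Rcpp;

// Single-site adaptive random-walk Metropolis with conjugate Gibbs updates
// for the precisions, for the BYM count model and its three-period
// ecological-regression extension. All randomness comes from R's RNG, so
// draws are reproducible under set.seed().

namespace {

// Robbins-Monro style scale adaptation toward a 0.44 acceptance rate,
// applied only during burn-in (batches of 50 sweeps).
inline void adapt(double &log_s, int acc, int batch) {
  double rate = acc / 50.0;
  double step = std::min(0.25, 1.0 / std::sqrt((double)batch));
  log_s += (rate > 0.44 ? step : -step);
  if (log_s < -10.0) log_s = -10.0;
  if (log_s > 5.0) log_s = 5.0;
}

inline double rgamma_rate(double shape, double rate) {
  return R::rgamma(shape, 1.0 / rate);
}

// sum over edges of (u_i - u_j)^2
inline double edge_ss(const NumericVector &u, const IntegerMatrix &edges) {
  double ss = 0.0;
  for (int k = 0; k < edges.nrow(); ++k) {
    double d = u[edges(k, 0)] - u[edges(k, 1)];
    ss += d * d;
  }
  return ss;
}

// Joint rescale of a field and its precision: (w, tau) -> (e^c w, e^-2c tau).
// The Gaussian/ICAR kernel exponent is invariant; collecting the kernel's
// tau^(rank/2) factor, the Gamma(a, b) prior on tau and the Jacobian leaves
// log-acceptance = delta-loglik - 2 a c - b tau (e^-2c - 1). Breaks the slow
// random walk along the scale ridge that single-site updates suffer from.
struct RescaleMove {
  double log_s = std::log(0.2);
  int acc = 0;
};

} // namespace

// [[Rcpp::export(name = ".bym_chain")]]
List bym_chain(IntegerVector O, NumericVector N,
               IntegerVector adj, IntegerVector adj_start,
               IntegerMatrix edges,
               double a_u, double b_u, double a_v, double b_v,
               int n_burn, int n_keep, int thin,
               bool fields,
               double alpha_init) {
  int n = O.size();
  int n_total = n_burn + n_keep * thin;

  NumericVector u(n, 0.0), v(n, 0.0);
  double alpha = alpha_init;
  double tau_u = 50.0, tau_v = 50.0;
  if (fields) {
    for (int i = 0; i < n; ++i) { u[i] = R::rnorm(0.0, 0.05); v[i] = R::rnorm(0.0, 0.05); }
    double m = mean(u);
    for (int i = 0; i < n; ++i) u[i] -= m;
  }

  NumericVector lp(n); // log rate per tract
  for (int i = 0; i < n; ++i) lp[i] = alpha + u[i] + v[i];

  double ls_a = std::log(0.1);
  NumericVector ls_u(n, std::log(0.1)), ls_v(n, std::log(0.1));
  int acc_a = 0; IntegerVector acc_u(n, 0), acc_v(n, 0);
  int batch = 0;
  RescaleMove rs_u, rs_v;

  double sumO = 0.0;
  for (int i = 0; i < n; ++i) sumO += O[i];

  NumericVector out_alpha(n_keep), out_tau_u(n_keep), out_tau_v(n_keep);
  NumericMatrix out_u(n_keep, n), out_v(n_keep, n);

  int kept = 0;
  for (int iter = 1; iter <= n_total; ++iter) {
    bool adapting = iter <= n_burn;

    if (fields) {
      // spatial field: Poisson likelihood x ICAR full conditional
      for (int i = 0; i < n; ++i) {
        double prop = u[i] + std::exp(ls_u[i]) * R::norm_rand();
        double du = prop - u[i];
        double nbsum = 0.0;
        int d_i = adj_start[i + 1] - adj_start[i];
        for (int k = adj_start[i]; k < adj_start[i + 1]; ++k) nbsum += u[adj[k]];
        double lognum = O[i] * du - N[i] * std::exp(lp[i]) * (std::exp(du) - 1.0)
          - 0.5 * tau_u * (d_i * (prop * prop - u[i] * u[i]) - 2.0 * du * nbsum);
        if (std::log(R::unif_rand()) < lognum) {
          u[i] = prop; lp[i] += du;
          if (adapting) ++acc_u[i];
        }
      }
      // identifiability: fold the field mean into the intercept
      double m = mean(u);
      for (int i = 0; i < n; ++i) u[i] -= m;
      alpha += m;

      // heterogeneous field
      for (int i = 0; i < n; ++i) {
        double prop = v[i] + std::exp(ls_v[i]) * R::norm_rand();
        double dv = prop - v[i];
        double lognum = O[i] * dv - N[i] * std::exp(lp[i]) * (std::exp(dv) - 1.0)
          - 0.5 * tau_v * (prop * prop - v[i] * v[i]);
        if (std::log(R::unif_rand()) < lognum) {
          v[i] = prop; lp[i] += dv;
          if (adapting) ++acc_v[i];
        }
      }
    }

    // intercept (flat prior)
    {
      double da = std::exp(ls_a) * R::norm_rand();
      double sumMu = 0.0;
      for (int i = 0; i < n; ++i) sumMu += N[i] * std::exp(lp[i]);
      double lognum = sumO * da - sumMu * (std::exp(da) - 1.0);
      if (std::log(R::unif_rand()) < lognum) {
        alpha += da;
        for (int i = 0; i < n; ++i) lp[i] += da;
        if (adapting) ++acc_a;
      }
    }

    // conjugate precision updates (prior draws when the fields are disabled)
    if (fields) {
      tau_u = rgamma_rate(a_u + 0.5 * (n - 1), b_u + 0.5 * edge_ss(u, edges));
      double ssv = 0.0;
      for (int i = 0; i < n; ++i) ssv += v[i] * v[i];
      tau_v = rgamma_rate(a_v + 0.5 * n, b_v + 0.5 * ssv);

      // joint (u, tau_u) rescale
      {
        double c = std::exp(rs_u.log_s) * R::norm_rand();
        double g = std::exp(c) - 1.0;
        double lognum = -2.0 * a_u * c - b_u * tau_u * (std::exp(-2.0 * c) - 1.0);
        for (int i = 0; i < n; ++i) {
          double du = g * u[i];
          lognum += O[i] * du - N[i] * std::exp(lp[i]) * (std::exp(du) - 1.0);
        }
        if (std::log(R::unif_rand()) < lognum) {
          for (int i = 0; i < n; ++i) { lp[i] += g * u[i]; u[i] *= std::exp(c); }
          tau_u *= std::exp(-2.0 * c);
          if (adapting) ++rs_u.acc;
        }
      }
      // joint (v, tau_v) rescale
      {
        double c = std::exp(rs_v.log_s) * R::norm_rand();
        double g = std::exp(c) - 1.0;
        double lognum = -2.0 * a_v * c - b_v * tau_v * (std::exp(-2.0 * c) - 1.0);
        for (int i = 0; i < n; ++i) {
          double dv = g * v[i];
          lognum += O[i] * dv - N[i] * std::exp(lp[i]) * (std::exp(dv) - 1.0);
        }
        if (std::log(R::unif_rand()) < lognum) {
          for (int i = 0; i < n; ++i) { lp[i] += g * v[i]; v[i] *= std::exp(c); }
          tau_v *= std::exp(-2.0 * c);
          if (adapting) ++rs_v.acc;
        }
      }
    } else {
      tau_u = rgamma_rate(a_u, b_u);
      tau_v = rgamma_rate(a_v, b_v);
    }

    if (adapting && iter % 50 == 0) {
      ++batch;
      adapt(ls_a, acc_a, batch); acc_a = 0;
      adapt(rs_u.log_s, rs_u.acc, batch); rs_u.acc = 0;
      adapt(rs_v.log_s, rs_v.acc, batch); rs_v.acc = 0;
      for (int i = 0; i < n; ++i) {
        adapt(ls_u[i], acc_u[i], batch); acc_u[i] = 0;
        adapt(ls_v[i], acc_v[i], batch); acc_v[i] = 0;
      }
    }

    if (iter > n_burn && (iter - n_burn) % thin == 0) {
      out_alpha[kept] = alpha;
      out_tau_u[kept] = tau_u;
      out_tau_v[kept] = tau_v;
      for (int i = 0; i < n; ++i) { out_u(kept, i) = u[i]; out_v(kept, i) = v[i]; }
      ++kept;
    }
  }

  return List::create(_["alpha"] = out_alpha, _["tau_u"] = out_tau_u,
                      _["tau_v"] = out_tau_v, _["u"] = out_u, _["v"] = out_v);
}

// [[Rcpp::export(name = ".eco_chain")]]
List eco_chain(IntegerMatrix O, NumericMatrix N, NumericVector x,
               IntegerVector adj, IntegerVector adj_start,
               IntegerMatrix edges,
               double a_u, double b_u, double a_v, double b_v,
               double beta_prior_sd,
               int n_burn, int n_keep, int thin,
               NumericVector alpha_init, bool keep_fields) {
  int n = O.nrow(), P = O.ncol();
  int n_total = n_burn + n_keep * thin;

  NumericVector alpha = clone(alpha_init);
  double b1 = R::rnorm(0.0, 0.1);
  NumericVector d(P, 0.0); // d[0] fixed at 0
  for (int p = 1; p < P; ++p) d[p] = R::rnorm(0.0, 0.1);
  NumericMatrix u(n, P), v(n, P);
  for (int p = 0; p < P; ++p) {
    double m = 0.0;
    for (int i = 0; i < n; ++i) { u(i, p) = R::rnorm(0.0, 0.05); m += u(i, p); }
    m /= n;
    for (int i = 0; i < n; ++i) { u(i, p) -= m; v(i, p) = R::rnorm(0.0, 0.05); }
  }
  double tau_u = 50.0, tau_v = 50.0;

  NumericMatrix lp(n, P);
  for (int p = 0; p < P; ++p)
    for (int i = 0; i < n; ++i)
      lp(i, p) = alpha[p] + (b1 + d[p]) * x[i] + u(i, p) + v(i, p);

  NumericVector ls_a(P, std::log(0.1)), ls_d(P, std::log(0.05));
  double ls_b = std::log(0.05);
  NumericMatrix ls_u(n, P), ls_v(n, P);
  std::fill(ls_u.begin(), ls_u.end(), std::log(0.1));
  std::fill(ls_v.begin(), ls_v.end(), std::log(0.1));
  IntegerVector acc_a(P, 0), acc_d(P, 0);
  int acc_b = 0, batch = 0;
  IntegerMatrix acc_u(n, P), acc_v(n, P);
  RescaleMove rs_u, rs_v;

  NumericVector sumO(P, 0.0);
  double sumOx = 0.0;
  NumericVector sumOx_p(P, 0.0);
  for (int p = 0; p < P; ++p)
    for (int i = 0; i < n; ++i) {
      sumO[p] += O(i, p);
      sumOx_p[p] += O(i, p) * x[i];
      sumOx += O(i, p) * x[i];
    }
  double prior_var = beta_prior_sd * beta_prior_sd;

  NumericMatrix out_alpha(n_keep, P), out_delta(n_keep, P);
  NumericVector out_b1(n_keep), out_tau_u(n_keep), out_tau_v(n_keep);
  NumericMatrix out_u, out_v;
  if (keep_fields) {
    out_u = NumericMatrix(n_keep, n * P);
    out_v = NumericMatrix(n_keep, n * P);
  }

  int kept = 0;
  for (int iter = 1; iter <= n_total; ++iter) {
    bool adapting = iter <= n_burn;

    for (int p = 0; p < P; ++p) {
      // spatial field, period p
      for (int i = 0; i < n; ++i) {
        double prop = u(i, p) + std::exp(ls_u(i, p)) * R::norm_rand();
        double du = prop - u(i, p);
        double nbsum = 0.0;
        int d_i = adj_start[i + 1] - adj_start[i];
        for (int k = adj_start[i]; k < adj_start[i + 1]; ++k) nbsum += u(adj[k], p);
        double lognum = O(i, p) * du - N(i, p) * std::exp(lp(i, p)) * (std::exp(du) - 1.0)
          - 0.5 * tau_u * (d_i * (prop * prop - u(i, p) * u(i, p)) - 2.0 * du * nbsum);
        if (std::log(R::unif_rand()) < lognum) {
          u(i, p) = prop; lp(i, p) += du;
          if (adapting) ++acc_u(i, p);
        }
      }
      double m = 0.0;
      for (int i = 0; i < n; ++i) m += u(i, p);
      m /= n;
      for (int i = 0; i < n; ++i) u(i, p) -= m;
      alpha[p] += m;

      // heterogeneous field, period p
      for (int i = 0; i < n; ++i) {
        double prop = v(i, p) + std::exp(ls_v(i, p)) * R::norm_rand();
        double dv = prop - v(i, p);
        double lognum = O(i, p) * dv - N(i, p) * std::exp(lp(i, p)) * (std::exp(dv) - 1.0)
          - 0.5 * tau_v * (prop * prop - v(i, p) * v(i, p));
        if (std::log(R::unif_rand()) < lognum) {
          v(i, p) = prop; lp(i, p) += dv;
          if (adapting) ++acc_v(i, p);
        }
      }

      // period intercept (flat prior)
      double da = std::exp(ls_a[p]) * R::norm_rand();
      double sumMu = 0.0;
      for (int i = 0; i < n; ++i) sumMu += N(i, p) * std::exp(lp(i, p));
      double lognum = sumO[p] * da - sumMu * (std::exp(da) - 1.0);
      if (std::log(R::unif_rand()) < lognum) {
        alpha[p] += da;
        for (int i = 0; i < n; ++i) lp(i, p) += da;
        if (adapting) ++acc_a[p];
      }
    }

    // baseline slope b1, Normal(0, beta_prior_sd^2) prior
    {
      double db = std::exp(ls_b) * R::norm_rand();
      double lognum = sumOx * db - 0.5 * (2.0 * b1 * db + db * db) / prior_var;
      for (int p = 0; p < P; ++p)
        for (int i = 0; i < n; ++i)
          lognum -= N(i, p) * std::exp(lp(i, p)) * (std::exp(x[i] * db) - 1.0);
      if (std::log(R::unif_rand()) < lognum) {
        b1 += db;
        for (int p = 0; p < P; ++p)
          for (int i = 0; i < n; ++i) lp(i, p) += x[i] * db;
        if (adapting) ++acc_b;
      }
    }

    // interaction offsets d_p, p >= 2
    for (int p = 1; p < P; ++p) {
      double dd = std::exp(ls_d[p]) * R::norm_rand();
      double lognum = sumOx_p[p] * dd - 0.5 * (2.0 * d[p] * dd + dd * dd) / prior_var;
      for (int i = 0; i < n; ++i)
        lognum -= N(i, p) * std::exp(lp(i, p)) * (std::exp(x[i] * dd) - 1.0);
      if (std::log(R::unif_rand()) < lognum) {
        d[p] += dd;
        for (int i = 0; i < n; ++i) lp(i, p) += x[i] * dd;
        if (adapting) ++acc_d[p];
      }
    }

    // shared precisions across the P period fields
    {
      double ssu = 0.0, ssv = 0.0;
      for (int p = 0; p < P; ++p) {
        NumericVector up = u(_, p);
        ssu += edge_ss(up, edges);
        for (int i = 0; i < n; ++i) ssv += v(i, p) * v(i, p);
      }
      tau_u = rgamma_rate(a_u + 0.5 * P * (n - 1), b_u + 0.5 * ssu);
      tau_v = rgamma_rate(a_v + 0.5 * P * n, b_v + 0.5 * ssv);
    }

    // joint (u, tau_u) rescale across all period fields
    {
      double c = std::exp(rs_u.log_s) * R::norm_rand();
      double g = std::exp(c) - 1.0;
      double lognum = -2.0 * a_u * c - b_u * tau_u * (std::exp(-2.0 * c) - 1.0);
      for (int p = 0; p < P; ++p)
        for (int i = 0; i < n; ++i) {
          double du = g * u(i, p);
          lognum += O(i, p) * du - N(i, p) * std::exp(lp(i, p)) * (std::exp(du) - 1.0);
        }
      if (std::log(R::unif_rand()) < lognum) {
        for (int p = 0; p < P; ++p)
          for (int i = 0; i < n; ++i) {
            lp(i, p) += g * u(i, p);
            u(i, p) *= std::exp(c);
          }
        tau_u *= std::exp(-2.0 * c);
        if (adapting) ++rs_u.acc;
      }
    }
    // joint (v, tau_v) rescale
    {
      double c = std::exp(rs_v.log_s) * R::norm_rand();
      double g = std::exp(c) - 1.0;
      double lognum = -2.0 * a_v * c - b_v * tau_v * (std::exp(-2.0 * c) - 1.0);
      for (int p = 0; p < P; ++p)
        for (int i = 0; i < n; ++i) {
          double dv = g * v(i, p);
          lognum += O(i, p) * dv - N(i, p) * std::exp(lp(i, p)) * (std::exp(dv) - 1.0);
        }
      if (std::log(R::unif_rand()) < lognum) {
        for (int p = 0; p < P; ++p)
          for (int i = 0; i < n; ++i) {
            lp(i, p) += g * v(i, p);
            v(i, p) *= std::exp(c);
          }
        tau_v *= std::exp(-2.0 * c);
        if (adapting) ++rs_v.acc;
      }
    }

    if (adapting && iter % 50 == 0) {
      ++batch;
      adapt(ls_b, acc_b, batch); acc_b = 0;
      adapt(rs_u.log_s, rs_u.acc, batch); rs_u.acc = 0;
      adapt(rs_v.log_s, rs_v.acc, batch); rs_v.acc = 0;
      for (int p = 0; p < P; ++p) {
        adapt(ls_a[p], acc_a[p], batch); acc_a[p] = 0;
        if (p >= 1) { adapt(ls_d[p], acc_d[p], batch); acc_d[p] = 0; }
        for (int i = 0; i < n; ++i) {
          adapt(ls_u(i, p), acc_u(i, p), batch); acc_u(i, p) = 0;
          adapt(ls_v(i, p), acc_v(i, p), batch); acc_v(i, p) = 0;
        }
      }
    }

    if (iter > n_burn && (iter - n_burn) % thin == 0) {
      for (int p = 0; p < P; ++p) {
        out_alpha(kept, p) = alpha[p];
        out_delta(kept, p) = d[p];
      }
      out_b1[kept] = b1;
      out_tau_u[kept] = tau_u;
      out_tau_v[kept] = tau_v;
      if (keep_fields) {
        for (int p = 0; p < P; ++p)
          for (int i = 0; i < n; ++i) {
            out_u(kept, p * n + i) = u(i, p);
            out_v(kept, p * n + i) = v(i, p);
          }
      }
      ++kept;
    }
  }

  List out = List::create(_["alpha"] = out_alpha, _["b1"] = out_b1,
                          _["delta"] = out_delta, _["tau_u"] = out_tau_u,
                          _["tau_v"] = out_tau_v);
  if (keep_fields) { out["u"] = out_u; out["v"] = out_v; }
  return out;
}
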