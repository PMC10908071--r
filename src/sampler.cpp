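// Metropolis-within-Gibbs kernel for the semiparametric partially linear
// mixed-effects model with skew-normal / skew-t random effects and errors.
//
// Hierarchy (per subject i with m_i visits):
//   y_i | phi_i, W_eps_i, v_eps_i ~ N(Z_i alpha + R_i phi_i
//                                      + delta_eps * (W_eps_i - c_eps),
//                                     sigma2_eps / v_eps_i * I)
//   phi_i | W_phi_i, v_phi_i      ~ N(delta_phi o (W_phi_i - c_phi),
//                                     Sigma_phi / v_phi_i)
//   W_. | v_.                     ~ N(0, I / v_.) truncated to (0, inf)
//   v_. | rho_.                   ~ Gamma(rho_./2, rate = rho_./2)
//
// c_eps / c_phi are the prior means of the truncated latents (a function of
// rho alone) when centering is on, and 0 otherwise.  Flavors: 0 = normal
// (delta pinned at 0, W unused, v pinned at 1), 1 = skew-normal (v pinned at
// 1), 2 = skew-t.  All randomness goes through R's RNG so seeding from R
// makes every draw reproducible.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;
using namespace arma;

static const double TWO_PI = 6.283185307179586476925286766559;

// ---------------------------------------------------------------- RNG utils

// standard normal truncated to (a, inf); Robert (1995) exponential
// rejection in the far tail, plain rejection otherwise
static double rtnorm_std(double a) {
  if (a < 0.25) {
    for (;;) {
      double x = R::norm_rand();
      if (x > a) return x;
    }
  }
  double lam = 0.5 * (a + std::sqrt(a * a + 4.0));
  for (;;) {
    double x = a + R::exp_rand() / lam;
    double d = x - lam;
    if (R::unif_rand() <= std::exp(-0.5 * d * d)) return x;
  }
}

static double rtnorm_pos_scalar(double mean, double sd) {
  return mean + sd * rtnorm_std(-mean / sd);
}

static vec rnorm_vec(int k) {
  vec z(k);
  for (int i = 0; i < k; ++i) z(i) = R::norm_rand();
  return z;
}

// draw x ~ N(mu, P^{-1}) given precision P (uses upper Cholesky P = U'U)
static vec rmvnorm_prec(const vec& b, const mat& P, vec* mean_out = nullptr) {
  mat U = chol(P);                       // upper
  vec mu = solve(trimatu(U), solve(trimatl(U.t()), b));
  if (mean_out) *mean_out = mu;
  return mu + solve(trimatu(U), rnorm_vec(P.n_rows));
}

// Wishart(df, S) via Bartlett decomposition, S a covariance-like scale
static mat rwishart(double df, const mat& S) {
  int d = S.n_rows;
  mat L = chol(S, "lower");
  mat A(d, d, fill::zeros);
  for (int i = 0; i < d; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  mat X = L * A;
  return X * X.t();
}

// [[Rcpp::export]]
NumericVector cpp_rtnorm_pos(int n, NumericVector mean, NumericVector sd) {
  NumericVector out(n);
  int nm = mean.size(), ns = sd.size();
  for (int i = 0; i < n; ++i)
    out[i] = rtnorm_pos_scalar(mean[i % nm], sd[i % ns]);
  return out;
}

// ------------------------------------------------------------- model state

struct Dat {
  vec y;
  mat Z;      // n x p stacked fixed design
  mat Rm;     // n x d stacked random design
  uvec start; // 0-based first row of each subject
  uvec len;   // visits per subject
  int m, n, p, d;
  cube RtR;   // d x d x m per-subject R_i' R_i
};

struct Pri {
  vec alpha0;     // prior mean of alpha
  vec theta;      // prior variances of alpha (diagonal)
  vec kap_dphi;   // prior variances of delta_phi
  double kap_deps;
  mat D;          // inverse-Wishart scale
  double nu;      // inverse-Wishart dof
  double e1, e2;  // inverse-gamma shape / rate for sigma2_eps
  double r0_phi, r0_eps; // exponential rates for the dof priors
  double trunc;   // lower truncation of the dof priors
};

struct Cfg {
  int re_fl, err_fl; // 0 normal, 1 skew-normal, 2 skew-t
  bool center;
};

struct St {
  vec alpha;
  mat phi;    // m x d
  mat Wphi;   // m x d
  vec Weps;   // n
  vec vphi, veps; // m
  double sigma2;
  mat Sigma, Sigma_inv;
  vec dphi;
  double deps;
  double rho_phi, rho_eps;
};

// prior mean of a positive-truncated N(0, 1/v) coordinate, v ~ Gamma(r/2, r/2)
static double c_of_rho(double rho) {
  return std::sqrt(2.0 / M_PI) * std::sqrt(rho / 2.0) *
         std::exp(R::lgammafn((rho - 1.0) / 2.0) - R::lgammafn(rho / 2.0));
}

static double c_eps_val(const St& s, const Cfg& c) {
  if (!c.center || c.err_fl == 0) return 0.0;
  if (c.err_fl == 1) return std::sqrt(2.0 / M_PI);
  return c_of_rho(s.rho_eps);
}

static double c_phi_val(const St& s, const Cfg& c) {
  if (!c.center || c.re_fl == 0) return 0.0;
  if (c.re_fl == 1) return std::sqrt(2.0 / M_PI);
  return c_of_rho(s.rho_phi);
}

// fitted random-effect part R_i phi_i, stacked over rows
static vec fit_re(const St& s, const Dat& dd) {
  vec out(dd.n, fill::zeros);
  for (int i = 0; i < dd.m; ++i) {
    if (dd.len(i) == 0) continue;
    uword a = dd.start(i), b = a + dd.len(i) - 1;
    out.subvec(a, b) = dd.Rm.rows(a, b) * s.phi.row(i).t();
  }
  return out;
}

// row-wise v_eps weights
static vec veps_by_row(const St& s, const Dat& dd) {
  vec w(dd.n);
  for (int i = 0; i < dd.m; ++i) {
    if (dd.len(i) == 0) continue;
    w.subvec(dd.start(i), dd.start(i) + dd.len(i) - 1).fill(s.veps(i));
  }
  return w;
}

// ------------------------------------------------------------ Gibbs blocks

static void upd_alpha(St& s, const Dat& dd, const Pri& pr, const Cfg& cf,
                      List* extras) {
  double ce = c_eps_val(s, cf);
  vec Wt = (cf.err_fl == 0) ? vec(dd.n, fill::zeros) : vec(s.Weps - ce);
  vec resid = dd.y - fit_re(s, dd) - s.deps * Wt;
  vec w = veps_by_row(s, dd) / s.sigma2;
  mat P = dd.Z.t() * (dd.Z.each_col() % w);
  P.diag() += 1.0 / pr.theta;
  vec b = dd.Z.t() * (w % resid) + pr.alpha0 / pr.theta;
  vec mu;
  s.alpha = rmvnorm_prec(b, P, &mu);
  if (extras) {
    (*extras)["cond_mean"] = wrap(mu);
    (*extras)["cond_cov"] = wrap(mat(inv_sympd(symmatu(P))));
  }
}

static void upd_phi(St& s, const Dat& dd, const Pri& pr, const Cfg& cf,
                    List* extras) {
  double ce = c_eps_val(s, cf), cp = c_phi_val(s, cf);
  vec Za = dd.Z * s.alpha;
  mat cond_mean;
  if (extras) cond_mean.set_size(dd.m, dd.d);
  for (int i = 0; i < dd.m; ++i) {
    vec Wt_i = (cf.re_fl == 0) ? vec(dd.d, fill::zeros)
                               : vec(s.Wphi.row(i).t() - cp);
    mat P = s.vphi(i) * s.Sigma_inv;
    vec b = s.vphi(i) * (s.Sigma_inv * (s.dphi % Wt_i));
    if (dd.len(i) > 0) {
      uword a = dd.start(i), e = a + dd.len(i) - 1;
      double we = s.veps(i) / s.sigma2;
      P += we * dd.RtR.slice(i);
      vec r = dd.y.subvec(a, e) - Za.subvec(a, e);
      if (cf.err_fl != 0) r -= s.deps * (s.Weps.subvec(a, e) - ce);
      b += we * (dd.Rm.rows(a, e).t() * r);
    }
    vec mu;
    s.phi.row(i) = rmvnorm_prec(b, P, &mu).t();
    if (extras) cond_mean.row(i) = mu.t();
  }
  if (extras) (*extras)["cond_mean"] = wrap(cond_mean);
}

// positive-truncated latents W_eps (per visit) and W_phi (componentwise)
static void upd_latents(St& s, const Dat& dd, const Pri&, const Cfg& cf,
                        List* extras) {
  double ce = c_eps_val(s, cf), cp = c_phi_val(s, cf);
  if (cf.err_fl != 0) {
    vec Za = dd.Z * s.alpha;
    vec fre = fit_re(s, dd);
    vec wmean(dd.n), wsd(dd.n);
    double denom = s.sigma2 + s.deps * s.deps;
    for (int i = 0; i < dd.m; ++i) {
      if (dd.len(i) == 0) continue;
      uword a = dd.start(i), e = a + dd.len(i) - 1;
      double sd = std::sqrt(s.sigma2 / (s.veps(i) * denom));
      for (uword j = a; j <= e; ++j) {
        double aa = dd.y(j) - Za(j) - fre(j) + s.deps * ce;
        double mu = s.deps * aa / denom;
        wmean(j) = mu;
        wsd(j) = sd;
        s.Weps(j) = rtnorm_pos_scalar(mu, sd);
      }
    }
    if (extras) {
      (*extras)["weps_cond_mean"] = wrap(wmean);
      (*extras)["weps_cond_sd"] = wrap(wsd);
    }
  }
  if (cf.re_fl != 0) {
    mat Dl = diagmat(s.dphi);
    mat A0 = Dl * s.Sigma_inv * Dl + eye(dd.d, dd.d);
    for (int i = 0; i < dd.m; ++i) {
      vec g = s.phi.row(i).t() + cp * s.dphi;
      vec b = s.vphi(i) * (Dl * (s.Sigma_inv * g));
      mat P = s.vphi(i) * A0;
      for (int k = 0; k < dd.d; ++k) {
        double off = dot(P.row(k).t(), s.Wphi.row(i).t()) -
                     P(k, k) * s.Wphi(i, k);
        double mu = (b(k) - off) / P(k, k);
        s.Wphi(i, k) = rtnorm_pos_scalar(mu, 1.0 / std::sqrt(P(k, k)));
      }
    }
  }
}

static void upd_scales(St& s, const Dat& dd, const Pri& pr, const Cfg& cf,
                       List* extras) {
  double ce = c_eps_val(s, cf), cp = c_phi_val(s, cf);
  // sigma2_eps | rest ~ IG(e1 + n/2, e2 + .5 * sum v_i e_ij^2)
  vec Wt = (cf.err_fl == 0) ? vec(dd.n, fill::zeros) : vec(s.Weps - ce);
  vec e = dd.y - dd.Z * s.alpha - fit_re(s, dd) - s.deps * Wt;
  vec w = veps_by_row(s, dd);
  double shape = pr.e1 + 0.5 * dd.n;
  double rate = pr.e2 + 0.5 * dot(w, square(e));
  s.sigma2 = 1.0 / R::rgamma(shape, 1.0 / rate);
  // Sigma_phi | rest ~ IW(nu + m, D + sum v_i u u')
  mat S = pr.D;
  for (int i = 0; i < dd.m; ++i) {
    vec Wt_i = (cf.re_fl == 0) ? vec(dd.d, fill::zeros)
                               : vec(s.Wphi.row(i).t() - cp);
    vec u = s.phi.row(i).t() - s.dphi % Wt_i;
    S += s.vphi(i) * (u * u.t());
  }
  double df = pr.nu + dd.m;
  int tries = 0;
  for (;;) {
    bool ok = true;
    mat Sinv;
    ok = inv_sympd(Sinv, symmatu(S));
    if (ok) {
      mat W = rwishart(df, Sinv);
      mat Sig;
      ok = inv_sympd(Sig, symmatu(W));
      if (ok) {
        s.Sigma_inv = symmatu(W);
        s.Sigma = symmatu(Sig);
        break;
      }
    }
    if (++tries >= 10)
      stop("update_scales: sampled covariance not positive definite after 10 attempts");
  }
  if (extras) {
    (*extras)["sigma2_shape"] = shape;
    (*extras)["sigma2_rate"] = rate;
    (*extras)["wishart_df"] = df;
    (*extras)["wishart_scale"] = wrap(S);
  }
}

static void upd_skew(St& s, const Dat& dd, const Pri& pr, const Cfg& cf,
                     List* extras) {
  double ce = c_eps_val(s, cf), cp = c_phi_val(s, cf);
  if (cf.err_fl != 0) {
    vec Wt = s.Weps - ce;
    vec e = dd.y - dd.Z * s.alpha - fit_re(s, dd);
    vec w = veps_by_row(s, dd) / s.sigma2;
    double prec = 1.0 / pr.kap_deps + dot(w, square(Wt));
    double mu = dot(w, Wt % e) / prec;
    s.deps = mu + R::norm_rand() / std::sqrt(prec);
    if (extras) {
      (*extras)["deps_mean"] = mu;
      (*extras)["deps_var"] = 1.0 / prec;
    }
  }
  if (cf.re_fl != 0) {
    mat P = diagmat(1.0 / pr.kap_dphi);
    vec b(dd.d, fill::zeros);
    for (int i = 0; i < dd.m; ++i) {
      mat Mt = diagmat(s.Wphi.row(i).t() - cp);
      P += s.vphi(i) * (Mt * s.Sigma_inv * Mt);
      b += s.vphi(i) * (Mt * (s.Sigma_inv * s.phi.row(i).t()));
    }
    vec mu;
    s.dphi = rmvnorm_prec(b, symmatu(P), &mu);
    if (extras) {
      (*extras)["dphi_mean"] = wrap(mu);
      (*extras)["dphi_cov"] = wrap(mat(inv_sympd(symmatu(P))));
    }
  }
}

static void upd_mixing(St& s, const Dat& dd, const Pri&, const Cfg& cf,
                       List* extras) {
  double ce = c_eps_val(s, cf), cp = c_phi_val(s, cf);
  vec es(dd.m, fill::zeros), er(dd.m, fill::zeros);
  vec ps(dd.m, fill::zeros), prr(dd.m, fill::zeros);
  if (cf.err_fl == 2) {
    vec Wt = s.Weps - ce;
    vec e = dd.y - dd.Z * s.alpha - fit_re(s, dd) - s.deps * Wt;
    for (int i = 0; i < dd.m; ++i) {
      double shape = 0.5 * s.rho_eps + dd.len(i);
      double rate = 0.5 * s.rho_eps;
      if (dd.len(i) > 0) {
        uword a = dd.start(i), b = a + dd.len(i) - 1;
        rate += 0.5 * dot(e.subvec(a, b), e.subvec(a, b)) / s.sigma2 +
                0.5 * dot(s.Weps.subvec(a, b), s.Weps.subvec(a, b));
      }
      s.veps(i) = R::rgamma(shape, 1.0 / rate);
      es(i) = shape; er(i) = rate;
    }
  }
  if (cf.re_fl == 2) {
    for (int i = 0; i < dd.m; ++i) {
      vec Wt_i = s.Wphi.row(i).t() - cp;
      vec u = s.phi.row(i).t() - s.dphi % Wt_i;
      double shape = 0.5 * s.rho_phi + dd.d;
      double rate = 0.5 * s.rho_phi + 0.5 * as_scalar(u.t() * s.Sigma_inv * u) +
                    0.5 * dot(s.Wphi.row(i), s.Wphi.row(i));
      s.vphi(i) = R::rgamma(shape, 1.0 / rate);
      ps(i) = shape; prr(i) = rate;
    }
  }
  if (extras) {
    (*extras)["veps_shape"] = wrap(es);
    (*extras)["veps_rate"] = wrap(er);
    (*extras)["vphi_shape"] = wrap(ps);
    (*extras)["vphi_rate"] = wrap(prr);
  }
}

// gamma-mixing log-likelihood + truncated-exponential prior + Jacobian of
// theta = log(rho - trunc)
static double rho_logpost_base(double rho, const vec& v, double r0,
                               double trunc) {
  int m = v.n_elem;
  double h = 0.5 * rho;
  return m * (h * std::log(h) - R::lgammafn(h)) + h * accu(log(v)) -
         h * accu(v) - r0 * rho + std::log(rho - trunc);
}

// extra data terms that depend on rho through the centering constant
static double rho_extra_eps(const St& s, const Dat& dd, const Cfg& cf,
                            double rho) {
  if (!cf.center) return 0.0;
  double ce = c_of_rho(rho);
  vec Wt = s.Weps - ce;
  vec e = dd.y - dd.Z * s.alpha - fit_re(s, dd) - s.deps * Wt;
  vec w = veps_by_row(s, dd);
  return -0.5 * dot(w, square(e)) / s.sigma2;
}

static double rho_extra_phi(const St& s, const Dat& dd, const Cfg& cf,
                            double rho) {
  if (!cf.center) return 0.0;
  double cp = c_of_rho(rho);
  double q = 0.0;
  for (int i = 0; i < dd.m; ++i) {
    vec u = s.phi.row(i).t() - s.dphi % (s.Wphi.row(i).t() - cp);
    q += s.vphi(i) * as_scalar(u.t() * s.Sigma_inv * u);
  }
  return -0.5 * q;
}

// returns acceptance probability; updates rho in place
static double upd_rho_one(double& rho, const vec& v, double r0, double trunc,
                          double step, const St& s, const Dat& dd,
                          const Cfg& cf, bool is_eps) {
  double th = std::log(rho - trunc);
  double th2 = th + step * R::norm_rand();
  double rho2 = trunc + std::exp(th2);
  double lp1 = rho_logpost_base(rho, v, r0, trunc) +
               (is_eps ? rho_extra_eps(s, dd, cf, rho)
                       : rho_extra_phi(s, dd, cf, rho));
  double lp2 = rho_logpost_base(rho2, v, r0, trunc) +
               (is_eps ? rho_extra_eps(s, dd, cf, rho2)
                       : rho_extra_phi(s, dd, cf, rho2));
  double acc = std::min(1.0, std::exp(lp2 - lp1));
  if (R::unif_rand() < acc) rho = rho2;
  return acc;
}

// conditional deviance of the observations at the current state
static double deviance_cpp(const St& s, const Dat& dd, const Cfg& cf) {
  double ce = c_eps_val(s, cf);
  vec Wt = (cf.err_fl == 0) ? vec(dd.n, fill::zeros) : vec(s.Weps - ce);
  vec e = dd.y - dd.Z * s.alpha - fit_re(s, dd) - s.deps * Wt;
  vec w = veps_by_row(s, dd);
  double dev = 0.0;
  for (int j = 0; j < dd.n; ++j)
    dev += std::log(TWO_PI * s.sigma2 / w(j)) + w(j) * e(j) * e(j) / s.sigma2;
  return dev;
}

// ------------------------------------------------------------- conversion

static Dat as_dat(const List& dat) {
  Dat dd;
  dd.y = as<vec>(dat["y"]);
  dd.Z = as<mat>(dat["Z"]);
  dd.Rm = as<mat>(dat["R"]);
  dd.start = as<uvec>(dat["start"]);
  dd.len = as<uvec>(dat["len"]);
  dd.m = dd.start.n_elem;
  dd.n = dd.y.n_elem;
  dd.p = dd.Z.n_cols;
  dd.d = dd.Rm.n_cols;
  dd.RtR.set_size(dd.d, dd.d, dd.m);
  for (int i = 0; i < dd.m; ++i) {
    if (dd.len(i) == 0) {
      dd.RtR.slice(i).zeros();
    } else {
      uword a = dd.start(i), b = a + dd.len(i) - 1;
      dd.RtR.slice(i) = dd.Rm.rows(a, b).t() * dd.Rm.rows(a, b);
    }
  }
  return dd;
}

static Pri as_pri(const List& pri) {
  Pri pr;
  pr.alpha0 = as<vec>(pri["alpha_mean"]);
  pr.theta = as<vec>(pri["alpha_var"]);
  pr.kap_dphi = as<vec>(pri["kappa_delta_phi"]);
  pr.kap_deps = as<double>(pri["kappa_delta_eps"]);
  pr.D = as<mat>(pri["D_phi"]);
  pr.nu = as<double>(pri["nu_phi"]);
  pr.e1 = as<double>(pri["sigma2_shape"]);
  pr.e2 = as<double>(pri["sigma2_rate"]);
  pr.r0_phi = as<double>(pri["rho_rate_phi"]);
  pr.r0_eps = as<double>(pri["rho_rate_eps"]);
  pr.trunc = as<double>(pri["rho_trunc"]);
  return pr;
}

static Cfg as_cfg(const List& cfg) {
  Cfg cf;
  cf.re_fl = as<int>(cfg["re_fl"]);
  cf.err_fl = as<int>(cfg["err_fl"]);
  cf.center = as<bool>(cfg["center"]);
  return cf;
}

static St as_st(const List& st) {
  St s;
  s.alpha = as<vec>(st["alpha"]);
  s.phi = as<mat>(st["phi"]);
  s.Wphi = as<mat>(st["W_phi"]);
  s.Weps = as<vec>(st["W_eps"]);
  s.vphi = as<vec>(st["v_phi"]);
  s.veps = as<vec>(st["v_eps"]);
  s.sigma2 = as<double>(st["sigma2_eps"]);
  s.Sigma = as<mat>(st["Sigma_phi"]);
  s.Sigma_inv = inv_sympd(symmatu(s.Sigma));
  s.dphi = as<vec>(st["delta_phi"]);
  s.deps = as<double>(st["delta_eps"]);
  s.rho_phi = as<double>(st["rho_phi"]);
  s.rho_eps = as<double>(st["rho_eps"]);
  return s;
}

static List st_to_list(const St& s) {
  return List::create(
      _["alpha"] = wrap(s.alpha), _["phi"] = wrap(s.phi),
      _["W_phi"] = wrap(s.Wphi), _["W_eps"] = wrap(s.Weps),
      _["v_phi"] = wrap(s.vphi), _["v_eps"] = wrap(s.veps),
      _["sigma2_eps"] = s.sigma2, _["Sigma_phi"] = wrap(s.Sigma),
      _["delta_phi"] = wrap(s.dphi), _["delta_eps"] = s.deps,
      _["rho_phi"] = s.rho_phi, _["rho_eps"] = s.rho_eps);
}

// ------------------------------------------------------------ entry points

// single-block update, used by the R-level wrappers and their oracle tests
// block: 1 alpha, 2 phi, 3 latents, 4 scales, 5 skewness, 6 mixing, 7 dof
// [[Rcpp::export]]
List cpp_update_block(int block, List state, List dat, List pri, List cfg,
                      double step = 0.3) {
  Dat dd = as_dat(dat);
  Pri pr = as_pri(pri);
  Cfg cf = as_cfg(cfg);
  St s = as_st(state);
  List extras;
  switch (block) {
    case 1: upd_alpha(s, dd, pr, cf, &extras); break;
    case 2: upd_phi(s, dd, pr, cf, &extras); break;
    case 3: upd_latents(s, dd, pr, cf, &extras); break;
    case 4: upd_scales(s, dd, pr, cf, &extras); break;
    case 5: upd_skew(s, dd, pr, cf, &extras); break;
    case 6: upd_mixing(s, dd, pr, cf, &extras); break;
    case 7: {
      if (cf.err_fl == 2)
        extras["acc_eps"] = upd_rho_one(s.rho_eps, s.veps, pr.r0_eps, pr.trunc,
                                        step, s, dd, cf, true);
      if (cf.re_fl == 2)
        extras["acc_phi"] = upd_rho_one(s.rho_phi, s.vphi, pr.r0_phi, pr.trunc,
                                        step, s, dd, cf, false);
      break;
    }
    default: stop("unknown block");
  }
  return List::create(_["state"] = st_to_list(s), _["extras"] = extras);
}

// [[Rcpp::export]]
double cpp_deviance(List state, List dat, List cfg) {
  Dat dd = as_dat(dat);
  Cfg cf = as_cfg(cfg);
  St s = as_st(state);
  return deviance_cpp(s, dd, cf);
}

// full chain: fixed cycle alpha -> phi -> latents -> scales -> skewness ->
// mixing -> dof; Robbins-Monro step adaptation during burn-in only
// [[Rcpp::export]]
List cpp_run_chain(List dat, List pri, List cfg, List init, int n_iter,
                   int burnin, int thin, double step0, double target_acc) {
  Dat dd = as_dat(dat);
  Pri pr = as_pri(pri);
  Cfg cf = as_cfg(cfg);
  St s = as_st(init);

  int n_keep = (n_iter - burnin) / thin;
  int nsig = dd.d * (dd.d + 1) / 2;
  int n_par = dd.p + 1 + nsig + dd.d + 1 + 2 + 1;
  mat draws(n_keep, n_par);

  mat phi_sum(dd.m, dd.d, fill::zeros), wphi_sum(dd.m, dd.d, fill::zeros);
  vec weps_sum(dd.n, fill::zeros), veps_sum(dd.m, fill::zeros),
      vphi_sum(dd.m, fill::zeros);
  double ls_eps = std::log(step0), ls_phi = std::log(step0);
  double acc_eps_sum = 0.0, acc_phi_sum = 0.0;
  int n_mh = 0, kept = 0;

  for (int it = 1; it <= n_iter; ++it) {
    upd_alpha(s, dd, pr, cf, nullptr);
    upd_phi(s, dd, pr, cf, nullptr);
    upd_latents(s, dd, pr, cf, nullptr);
    upd_scales(s, dd, pr, cf, nullptr);
    upd_skew(s, dd, pr, cf, nullptr);
    upd_mixing(s, dd, pr, cf, nullptr);
    if (cf.err_fl == 2 || cf.re_fl == 2) {
      ++n_mh;
      double gam = (it <= burnin) ? 2.0 / std::pow((double)it, 0.6) : 0.0;
      if (cf.err_fl == 2) {
        double a = upd_rho_one(s.rho_eps, s.veps, pr.r0_eps, pr.trunc,
                               std::exp(ls_eps), s, dd, cf, true);
        acc_eps_sum += a;
        ls_eps = std::min(2.3, std::max(-6.9, ls_eps + gam * (a - target_acc)));
      }
      if (cf.re_fl == 2) {
        double a = upd_rho_one(s.rho_phi, s.vphi, pr.r0_phi, pr.trunc,
                               std::exp(ls_phi), s, dd, cf, false);
        acc_phi_sum += a;
        ls_phi = std::min(2.3, std::max(-6.9, ls_phi + gam * (a - target_acc)));
      }
    }
    if (it > burnin && (it - burnin) % thin == 0) {
      rowvec row(n_par);
      int k = 0;
      for (int j = 0; j < dd.p; ++j) row(k++) = s.alpha(j);
      row(k++) = s.sigma2;
      for (int j = 0; j < dd.d; ++j)
        for (int i2 = 0; i2 <= j; ++i2) row(k++) = s.Sigma(i2, j);
      for (int j = 0; j < dd.d; ++j) row(k++) = s.dphi(j);
      row(k++) = s.deps;
      row(k++) = s.rho_phi;
      row(k++) = s.rho_eps;
      row(k++) = deviance_cpp(s, dd, cf);
      draws.row(kept++) = row;
      phi_sum += s.phi;
      wphi_sum += s.Wphi;
      weps_sum += s.Weps;
      veps_sum += s.veps;
      vphi_sum += s.vphi;
    }
    if (it % 512 == 0) Rcpp::checkUserInterrupt();
  }

  double inv = n_keep > 0 ? 1.0 / n_keep : 0.0;
  return List::create(
      _["draws"] = wrap(draws),
      _["phi_mean"] = wrap(mat(phi_sum * inv)),
      _["W_phi_mean"] = wrap(mat(wphi_sum * inv)),
      _["W_eps_mean"] = wrap(vec(weps_sum * inv)),
      _["v_eps_mean"] = wrap(vec(veps_sum * inv)),
      _["v_phi_mean"] = wrap(vec(vphi_sum * inv)),
      _["acc_rho_eps"] = n_mh > 0 ? acc_eps_sum / n_mh : NA_REAL,
      _["acc_rho_phi"] = n_mh > 0 ? acc_phi_sum / n_mh : NA_REAL,
      _["step_eps"] = std::exp(ls_eps), _["step_phi"] = std::exp(ls_phi),
      _["final_state"] = st_to_list(s));
}
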