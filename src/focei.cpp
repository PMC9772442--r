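// Core numerics for the joint VEN/ODV population model:
//  - closed-form concentrations for the depot -> parent -> metabolite chain
//    (single dose, repeated dosing, steady state),
//  - FOCEI inner problem (empirical-Bayes eta modes) and the linearized
//    marginal -2LL contribution per subject,
//  - population predictions at supplied etas (simulation support),
//  - goodness-of-fit quantities (PRED/IPRED/CWRES).
//
// Parameter vector layout (natural scale) everywhere:
//   p[0] cl_f (L/h), p[1] v_f (L), p[2] clm_f (L/h), p[3] vm_f (L),
//   p[4] ka (1/h), p[5] fp (0..1)
// Analyte codes: 0 = VEN (parent), 1 = ODV (metabolite).

#define ARMA_WARN_LEVEL 1  // transient singular systems are handled locally
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------------------
// stable exponential differences
// ---------------------------------------------------------------------------

// (exp(-a t) - exp(-b t)) / (b - a); -> t exp(-a t) as b -> a.
// Symmetric in (a, b); computed overflow-free for nonnegative rates.
static inline double ediff_(double a, double b, double t) {
  if (a > b) std::swap(a, b);
  double d = b - a;
  if (d == 0.0) return t * std::exp(-a * t);
  return std::exp(-a * t) * (-std::expm1(-d * t)) / d;
}

// second divided difference of exp(-x t) over nodes {a,b,c}; symmetric,
// nonnegative, and stable under node confluence (-> t^2/2 exp(-mu t)).
static double dd2exp_(double a, double b, double c, double t) {
  double n0 = a, n1 = b, n2 = c;
  if (n0 > n1) std::swap(n0, n1);
  if (n1 > n2) std::swap(n1, n2);
  if (n0 > n1) std::swap(n0, n1);
  double span = n2 - n0;
  if (span * t < 1e-7 || span < 1e-12 * std::max(n2, 1e-300)) {
    double mu = (n0 + n1 + n2) / 3.0;
    return 0.5 * t * t * std::exp(-mu * t);
  }
  // first divided differences of exp(-x t) over adjacent (sorted) pairs
  double f01 = -ediff_(n0, n1, t);
  double f12 = -ediff_(n1, n2, t);
  return (f12 - f01) / span;
}

// ---------------------------------------------------------------------------
// unit-dose amounts in the central compartments at time dt after one dose
// ---------------------------------------------------------------------------

static inline double unitA1_(double ka, double kp, double fp, double dt) {
  if (dt <= 0.0) return 0.0;
  return (1.0 - fp) * ka * ediff_(kp, ka, dt);
}

static inline double unitA2_(double ka, double kp, double km, double fp,
                             double dt) {
  if (dt <= 0.0) return 0.0;
  return fp * ka * ediff_(ka, km, dt) +
         (1.0 - fp) * ka * kp * dd2exp_(ka, kp, km, dt);
}

// exponential-sum representation (valid when rates are well separated)
struct ExpSum {
  int n;
  double lam[3];
  double c[3];
};

static bool make_expsum_(const double* p, int analyte, ExpSum& es) {
  double cl = p[0], v = p[1], clm = p[2], vm = p[3], ka = p[4], fp = p[5];
  double kp = cl / v, km = clm / vm;
  double mx = std::max(ka, std::max(kp, km));
  double gap = std::min(std::fabs(ka - kp),
                        std::min(std::fabs(ka - km), std::fabs(kp - km)));
  if (!(gap > 1e-4 * mx)) return false;  // near-degenerate: caller falls back
  if (analyte == 0) {
    double c = (1.0 - fp) * ka / (ka - kp);
    es.n = 2;
    es.lam[0] = kp; es.c[0] = c;
    es.lam[1] = ka; es.c[1] = -c;
  } else {
    double b1 = fp * ka;
    double b2 = (1.0 - fp) * ka * kp;
    es.n = 3;
    es.lam[0] = ka; es.c[0] = b1 / (km - ka) + b2 / ((kp - ka) * (km - ka));
    es.lam[1] = kp; es.c[1] = b2 / ((ka - kp) * (km - kp));
    es.lam[2] = km; es.c[2] = -b1 / (km - ka) + b2 / ((ka - km) * (kp - km));
  }
  return true;
}

// ---------------------------------------------------------------------------
// concentration at one time under a regimen
//
// dose matrix columns: time, amt, ii, addl, ss.
// A steady-state event (ss = 1) resets the system: it represents an
// established dosing train; the most recent ss event at or before t governs,
// together with any later non-ss doses.
// ---------------------------------------------------------------------------

// strict = true: raise numerical errors (user-facing prediction surface);
// strict = false: cap degenerate accumulation factors so transient optimizer
// excursions yield a huge-but-finite objective instead of an exception.
static double conc_at_(const double* p, const arma::mat& dose, double t,
                       int analyte, const ExpSum* es, const bool* es_ok,
                       bool strict) {
  double cl = p[0], v = p[1], clm = p[2], vm = p[3], ka = p[4], fp = p[5];
  double kp = cl / v, km = clm / vm;
  double vol = (analyte == 0) ? v : vm;
  int nd = dose.n_rows;

  int ssrow = -1;
  double sstime = -1.0;
  for (int r = 0; r < nd; ++r)
    if (dose(r, 4) > 0.5 && dose(r, 0) <= t && dose(r, 0) >= sstime) {
      ssrow = r;
      sstime = dose(r, 0);
    }

  bool ok = es_ok[analyte];
  const ExpSum& E = es[analyte];
  double amt_total = 0.0;

  for (int r = 0; r < nd; ++r) {
    double td = dose(r, 0), amtd = dose(r, 1), ii = dose(r, 2);
    int addl = (int)dose(r, 3);
    bool ss = dose(r, 4) > 0.5;
    if (td > t) continue;
    if (ss && r != ssrow) continue;         // superseded ss train
    if (ssrow >= 0 && !ss && td < sstime) continue;  // history before reset

    double contrib = 0.0;
    if (ss) {
      if (ii <= 0.0) stop("steady-state dose event requires a positive interdose interval");
      double dt = t - td;
      if (ok) {
        for (int k = 0; k < E.n; ++k) {
          double l = E.lam[k];
          double den = -std::expm1(-l * ii);
          if (den < 1e-12) {
            if (strict)
              stop("numerical error: steady-state accumulation factor overflow (lambda * tau too small)");
            den = 1e-12;
          }
          contrib += E.c[k] * std::exp(-l * dt) / den;
        }
      } else {
        double acc = 0.0;
        for (int k = 0; k < 5000; ++k) {
          double dtk = dt + k * ii;
          double a = (analyte == 0) ? unitA1_(ka, kp, fp, dtk)
                                    : unitA2_(ka, kp, km, fp, dtk);
          acc += a;
          if (k > 20 && a < 1e-12 * std::max(acc, 1e-300)) break;
        }
        contrib = acc;
      }
    } else {
      int m = 1;
      double dlast = t - td;
      if (ii > 0.0 && addl > 0) {
        int kmax = (int)std::floor((t - td) / ii + 1e-12);
        if (kmax > addl) kmax = addl;
        if (kmax < 0) kmax = 0;
        m = kmax + 1;
        dlast = t - td - (double)(m - 1) * ii;
        if (dlast < 0.0) dlast = 0.0;
      }
      if (m > 1 && ok) {
        for (int k = 0; k < E.n; ++k) {
          double l = E.lam[k];
          double ei = std::exp(-l * ii);
          double geo;
          if (1.0 - ei < 1e-12) {
            // l * ii underflow: partial sum degenerates to m equal terms
            geo = (double)m;
          } else {
            geo = (1.0 - std::pow(ei, (double)m)) / (1.0 - ei);
          }
          contrib += E.c[k] * std::exp(-l * dlast) * geo;
        }
      } else if (m > 1) {
        for (int j = 0; j < m; ++j) {
          double dtk = dlast + (double)j * ii;
          contrib += (analyte == 0) ? unitA1_(ka, kp, fp, dtk)
                                    : unitA2_(ka, kp, km, fp, dtk);
        }
      } else {
        contrib = (analyte == 0) ? unitA1_(ka, kp, fp, dlast)
                                 : unitA2_(ka, kp, km, fp, dlast);
      }
    }
    amt_total += amtd * contrib;
  }
  return 1000.0 * amt_total / vol;
}

static void check_params_(const double* p) {
  for (int j = 0; j < 6; ++j)
    if (!std::isfinite(p[j])) stop("invalid parameter: non-finite structural parameter");
  if (p[0] <= 0 || p[1] <= 0 || p[2] <= 0 || p[3] <= 0 || p[4] <= 0)
    stop("invalid parameter: clearances, volumes and ka must be strictly positive");
  if (p[5] < 0 || p[5] > 1) stop("invalid parameter: fp must lie in [0, 1]");
}

static void pred_profile_(const double* p, const arma::mat& dose,
                          const arma::vec& times, const arma::ivec& analyte,
                          arma::vec& out, bool strict = false) {
  ExpSum es[2];
  bool ok[2];
  ok[0] = make_expsum_(p, 0, es[0]);
  ok[1] = make_expsum_(p, 1, es[1]);
  for (arma::uword i = 0; i < times.n_elem; ++i)
    out(i) = conc_at_(p, dose, times(i), analyte(i), es, ok, strict);
}

// [[Rcpp::export]]
NumericVector cpp_pred(NumericVector p6, NumericMatrix dose,
                       NumericVector times, IntegerVector analyte) {
  check_params_(p6.begin());
  arma::mat D(dose.begin(), dose.nrow(), dose.ncol(), false);
  arma::vec t(times.begin(), times.size(), false);
  arma::ivec a(analyte.size());
  for (int i = 0; i < analyte.size(); ++i) a(i) = analyte[i];
  arma::vec out(t.n_elem);
  pred_profile_(p6.begin(), D, t, a, out, true);
  return NumericVector(out.begin(), out.end());
}

// ---------------------------------------------------------------------------
// model / data containers for estimation
// ---------------------------------------------------------------------------

struct SubjData {
  arma::vec time, dv;
  arma::ivec analyte;
  arma::mat dose;
  arma::vec covx;  // covariate value per effect (subject-specific)
};

struct ModelDef {
  arma::vec theta;     // 6 structural typical values
  arma::vec covtheta;  // effect coefficients
  arma::ivec effpar;   // 0-based structural index per effect
  arma::ivec efftype;  // 0 categorical linear (1 + theta * x), 1 power (x/ref)^theta
  arma::vec effref;
  arma::ivec iiv;      // 0-based structural indices carrying etas
  arma::vec omega2;
  arma::vec sigma2;    // (VEN, ODV)
  double add2;         // additive variance floor (ng/ml)^2
};

static void parse_model_(const List& model, ModelDef& M) {
  M.theta = as<arma::vec>(model["theta"]);
  M.covtheta = as<arma::vec>(model["covtheta"]);
  M.effpar = as<arma::ivec>(model["effpar"]);
  M.efftype = as<arma::ivec>(model["efftype"]);
  M.effref = as<arma::vec>(model["effref"]);
  M.iiv = as<arma::ivec>(model["iiv"]);
  M.omega2 = as<arma::vec>(model["omega2"]);
  M.sigma2 = as<arma::vec>(model["sigma2"]);
  M.add2 = as<double>(model["add2"]);
  if (M.theta.n_elem != 6) stop("theta must have length 6");
  if (M.sigma2.n_elem != 2) stop("sigma2 must have length 2");
  if (M.omega2.n_elem != M.iiv.n_elem) stop("omega2 length must match iiv");
}

static void parse_subject_(const List& s, SubjData& S) {
  S.time = as<arma::vec>(s["time"]);
  S.dv = as<arma::vec>(s["dv"]);
  S.analyte = as<arma::ivec>(s["analyte"]);
  S.dose = as<arma::mat>(s["dose"]);
  S.covx = as<arma::vec>(s["covx"]);
}

typedef std::vector<SubjData> SubjVec;

// pre-parse the subject list once per fit; the resulting handle is accepted
// anywhere a subject list is
// [[Rcpp::export]]
SEXP cpp_build_data(List subjects) {
  XPtr<SubjVec> ptr(new SubjVec(subjects.size()), true);
  for (int i = 0; i < subjects.size(); ++i)
    parse_subject_(subjects[i], (*ptr)[i]);
  return ptr;
}

static const SubjVec* get_subjects_(SEXP subjects, SubjVec& local) {
  if (TYPEOF(subjects) == EXTPTRSXP) {
    XPtr<SubjVec> ptr(subjects);
    return ptr.get();
  }
  List lst(subjects);
  local.resize(lst.size());
  for (int i = 0; i < lst.size(); ++i) parse_subject_(lst[i], local[i]);
  return &local;
}

// individual parameters: typical values x covariate terms x exp(eta)
static void indiv_params_(const ModelDef& M, const SubjData& S,
                          const arma::vec& eta, double* p) {
  for (int j = 0; j < 6; ++j) p[j] = M.theta(j);
  for (arma::uword e = 0; e < M.covtheta.n_elem; ++e) {
    int j = M.effpar(e);
    double x = S.covx(e);
    if (M.efftype(e) == 0) {
      double f = 1.0 + M.covtheta(e) * x;
      if (f <= 0.0) stop("invalid-effect: categorical covariate term 1 + theta * x is not positive");
      p[j] *= f;
    } else {
      p[j] *= std::pow(x / M.effref(e), M.covtheta(e));
    }
  }
  for (arma::uword k = 0; k < M.iiv.n_elem; ++k)
    p[M.iiv(k)] *= std::exp(eta(k));
}

static void pred_subject_(const ModelDef& M, const SubjData& S,
                          const arma::vec& eta, arma::vec& f) {
  double p[6];
  indiv_params_(M, S, eta, p);
  pred_profile_(p, S.dose, S.time, S.analyte, f);
}

// inner (conditional) objective:
//   sum_j [ (y_j - f_j)^2 / h_j + log h_j ] + sum_k eta_k^2 / omega2_k
// with h_j = sigma2[analyte_j] * f_j^2 + add2.
static double inner_obj_(const ModelDef& M, const SubjData& S,
                         const arma::vec& eta, arma::vec& f, arma::vec& h) {
  pred_subject_(M, S, eta, f);
  double acc = 0.0;
  for (arma::uword j = 0; j < f.n_elem; ++j) {
    double hj = M.sigma2(S.analyte(j)) * f(j) * f(j) + M.add2;
    if (hj <= 0.0) stop("residual variance is zero at a zero prediction; set a positive additive floor");
    h(j) = hj;
    double r = S.dv(j) - f(j);
    acc += r * r / hj + std::log(hj);
  }
  for (arma::uword k = 0; k < M.iiv.n_elem; ++k)
    if (M.omega2(k) > 1e-12) acc += eta(k) * eta(k) / M.omega2(k);
  return acc;
}

// ---------------------------------------------------------------------------
// inner solver: damped Gauss-Newton on the conditional objective.
// Active dimensions are those with omega2 > 1e-12; others stay pinned at 0.
// On return f, J (n_obs x n_active), h are evaluated at the mode.
// ---------------------------------------------------------------------------

static const double ETA_FD_H = 1e-4;

static void eta_jac_(const ModelDef& M, const SubjData& S, const arma::vec& eta,
                     const arma::uvec& act, arma::mat& J) {
  arma::vec fp_(S.time.n_elem), fm_(S.time.n_elem);
  for (arma::uword a = 0; a < act.n_elem; ++a) {
    arma::vec e1 = eta;
    e1(act(a)) += ETA_FD_H;
    pred_subject_(M, S, e1, fp_);
    e1(act(a)) -= 2.0 * ETA_FD_H;
    pred_subject_(M, S, e1, fm_);
    J.col(a) = (fp_ - fm_) / (2.0 * ETA_FD_H);
  }
}

static double inner_solve_(const ModelDef& M, const SubjData& S,
                           arma::vec& eta, arma::vec& f, arma::mat& J,
                           arma::vec& h, const arma::uvec& act, double tol,
                           int maxit, int& iters) {
  int n = S.time.n_elem;
  int na = act.n_elem;
  f.set_size(n);
  h.set_size(n);
  J.set_size(n, na);
  double obj = inner_obj_(M, S, eta, f, h);
  // a stale warm start can trap the solver; fall back to the prior mode
  // whenever it is no worse
  if (arma::norm(eta, "inf") > 0.0) {
    arma::vec f0(n), h0(n);
    arma::vec zero(eta.n_elem, arma::fill::zeros);
    double obj0 = inner_obj_(M, S, zero, f0, h0);
    if (!std::isfinite(obj) || obj0 < obj) {
      eta = zero;
      obj = obj0;
      f = f0;
      h = h0;
    }
  }
  iters = 0;
  if (na == 0) return obj;

  double lev = 0.0;  // Levenberg damping
  bool jac_current = false;
  for (int it = 0; it < maxit; ++it) {
    if (!jac_current) {
      eta_jac_(M, S, eta, act, J);
      jac_current = true;
    }
    arma::vec g(na, arma::fill::zeros);
    arma::mat B(na, na, arma::fill::zeros);
    for (int j = 0; j < n; ++j) {
      double r = S.dv(j) - f(j);
      double hj = h(j);
      double sf = 2.0 * M.sigma2(S.analyte(j)) * f(j);  // dh/df
      for (int a = 0; a < na; ++a) {
        double Jf = J(j, a);
        double hp = sf * Jf;  // dh/deta_a
        g(a) += -2.0 * r * Jf / hj - r * r * hp / (hj * hj) + hp / hj;
        for (int b = 0; b <= a; ++b) {
          double add = 2.0 * J(j, a) * J(j, b) / hj +
                       (sf * Jf) * (sf * J(j, b)) / (hj * hj);
          B(a, b) += add;
        }
      }
    }
    for (int a = 0; a < na; ++a) {
      double w2 = M.omega2(act(a));
      g(a) += 2.0 * eta(act(a)) / w2;
      B(a, a) += 2.0 / w2;
      for (int b = 0; b < a; ++b) B(b, a) = B(a, b);
    }
    if (arma::norm(g, "inf") < tol) break;

    bool moved = false;
    for (int tries = 0; tries < 8 && !moved; ++tries) {
      arma::mat Bd = B;
      if (lev > 0.0) Bd.diag() += lev * (arma::abs(B.diag()) + 1e-8);
      arma::mat Lc;
      bool okslv = arma::chol(Lc, Bd, "lower");
      arma::vec step;
      if (okslv) {
        step = -arma::solve(arma::trimatu(Lc.t()),
                            arma::solve(arma::trimatl(Lc), g));
      }
      if (okslv) {
        double alpha = 1.0;
        for (int ls = 0; ls < 12; ++ls) {
          arma::vec etry = eta;
          for (int a = 0; a < na; ++a) etry(act(a)) += alpha * step(a);
          arma::vec ftry(n), htry(n);
          double otry = inner_obj_(M, S, etry, ftry, htry);
          if (otry < obj - 1e-12 * std::fabs(obj)) {
            eta = etry;
            obj = otry;
            f = ftry;
            h = htry;
            moved = true;
            jac_current = false;
            break;
          }
          alpha *= 0.5;
        }
      }
      if (!moved) lev = (lev == 0.0) ? 1e-3 : lev * 10.0;
    }
    ++iters;
    if (!moved) break;   // cannot improve further (typically FD-noise floor)
    if (lev > 0.0) lev *= 0.1;
  }
  if (!jac_current) eta_jac_(M, S, eta, act, J);  // jacobian at the mode
  return obj;
}

// FOCEI linearized contribution for one subject (2*pi constant omitted):
//   C = J Omega_act J' + diag(h);  r = y - f + J eta_act
//   ofv_i = log|C| + r' C^-1 r
static double focei_contrib_(const ModelDef& M, const SubjData& S,
                             const arma::vec& eta, const arma::vec& f,
                             const arma::mat& J, const arma::vec& h,
                             const arma::uvec& act, int& nridge) {
  int n = S.time.n_elem;
  arma::mat C;
  if (act.n_elem > 0) {
    arma::vec w2(act.n_elem);
    arma::vec ea(act.n_elem);
    for (arma::uword a = 0; a < act.n_elem; ++a) {
      w2(a) = M.omega2(act(a));
      ea(a) = eta(act(a));
    }
    C = J * arma::diagmat(w2) * J.t();
    C.diag() += h;
    arma::vec r = S.dv - f + J * ea;
    arma::mat L;
    if (!arma::chol(L, C, "lower")) {
      C.diag() += 1e-10 * std::max(1.0, arma::mean(h));
      ++nridge;
      if (!arma::chol(L, C, "lower")) stop("numerical error: marginal covariance not positive definite");
    }
    arma::vec z = arma::solve(arma::trimatl(L), r);
    double logdet = 2.0 * arma::accu(arma::log(L.diag()));
    return logdet + arma::dot(z, z);
  }
  double acc = 0.0;
  for (int j = 0; j < n; ++j) {
    double r = S.dv(j) - f(j);
    acc += std::log(h(j)) + r * r / h(j);
  }
  return acc;
}

static arma::uvec active_dims_(const ModelDef& M) {
  std::vector<arma::uword> v;
  for (arma::uword k = 0; k < M.omega2.n_elem; ++k)
    if (M.omega2(k) > 1e-12) v.push_back(k);
  return arma::uvec(v);
}

// [[Rcpp::export]]
List cpp_focei(SEXP subjects, List model, NumericMatrix eta_warm,
               double inner_tol, int inner_maxit) {
  ModelDef M;
  parse_model_(model, M);
  check_params_(M.theta.memptr());
  SubjVec local;
  const SubjVec* SV = get_subjects_(subjects, local);
  int ns = SV->size();
  int neta = M.iiv.n_elem;
  if (eta_warm.nrow() != ns || eta_warm.ncol() != neta)
    stop("eta_warm has wrong dimensions");
  arma::uvec act = active_dims_(M);

  arma::mat eta_out(ns, neta, arma::fill::zeros);
  arma::vec ofv_i(ns, arma::fill::zeros);
  arma::vec innerobj(ns, arma::fill::zeros);
  IntegerVector iters(ns);
  int nridge = 0;

  for (int i = 0; i < ns; ++i) {
    const SubjData& S = (*SV)[i];
    if (S.time.n_elem == 0) continue;  // nothing observed: skip
    arma::vec eta(neta, arma::fill::zeros);
    for (int k = 0; k < neta; ++k) eta(k) = eta_warm(i, k);
    for (int k = 0; k < neta; ++k)
      if (M.omega2(k) <= 1e-12) eta(k) = 0.0;
    arma::vec f, h;
    arma::mat J;
    int it = 0;
    innerobj(i) = inner_solve_(M, S, eta, f, J, h, act, inner_tol, inner_maxit, it);
    iters[i] = it;
    ofv_i(i) = focei_contrib_(M, S, eta, f, J, h, act, nridge);
    for (int k = 0; k < neta; ++k) eta_out(i, k) = eta(k);
  }

  return List::create(_["ofv"] = arma::accu(ofv_i), _["ofv_i"] = wrap(ofv_i),
                      _["eta"] = wrap(eta_out), _["inner_obj"] = wrap(innerobj),
                      _["inner_iters"] = iters, _["n_ridge"] = nridge);
}

// single-subject inner problem (exported for eta_mode and oracles)
// [[Rcpp::export]]
List cpp_inner(List subject, List model, NumericVector eta0, double tol,
               int maxit) {
  ModelDef M;
  parse_model_(model, M);
  check_params_(M.theta.memptr());
  SubjData S;
  parse_subject_(subject, S);
  if (S.time.n_elem == 0) stop("subject has no retained observations");
  arma::uvec act = active_dims_(M);
  arma::vec eta = as<arma::vec>(eta0);
  arma::vec f, h;
  arma::mat J;
  int it = 0;
  double obj = inner_solve_(M, S, eta, f, J, h, act, tol, maxit, it);
  return List::create(_["eta"] = wrap(eta), _["objective"] = obj,
                      _["f"] = wrap(f), _["jac"] = wrap(J),
                      _["h"] = wrap(h), _["iterations"] = it);
}

// conditional objective at a fixed eta (no optimization) — oracle support
// [[Rcpp::export]]
double cpp_inner_objective(List subject, List model, NumericVector eta) {
  ModelDef M;
  parse_model_(model, M);
  SubjData S;
  parse_subject_(subject, S);
  arma::vec e = as<arma::vec>(eta);
  arma::vec f(S.time.n_elem), h(S.time.n_elem);
  return inner_obj_(M, S, e, f, h);
}

// predictions for all subjects at supplied etas (rows of eta matrix)
// [[Rcpp::export]]
NumericVector cpp_pop_pred(SEXP subjects, List model, NumericMatrix eta) {
  ModelDef M;
  parse_model_(model, M);
  check_params_(M.theta.memptr());
  SubjVec local;
  const SubjVec* SV = get_subjects_(subjects, local);
  int ns = SV->size();
  int neta = M.iiv.n_elem;
  if (eta.nrow() != ns || eta.ncol() != neta) stop("eta has wrong dimensions");
  std::vector<double> out;
  for (int i = 0; i < ns; ++i) {
    const SubjData& S = (*SV)[i];
    arma::vec e(neta);
    for (int k = 0; k < neta; ++k) e(k) = eta(i, k);
    arma::vec f(S.time.n_elem);
    pred_subject_(M, S, e, f);
    for (arma::uword j = 0; j < f.n_elem; ++j) out.push_back(f(j));
  }
  return wrap(out);
}

// GOF quantities at the eta modes:
//   PRED  = f(eta = 0) (covariate-adjusted typical prediction)
//   IPRED = f(eta-hat)
//   CWRES = C^{-1/2} (y - (f(eta-hat) - J eta-hat))
// [[Rcpp::export]]
List cpp_gof(SEXP subjects, List model, NumericMatrix eta) {
  ModelDef M;
  parse_model_(model, M);
  check_params_(M.theta.memptr());
  SubjVec local;
  const SubjVec* SV = get_subjects_(subjects, local);
  int ns = SV->size();
  int neta = M.iiv.n_elem;
  arma::uvec act = active_dims_(M);
  std::vector<double> pred, ipred, cwres;
  int nridge = 0;

  for (int i = 0; i < ns; ++i) {
    const SubjData& S = (*SV)[i];
    int n = S.time.n_elem;
    if (n == 0) continue;
    arma::vec e(neta, arma::fill::zeros);
    for (int k = 0; k < neta; ++k) e(k) = eta(i, k);
    arma::vec zero(neta, arma::fill::zeros);
    arma::vec f0(n), fhat(n), h(n);
    pred_subject_(M, S, zero, f0);
    pred_subject_(M, S, e, fhat);
    for (int j = 0; j < n; ++j)
      h(j) = M.sigma2(S.analyte(j)) * fhat(j) * fhat(j) + M.add2;
    arma::mat J(n, (int)act.n_elem);
    eta_jac_(M, S, e, act, J);

    arma::mat C;
    arma::vec res;
    if (act.n_elem > 0) {
      arma::vec w2((int)act.n_elem), ea((int)act.n_elem);
      for (arma::uword a = 0; a < act.n_elem; ++a) {
        w2(a) = M.omega2(act(a));
        ea(a) = e(act(a));
      }
      C = J * arma::diagmat(w2) * J.t();
      C.diag() += h;
      res = S.dv - (fhat - J * ea);
    } else {
      C = arma::diagmat(h);
      res = S.dv - fhat;
    }
    arma::vec eval;
    arma::mat evec;
    if (!arma::eig_sym(eval, evec, C)) stop("numerical error: eigendecomposition of marginal covariance failed");
    if (eval.min() <= 0.0) {
      C.diag() += 1e-10 * std::max(1.0, arma::mean(h));
      ++nridge;
      arma::eig_sym(eval, evec, C);
    }
    arma::vec w = evec.t() * res;
    w /= arma::sqrt(eval);
    arma::vec cw = evec * w;  // C^{-1/2} res (symmetric inverse square root)
    for (int j = 0; j < n; ++j) {
      pred.push_back(f0(j));
      ipred.push_back(fhat(j));
      cwres.push_back(cw(j));
    }
  }
  return List::create(_["PRED"] = wrap(pred), _["IPRED"] = wrap(ipred),
                      _["CWRES"] = wrap(cwres), _["n_ridge"] = nridge);
}
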