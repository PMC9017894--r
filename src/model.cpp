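// Log posterior, analytic gradient, and HMC transition kernel for the
// hierarchical trial-level learning model.
//
// Observation model: correct_i ~ Bernoulli(p_i) with
//   p_i = 0.5 + (0.5 - eps) * (1 - 2^(-(x_i / theta_p(t_i))^beta_p)),
//   theta_p(t) = exp(A_p + (S_p - A_p) * 2^(-(t - 1) / 10^{R_p})).
// Each component c in {A, S, R} has participant-level value
//   c_p = X[p,] . b_c + (mono terms) + sigma_c * z_{c,p},
// the monotone ordinal term being bv_c * cumzeta_c[level_p]
// (+ bav_c * age_p * cumzeta_c[level_p] when the interaction is on),
// and log beta_p = b_sh0 + sigma_sh * z_{sh,p}.
//
// Unconstrained parameter layout (see par_layout() on the R side):
//   bA(K) bS(K) bR(K) [bv(3)] [bav(3)] [r(3)] b_sh0 logsig(4)
//   zA(P) zS(P) zR(P) zsh(P) [le]

#include <Rcpp.h>
using namespace Rcpp;

static const double LN2 = 0.6931471805599453;
static const double LN10 = 2.302585092994046;
static const double HALF_LOG_2PI = 0.9189385332046727;

struct ModelData {
  IntegerVector y;       // correctness 0/1
  NumericVector x;       // SOA in seconds (> 0)
  NumericVector tt;      // trial index (>= 1)
  IntegerVector pid;     // 0-based participant index
  int n, P, K;
  NumericMatrix X;       // P x K participant-level design
  bool has_mono, mono_int, est_lapse;
  IntegerVector vlev;    // valence level 0/1/2 (if has_mono)
  NumericVector xage;    // age code per participant (for mono interaction)
  double lapse_fixed;
  NumericMatrix prior_b_mean, prior_b_sd;  // K x 3 (columns A, S, R)
  double prior_bv_sd, prior_shape_mean, prior_shape_sd, prior_sigma_sd;
  double prior_lapse_a, prior_lapse_b;
};

static ModelData unpack(const List& data) {
  ModelData d;
  d.y = data["y"]; d.x = data["x"]; d.tt = data["tt"]; d.pid = data["pid"];
  d.n = d.y.size();
  d.P = as<int>(data["P"]);
  d.X = as<NumericMatrix>(data["X"]);
  d.K = d.X.ncol();
  d.has_mono = as<bool>(data["has_mono"]);
  d.mono_int = as<bool>(data["mono_int"]);
  d.est_lapse = as<bool>(data["est_lapse"]);
  d.vlev = data["vlev"];
  d.xage = data["xage"];
  d.lapse_fixed = as<double>(data["lapse"]);
  d.prior_b_mean = as<NumericMatrix>(data["prior_b_mean"]);
  d.prior_b_sd = as<NumericMatrix>(data["prior_b_sd"]);
  d.prior_bv_sd = as<double>(data["prior_bv_sd"]);
  d.prior_shape_mean = as<double>(data["prior_shape_mean"]);
  d.prior_shape_sd = as<double>(data["prior_shape_sd"]);
  d.prior_sigma_sd = as<double>(data["prior_sigma_sd"]);
  d.prior_lapse_a = as<double>(data["prior_lapse_a"]);
  d.prior_lapse_b = as<double>(data["prior_lapse_b"]);
  return d;
}

static int n_par(const ModelData& d) {
  int np = 3 * d.K + 1 + 4 + 4 * d.P;
  if (d.has_mono) np += 3 + 3;            // bv + simplex logits
  if (d.has_mono && d.mono_int) np += 3;  // bav
  if (d.est_lapse) np += 1;
  return np;
}

static inline double sigmoid(double x) {
  return x >= 0 ? 1.0 / (1.0 + std::exp(-x))
                : std::exp(x) / (1.0 + std::exp(x));
}

// Evaluates log density (likelihood, optionally + prior with transform
// Jacobians) and, when grad is non-null, accumulates the full gradient.
static double lp_impl(const ModelData& d, const NumericVector& par,
                      bool include_prior, std::vector<double>* grad) {
  const int K = d.K, P = d.P;
  int off = 0;
  const int iA = off; off += K;
  const int iS = off; off += K;
  const int iR = off; off += K;
  int ibv = -1, ibav = -1, ir = -1;
  if (d.has_mono) { ibv = off; off += 3; }
  if (d.has_mono && d.mono_int) { ibav = off; off += 3; }
  if (d.has_mono) { ir = off; off += 3; }
  const int ish = off; off += 1;
  const int isig = off; off += 4;
  const int izA = off; off += P;
  const int izS = off; off += P;
  const int izR = off; off += P;
  const int izsh = off; off += P;
  int ile = -1;
  if (d.est_lapse) { ile = off; off += 1; }

  double sig[4];
  for (int j = 0; j < 4; ++j) sig[j] = std::exp(par[isig + j]);
  double zeta1[3] = {0.5, 0.5, 0.5};
  if (d.has_mono)
    for (int c = 0; c < 3; ++c) zeta1[c] = sigmoid(par[ir + c]);
  double eps = d.est_lapse ? 0.5 * sigmoid(par[ile]) : d.lapse_fixed;
  const double cc = 0.5 - eps;

  // participant-level component values
  std::vector<double> Ap(P), Sp(P), Rp(P), lbp(P), czA(P), czS(P), czR(P);
  for (int p = 0; p < P; ++p) {
    double a = 0, s = 0, r = 0;
    for (int k = 0; k < K; ++k) {
      const double xk = d.X(p, k);
      a += xk * par[iA + k];
      s += xk * par[iS + k];
      r += xk * par[iR + k];
    }
    if (d.has_mono) {
      const int lv = d.vlev[p];
      czA[p] = lv == 0 ? 0.0 : (lv == 1 ? zeta1[0] : 1.0);
      czS[p] = lv == 0 ? 0.0 : (lv == 1 ? zeta1[1] : 1.0);
      czR[p] = lv == 0 ? 0.0 : (lv == 1 ? zeta1[2] : 1.0);
      double mA = par[ibv + 0], mS = par[ibv + 1], mR = par[ibv + 2];
      if (d.mono_int) {
        mA += par[ibav + 0] * d.xage[p];
        mS += par[ibav + 1] * d.xage[p];
        mR += par[ibav + 2] * d.xage[p];
      }
      a += mA * czA[p]; s += mS * czS[p]; r += mR * czR[p];
    }
    Ap[p] = a + sig[0] * par[izA + p];
    Sp[p] = s + sig[1] * par[izS + p];
    Rp[p] = r + sig[2] * par[izR + p];
    lbp[p] = par[ish] + sig[3] * par[izsh + p];
  }

  std::vector<double> t10(P), betap(P);
  for (int p = 0; p < P; ++p) {
    t10[p] = std::pow(10.0, -Rp[p]);
    betap[p] = std::exp(lbp[p]);
  }

  // per-participant gradient accumulators on (A, S, R, log beta, eps)
  std::vector<double> gA, gS, gR, gLB;
  double gEPS = 0.0;
  if (grad) { gA.assign(P, 0); gS.assign(P, 0); gR.assign(P, 0); gLB.assign(P, 0); }

  double lp = 0.0;
  for (int i = 0; i < d.n; ++i) {
    const int p = d.pid[i];
    const double m = (d.tt[i] - 1.0) * t10[p];
    const double q = std::exp(-LN2 * m);
    const double lnth = Ap[p] + (Sp[p] - Ap[p]) * q;
    const double a = betap[p] * (std::log(d.x[i]) - lnth);
    double w, uw, u;
    if (a > 25.0) {            // u astronomically large: PF fully saturated
      w = 0.0; uw = 0.0; u = 0.0;
    } else {
      u = std::exp(a);
      w = std::exp(-LN2 * u);
      uw = u * w;
    }
    const double pcor = 1.0 - eps - cc * w;
    double dLdp;
    if (d.y[i] == 1) {
      lp += std::log(pcor);
      dLdp = 1.0 / pcor;
    } else {
      const double perr = eps + cc * w;
      lp += std::log(perr);
      dLdp = -1.0 / perr;
    }
    if (grad) {
      // dL/du = dLdp * cc * LN2 * w; du/dlnth = -beta * u
      const double guw = dLdp * cc * LN2 * uw;  // = dL/du * u
      const double gl = -betap[p] * guw;        // = dL/d(log theta)
      gA[p] += gl * (1.0 - q);
      gS[p] += gl * q;
      gR[p] += gl * (Sp[p] - Ap[p]) * q * LN2 * LN10 * m;
      gLB[p] += guw * a;
      if (d.est_lapse) gEPS += dLdp * (w - 1.0);
    }
  }

  std::vector<double> gdummy;
  std::vector<double>& g = grad ? *grad : gdummy;
  if (grad) {
    g.assign(n_par(d), 0.0);
    for (int p = 0; p < P; ++p) {
      for (int k = 0; k < K; ++k) {
        const double xk = d.X(p, k);
        g[iA + k] += gA[p] * xk;
        g[iS + k] += gS[p] * xk;
        g[iR + k] += gR[p] * xk;
      }
      if (d.has_mono) {
        g[ibv + 0] += gA[p] * czA[p];
        g[ibv + 1] += gS[p] * czS[p];
        g[ibv + 2] += gR[p] * czR[p];
        if (d.mono_int) {
          g[ibav + 0] += gA[p] * czA[p] * d.xage[p];
          g[ibav + 1] += gS[p] * czS[p] * d.xage[p];
          g[ibav + 2] += gR[p] * czR[p] * d.xage[p];
        }
        if (d.vlev[p] == 1) {
          double mA = par[ibv + 0], mS = par[ibv + 1], mR = par[ibv + 2];
          if (d.mono_int) {
            mA += par[ibav + 0] * d.xage[p];
            mS += par[ibav + 1] * d.xage[p];
            mR += par[ibav + 2] * d.xage[p];
          }
          g[ir + 0] += gA[p] * mA * zeta1[0] * (1.0 - zeta1[0]);
          g[ir + 1] += gS[p] * mS * zeta1[1] * (1.0 - zeta1[1]);
          g[ir + 2] += gR[p] * mR * zeta1[2] * (1.0 - zeta1[2]);
        }
      }
      g[izA + p] += gA[p] * sig[0];
      g[izS + p] += gS[p] * sig[1];
      g[izR + p] += gR[p] * sig[2];
      g[izsh + p] += gLB[p] * sig[3];
      g[isig + 0] += gA[p] * par[izA + p] * sig[0];
      g[isig + 1] += gS[p] * par[izS + p] * sig[1];
      g[isig + 2] += gR[p] * par[izR + p] * sig[2];
      g[isig + 3] += gLB[p] * par[izsh + p] * sig[3];
      g[ish] += gLB[p];
    }
    if (d.est_lapse) {
      // d eps / d le for eps = 0.5 * sigmoid(le)
      const double deps = eps * (1.0 - 2.0 * eps);
      g[ile] += gEPS * deps;
    }
  }

  if (include_prior) {
    // fixed effects per component
    for (int c = 0; c < 3; ++c) {
      const int base = c == 0 ? iA : (c == 1 ? iS : iR);
      for (int k = 0; k < K; ++k) {
        const double mu = d.prior_b_mean(k, c), sd = d.prior_b_sd(k, c);
        const double zd = (par[base + k] - mu) / sd;
        lp += -0.5 * zd * zd - std::log(sd) - HALF_LOG_2PI;
        if (grad) g[base + k] += -zd / sd;
      }
    }
    if (d.has_mono) {
      const double sd = d.prior_bv_sd;
      for (int c = 0; c < 3; ++c) {
        double zd = par[ibv + c] / sd;
        lp += -0.5 * zd * zd - std::log(sd) - HALF_LOG_2PI;
        if (grad) g[ibv + c] += -zd / sd;
        if (d.mono_int) {
          zd = par[ibav + c] / sd;
          lp += -0.5 * zd * zd - std::log(sd) - HALF_LOG_2PI;
          if (grad) g[ibav + c] += -zd / sd;
        }
        // Dirichlet(1,1) on (zeta1, 1 - zeta1) + logit Jacobian
        lp += std::log(zeta1[c]) + std::log(1.0 - zeta1[c]);
        if (grad) g[ir + c] += 1.0 - 2.0 * zeta1[c];
      }
    }
    {
      const double zd = (par[ish] - d.prior_shape_mean) / d.prior_shape_sd;
      lp += -0.5 * zd * zd - std::log(d.prior_shape_sd) - HALF_LOG_2PI;
      if (grad) g[ish] += -zd / d.prior_shape_sd;
    }
    for (int j = 0; j < 4; ++j) {
      // half-normal(0, s) on sigma, log transform Jacobian
      const double s0 = d.prior_sigma_sd;
      lp += -0.5 * sig[j] * sig[j] / (s0 * s0) + par[isig + j];
      if (grad) g[isig + j] += -sig[j] * sig[j] / (s0 * s0) + 1.0;
    }
    for (int p = 0; p < P; ++p) {
      lp += -0.5 * (par[izA + p] * par[izA + p] +
                    par[izS + p] * par[izS + p] +
                    par[izR + p] * par[izR + p] +
                    par[izsh + p] * par[izsh + p]) - 4.0 * HALF_LOG_2PI;
      if (grad) {
        g[izA + p] += -par[izA + p];
        g[izS + p] += -par[izS + p];
        g[izR + p] += -par[izR + p];
        g[izsh + p] += -par[izsh + p];
      }
    }
    if (d.est_lapse) {
      // Beta(a0, b0) on v = 2 * eps, logit-scaled, with Jacobian
      const double v = 2.0 * eps;
      lp += (d.prior_lapse_a - 1.0) * std::log(v) +
            (d.prior_lapse_b - 1.0) * std::log(1.0 - v) +
            std::log(v) + std::log(1.0 - v);
      if (grad) g[ile] += d.prior_lapse_a * (1.0 - v) - d.prior_lapse_b * v;
    }
  }
  return lp;
}

// [[Rcpp::export]]
double pl_lp(NumericVector par, List data, bool include_prior = true) {
  ModelData d = unpack(data);
  if ((int)par.size() != n_par(d)) stop("parameter vector has wrong length");
  return lp_impl(d, par, include_prior, nullptr);
}

// [[Rcpp::export]]
List pl_lp_grad(NumericVector par, List data, bool include_prior = true) {
  ModelData d = unpack(data);
  if ((int)par.size() != n_par(d)) stop("parameter vector has wrong length");
  std::vector<double> g;
  double lp = lp_impl(d, par, include_prior, &g);
  return List::create(_["lp"] = lp, _["grad"] = NumericVector(g.begin(), g.end()));
}

// [[Rcpp::export]]
int pl_n_par(List data) {
  return n_par(unpack(data));
}

// One HMC chain with dual-averaging step-size adaptation and diagonal
// mass-matrix estimation during warmup. Uses R's RNG so results are
// reproducible under set.seed().
// [[Rcpp::export]]
List pl_hmc(List data, NumericVector init, int n_warmup, int n_iter,
            double init_step = 0.05, double target_accept = 0.8,
            int max_leapfrog = 32, double max_deltaH = 1000.0) {
  ModelData d = unpack(data);
  const int D = n_par(d);
  if ((int)init.size() != D) stop("init has wrong length");

  NumericVector th = clone(init);
  std::vector<double> grad;
  double lp = lp_impl(d, th, true, &grad);
  if (!std::isfinite(lp)) stop("non-finite log density at the initial value");

  std::vector<double> minv(D, 1.0);  // inverse mass = posterior variance
  // dual averaging state (Hoffman & Gelman defaults); the counter restarts
  // when the metric is updated so the step size re-adapts under it
  double log_eps = std::log(init_step), log_eps_bar = std::log(init_step);
  double Hbar = 0.0, mu = std::log(10.0 * init_step);
  double da_count = 0.0;
  const double da_gamma = 0.05, da_t0 = 10.0, da_kappa = 0.75;

  const int w_var_lo = std::max(1, (int)(0.30 * n_warmup));
  const int w_var_hi = std::max(w_var_lo + 1, (int)(0.70 * n_warmup));
  std::vector<double> vsum(D, 0.0), vsum2(D, 0.0);
  int vcount = 0;

  NumericMatrix draws(n_iter, D);
  NumericVector lp_out(n_iter), accept_out(n_iter);
  int divergences = 0;
  double accept_sum = 0.0;

  std::vector<double> th_prop(D), p0(D), pm(D), gprop(grad);

  for (int it = 0; it < n_warmup + n_iter; ++it) {
    const bool warm = it < n_warmup;
    const double eps = warm ? std::exp(log_eps) : std::exp(log_eps_bar);
    const int L = 1 + (int)std::floor(R::unif_rand() * max_leapfrog);

    double ke0 = 0.0;
    for (int j = 0; j < D; ++j) {
      p0[j] = R::norm_rand() / std::sqrt(minv[j]);
      ke0 += 0.5 * p0[j] * p0[j] * minv[j];
    }
    const double H0 = -lp + ke0;

    for (int j = 0; j < D; ++j) { th_prop[j] = th[j]; pm[j] = p0[j]; }
    double lp_prop = lp;
    gprop = grad;
    bool bad = false;
    for (int l = 0; l < L; ++l) {
      for (int j = 0; j < D; ++j) pm[j] += 0.5 * eps * gprop[j];
      for (int j = 0; j < D; ++j) th_prop[j] += eps * minv[j] * pm[j];
      NumericVector thv(th_prop.begin(), th_prop.end());
      lp_prop = lp_impl(d, thv, true, &gprop);
      if (!std::isfinite(lp_prop)) { bad = true; break; }
      for (int j = 0; j < D; ++j) pm[j] += 0.5 * eps * gprop[j];
    }

    double alpha;
    if (bad) {
      alpha = 0.0;
    } else {
      double ke1 = 0.0;
      for (int j = 0; j < D; ++j) ke1 += 0.5 * pm[j] * pm[j] * minv[j];
      const double dH = (-lp_prop + ke1) - H0;
      if (!std::isfinite(dH) || dH > max_deltaH) {
        alpha = 0.0;
        if (!warm) ++divergences;
      } else {
        alpha = dH < 0 ? 1.0 : std::exp(-dH);
      }
    }
    if (bad && !warm) ++divergences;

    if (alpha > 0 && R::unif_rand() < alpha) {
      for (int j = 0; j < D; ++j) th[j] = th_prop[j];
      lp = lp_prop;
      grad = gprop;
    }

    if (warm) {
      // dual averaging toward the target acceptance rate
      da_count += 1.0;
      Hbar = (1.0 - 1.0 / (da_count + da_t0)) * Hbar +
             (target_accept - alpha) / (da_count + da_t0);
      log_eps = mu - std::sqrt(da_count) / da_gamma * Hbar;
      const double w = std::pow(da_count, -da_kappa);
      log_eps_bar = w * log_eps + (1.0 - w) * log_eps_bar;

      if (it >= w_var_lo && it < w_var_hi) {
        for (int j = 0; j < D; ++j) {
          vsum[j] += th[j];
          vsum2[j] += th[j] * th[j];
        }
        ++vcount;
      }
      if (it == w_var_hi - 1 && vcount > 10) {
        for (int j = 0; j < D; ++j) {
          const double mn = vsum[j] / vcount;
          double v = vsum2[j] / vcount - mn * mn;
          v = v * vcount / (vcount - 1.0);
          minv[j] = std::max(v, 1e-8) + 1e-6;
        }
        // restart step-size adaptation from scratch under the new metric
        mu = std::log(10.0 * std::exp(log_eps));
        log_eps_bar = log_eps;
        Hbar = 0.0;
        da_count = 0.0;
      }
    } else {
      const int k = it - n_warmup;
      for (int j = 0; j < D; ++j) draws(k, j) = th[j];
      lp_out[k] = lp;
      accept_out[k] = alpha;
      accept_sum += alpha;
    }
    if (it % 64 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["draws"] = draws, _["lp"] = lp_out,
    _["accept_rate"] = accept_sum / std::max(1, n_iter),
    _["divergences"] = divergences,
    _["step_size"] = std::exp(log_eps_bar),
    _["inv_mass"] = NumericVector(minv.begin(), minv.end()));
}
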