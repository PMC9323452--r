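// Hidden-Markov likelihood engine and adaptive Metropolis-within-Gibbs
// sampler for the multi-state capture-recapture model with correlated
// temporal random effects.
//
// Latent states are coded 0..S-1 (0 = juvenile, then optional
// pre_breeder / non_breeder / failed_breeder, then successful_breeder),
// dead = S. The per-individual likelihood conditions on first capture,
// runs the forward recursion over the detection span, and closes with an
// exact probability-of-no-future-detection term chi shared by all
// individuals with the same (last year, age, state) — making single-year
// parameter updates cheap.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double invlogit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

struct Engine {
  int T, S, A, K, ctype, family, bfa, det_year;
  int pre, non, fail, succ;
  int col_psi, col_pi, col_om;
  std::vector<int> cls_phi, cls_psi, cls_pi, cls_om, cls_p;
  std::vector<int> i_mu;
  std::vector<int> i_fphi, i_fpsi, i_fpi, i_fom, i_fp;
  std::vector<int> i_gphi, i_gpsi, i_gpi, i_gp;
  int i_logsigom, i_alpha0, i_alphap0, i_L0, i_logdelta0, i_logsigp;
  std::vector<int> L_row, L_col;

  inline int tidx(int y, int a, int s, int s2) const {
    return ((y * A + (a - 1)) * S + s) * (S + 1) + s2;
  }
  inline int pidx(int y, int a, int s) const {
    return (y * A + (a - 1)) * S + s;
  }
  inline int oidx(int y, int a) const { return y * A + (a - 1); }
  inline int cidx(int t, int a, int s) const {
    return (t * (A + 1) + a) * S + s;
  }
  inline double alpha(const std::vector<double>& th, int t, int k) const {
    return th[i_alpha0 + k * T + (t - 1)];
  }
};

struct Data {
  int n;
  std::vector<int> entry, entry_age, entry_state, tlast, off;
  std::vector<int> obs_det, obs_state, obs_count;
  // chi groups: individuals pooled by (last detection year, age, state)
  std::vector<int> gt, ga, gs, gn;
};

static std::vector<int> ivec(SEXP x) {
  IntegerVector v(x);
  return std::vector<int>(v.begin(), v.end());
}

static Engine makeEngine(List e) {
  Engine g;
  g.T = e["T"]; g.S = e["S"]; g.A = e["A"]; g.K = e["K"];
  g.ctype = e["ctype"]; g.family = e["family"]; g.bfa = e["bfa"];
  g.det_year = e["det_year"];
  g.pre = e["pre"]; g.non = e["non"]; g.fail = e["fail"]; g.succ = e["succ"];
  g.col_psi = e["col_psi"]; g.col_pi = e["col_pi"]; g.col_om = e["col_om"];
  g.cls_phi = ivec(e["cls_phi"]); g.cls_psi = ivec(e["cls_psi"]);
  g.cls_pi = ivec(e["cls_pi"]); g.cls_om = ivec(e["cls_om"]);
  g.cls_p = ivec(e["cls_p"]);
  g.i_mu = ivec(e["i_mu"]);
  g.i_fphi = ivec(e["i_fphi"]); g.i_fpsi = ivec(e["i_fpsi"]);
  g.i_fpi = ivec(e["i_fpi"]); g.i_fom = ivec(e["i_fom"]);
  g.i_fp = ivec(e["i_fp"]);
  g.i_gphi = ivec(e["i_gphi"]); g.i_gpsi = ivec(e["i_gpsi"]);
  g.i_gpi = ivec(e["i_gpi"]); g.i_gp = ivec(e["i_gp"]);
  g.i_logsigom = as<IntegerVector>(e["i_logsigom"])[0];
  g.i_alpha0 = e["i_alpha0"]; g.i_alphap0 = e["i_alphap0"];
  g.i_L0 = e["i_L0"]; g.i_logdelta0 = e["i_logdelta0"];
  g.i_logsigp = as<IntegerVector>(e["i_logsigp"])[0];
  g.L_row = ivec(e["L_row"]); g.L_col = ivec(e["L_col"]);
  return g;
}

static Data makeData(List d, const Engine& g) {
  Data x;
  x.n = d["n"];
  x.entry = ivec(d["entry"]); x.entry_age = ivec(d["entry_age"]);
  x.entry_state = ivec(d["entry_state"]); x.tlast = ivec(d["tlast"]);
  x.off = ivec(d["off"]);
  x.obs_det = ivec(d["obs_det"]); x.obs_state = ivec(d["obs_state"]);
  x.obs_count = ivec(d["obs_count"]);
  std::vector<int> counts((g.T + 1) * (g.A + 1) * g.S, 0);
  for (int i = 0; i < x.n; ++i) {
    int a = std::min(x.entry_age[i] + x.tlast[i] - x.entry[i], g.A);
    int s = x.tlast[i] > x.entry[i]
      ? x.obs_state[x.off[i] + (x.tlast[i] - x.entry[i] - 1)]
      : x.entry_state[i];
    counts[g.cidx(x.tlast[i], a, s)] += 1;
  }
  for (int t = 1; t <= g.T; ++t)
    for (int a = 0; a <= g.A; ++a)
      for (int s = 0; s < g.S; ++s) {
        int c = counts[g.cidx(t, a, s)];
        if (c > 0) {
          x.gt.push_back(t); x.ga.push_back(a); x.gs.push_back(s);
          x.gn.push_back(c);
        }
      }
  return x;
}

struct Arrays {
  std::vector<double> trans, pdet, ometa;
  void init(const Engine& g) {
    trans.assign((g.T + 1) * g.A * g.S * (g.S + 1), 0.0);
    pdet.assign((g.T + 1) * g.A * g.S, 0.0);
    ometa.assign((g.T + 1) * g.A, 0.0);
  }
};

// transition/observation parameters governing year y (the interval into
// y and the reproduction/detection season at y)
static void computeYear(const Engine& g, const std::vector<double>& th,
                        int y, Arrays& ar) {
  const double mu_phi = th[g.i_mu[0]], mu_psi = th[g.i_mu[1]],
               mu_pi = th[g.i_mu[2]], mu_om = th[g.i_mu[3]],
               mu_p = th[g.i_mu[4]];
  const int srow = (g.ctype == 1) ? y : y - 1;
  const double aj = g.alpha(th, srow, 0), aad = g.alpha(th, srow, 1);
  const double apsi = g.col_psi >= 0 ? g.alpha(th, y, g.col_psi) : 0.0;
  const double api = g.col_pi >= 0 ? g.alpha(th, y, g.col_pi) : 0.0;
  const double aom = g.col_om >= 0 ? g.alpha(th, y, g.col_om) : 0.0;
  const double ap = g.det_year ? th[g.i_alphap0 + (y - 1)] : 0.0;
  for (int a = 1; a <= g.A; ++a) {
    const double fphi = th[g.i_fphi[g.cls_phi[a - 1] - 1]];
    const double fpsi = th[g.i_fpsi[g.cls_psi[a - 1] - 1]];
    const double fpi = th[g.i_fpi[g.cls_pi[a - 1] - 1]];
    const double fom = th[g.i_fom[g.cls_om[a - 1] - 1]];
    const double fp = th[g.i_fp[g.cls_p[a - 1] - 1]];
    for (int s = 0; s < g.S; ++s) {
      const double asurv = (a == 1) ? aj : aad;
      const double phi = invlogit(mu_phi + fphi + th[g.i_gphi[s]] + asurv);
      double psi;
      if (a < g.bfa) psi = 0.0;
      else if (g.col_psi >= 0)
        psi = invlogit(mu_psi + fpsi + th[g.i_gpsi[s]] + apsi);
      else psi = 1.0;
      const double pi = (g.col_pi >= 0)
        ? invlogit(mu_pi + fpi + th[g.i_gpi[s]] + api) : 1.0;
      double* row = &ar.trans[g.tidx(y, a, s, 0)];
      for (int s2 = 0; s2 <= g.S; ++s2) row[s2] = 0.0;
      row[g.S] = 1.0 - phi;
      const double nb = phi * (1.0 - psi);
      if (nb > 0.0) {
        const int dest = ((s == 0 || s == g.pre) && g.pre >= 0) ? g.pre : g.non;
        row[dest] += nb;
      }
      const double bf = phi * psi * (1.0 - pi);
      if (bf > 0.0) row[g.fail] += bf;
      row[g.succ] += phi * psi * pi;
    }
    for (int s2 = 0; s2 < g.S; ++s2)
      ar.pdet[g.pidx(y, a, s2)] = invlogit(mu_p + fp + th[g.i_gp[s2]] + ap);
    ar.ometa[g.oidx(y, a)] = mu_om + fom + aom;
  }
}

static void computeAll(const Engine& g, const std::vector<double>& th,
                       Arrays& ar) {
  for (int y = 2; y <= g.T; ++y) computeYear(g, th, y, ar);
}

// chi[t][a][s]: probability of never being detected again given state s
// and age a at year t
static void computeChi(const Engine& g, const Arrays& ar,
                       std::vector<double>& chi) {
  for (int a = 0; a <= g.A; ++a)
    for (int s = 0; s < g.S; ++s) chi[g.cidx(g.T, a, s)] = 1.0;
  for (int t = g.T - 1; t >= 1; --t) {
    for (int a = 0; a <= g.A; ++a) {
      const int a1 = std::min(a + 1, g.A);
      for (int s = 0; s < g.S; ++s) {
        const double* row = &ar.trans[g.tidx(t + 1, a1, s, 0)];
        double acc = row[g.S];
        for (int s2 = 0; s2 < g.S; ++s2) {
          if (row[s2] > 0.0)
            acc += row[s2] * (1.0 - ar.pdet[g.pidx(t + 1, a1, s2)]) *
                   chi[g.cidx(t + 1, std::min(a + 1, g.A), s2)];
        }
        chi[g.cidx(t, a, s)] = acc;
      }
    }
  }
}

static double chiTerm(const Engine& g, const Data& d,
                      const std::vector<double>& chi) {
  double out = 0.0;
  for (size_t i = 0; i < d.gt.size(); ++i) {
    const double c = chi[g.cidx(d.gt[i], d.ga[i], d.gs[i])];
    if (c <= 0.0) return R_NegInf;
    out += d.gn[i] * std::log(c);
  }
  return out;
}

static double countLogdens(const Engine& g, const std::vector<double>& th,
                           double eta, int cnt) {
  switch (g.family) {
    case 0: // fixed single offspring
      return cnt == 1 ? 0.0 : R_NegInf;
    case 1: { // Bernoulli on the extra offspring
      const double q = invlogit(eta);
      if (cnt == 2) return std::log(q);
      if (cnt == 1) return std::log1p(-q);
      return R_NegInf;
    }
    case 2: { // normal truncated at 0, identity link
      const double sig = std::exp(th[g.i_logsigom]);
      return R::dnorm(cnt, eta, sig, 1) -
             R::pnorm(0.0, eta, sig, 0, 1);
    }
    case 3: { // Poisson truncated at 0, log link
      if (cnt < 1) return R_NegInf;
      const double lam = std::exp(eta);
      return cnt * eta - lam - R::lgammafn(cnt + 1.0) -
             std::log1p(-std::exp(-lam));
    }
  }
  return R_NegInf;
}

// forward pass over the detection span (entry+1 .. last detection);
// the after-last-detection part lives in the chi term
static double fwdInd(const Engine& g, const Data& d,
                     const std::vector<double>& th, const Arrays& ar, int i) {
  const int e = d.entry[i], tl = d.tlast[i];
  if (tl <= e) return 0.0;
  std::vector<double> dist(g.S + 1, 0.0), w(g.S + 1, 0.0);
  dist[d.entry_state[i]] = 1.0;
  double ll = 0.0;
  const int off = d.off[i];
  for (int y = e + 1; y <= tl; ++y) {
    const int a1 = std::min(d.entry_age[i] + y - e, g.A);
    for (int s2 = 0; s2 <= g.S; ++s2) w[s2] = 0.0;
    for (int s = 0; s < g.S; ++s) {
      const double ds = dist[s];
      if (ds <= 0.0) continue;
      const double* row = &ar.trans[g.tidx(y, a1, s, 0)];
      for (int s2 = 0; s2 <= g.S; ++s2) w[s2] += ds * row[s2];
    }
    w[g.S] += dist[g.S];
    const int j = off + (y - e - 1);
    if (d.obs_det[j] == 1) {
      const int so = d.obs_state[j];
      double val = w[so] * ar.pdet[g.pidx(y, a1, so)];
      const int cnt = d.obs_count[j];
      if (cnt >= 0 && val > 0.0)
        val *= std::exp(countLogdens(g, th, ar.ometa[g.oidx(y, a1)], cnt));
      if (val <= 0.0 || !std::isfinite(val)) return R_NegInf;
      ll += std::log(val);
      for (int s2 = 0; s2 <= g.S; ++s2) dist[s2] = 0.0;
      dist[so] = 1.0;
    } else {
      double c = w[g.S];
      for (int s2 = 0; s2 < g.S; ++s2) {
        w[s2] *= 1.0 - ar.pdet[g.pidx(y, a1, s2)];
        c += w[s2];
      }
      if (c <= 0.0) return R_NegInf;
      ll += std::log(c);
      for (int s2 = 0; s2 <= g.S; ++s2) dist[s2] = w[s2] / c;
    }
  }
  return ll;
}

// [[Rcpp::export]]
List cpp_dataset_loglik(List engineL, List dataL, NumericVector theta) {
  Engine g = makeEngine(engineL);
  Data d = makeData(dataL, g);
  std::vector<double> th(theta.begin(), theta.end());
  Arrays ar; ar.init(g);
  computeAll(g, th, ar);
  std::vector<double> chi((g.T + 1) * (g.A + 1) * g.S, 1.0);
  computeChi(g, ar, chi);
  NumericVector per(d.n);
  double tot = 0.0;
  for (int i = 0; i < d.n; ++i) {
    const int a = std::min(d.entry_age[i] + d.tlast[i] - d.entry[i], g.A);
    const int s = d.tlast[i] > d.entry[i]
      ? d.obs_state[d.off[i] + (d.tlast[i] - d.entry[i] - 1)]
      : d.entry_state[i];
    const double cc = chi[g.cidx(d.tlast[i], a, s)];
    per[i] = fwdInd(g, d, th, ar, i) + (cc > 0 ? std::log(cc) : R_NegInf);
    tot += per[i];
  }
  return List::create(_["total"] = tot, _["per_individual"] = per);
}

// ---------------------------------------------------------------------
// sampler

struct Hyper {
  // Sigma = D L L' D with D = diag(exp(logdelta)); Omega = Sigma^{-1}
  std::vector<double> Omega;
  double logdet;
  bool ok;
};

static Hyper buildHyper(const Engine& g, const std::vector<double>& th) {
  const int K = g.K;
  Hyper h; h.Omega.assign(K * K, 0.0); h.ok = true; h.logdet = 0.0;
  std::vector<double> M(K * K, 0.0);
  for (size_t e = 0; e < g.L_row.size(); ++e) {
    const int r = g.L_row[e], c = g.L_col[e];
    // diagonal loadings are stored on the log scale (positivity)
    const double v = (r == c) ? std::exp(th[g.i_L0 + e]) : th[g.i_L0 + e];
    M[r * K + c] = v * std::exp(th[g.i_logdelta0 + r]);
  }
  for (int k = 0; k < K; ++k) {
    if (std::fabs(M[k * K + k]) < 1e-10) { h.ok = false; return h; }
    h.logdet += 2.0 * std::log(std::fabs(M[k * K + k]));
  }
  // invert lower-triangular M by forward substitution
  std::vector<double> Mi(K * K, 0.0);
  for (int c = 0; c < K; ++c) {
    Mi[c * K + c] = 1.0 / M[c * K + c];
    for (int r = c + 1; r < K; ++r) {
      double acc = 0.0;
      for (int j = c; j < r; ++j) acc += M[r * K + j] * Mi[j * K + c];
      Mi[r * K + c] = -acc / M[r * K + r];
    }
  }
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) {
      double acc = 0.0;
      for (int k = std::max(i, j); k < K; ++k)
        acc += Mi[k * K + i] * Mi[k * K + j];
      h.Omega[i * K + j] = acc;
    }
  return h;
}

static double alphaRowQuad(const Engine& g, const std::vector<double>& th,
                           const Hyper& h, int t) {
  double q = 0.0;
  for (int j = 0; j < g.K; ++j) {
    const double aj = g.alpha(th, t, j);
    for (int k = 0; k < g.K; ++k)
      q += aj * h.Omega[j * g.K + k] * g.alpha(th, t, k);
  }
  return q;
}

static double slotLogprior(int code, double mean, double sd, double v) {
  if (code == 1) {
    const double z = (v - mean) / sd;
    return -0.5 * z * z;
  }
  if (code == 2) { // half-normal on exp(v), with log-scale Jacobian
    const double s = std::exp(v) / sd;
    return -0.5 * s * s + v;
  }
  if (code == 3) { // chi with df = mean on exp(v), log-scale Jacobian
    return mean * v - 0.5 * std::exp(2.0 * v);
  }
  return 0.0;
}

// [[Rcpp::export]]
List cpp_run_chain(List engineL, List dataL, NumericVector theta0,
                   List blocks, IntegerVector block_type,
                   IntegerVector block_year, IntegerVector prior_code,
                   NumericVector prior_mean, NumericVector prior_sd,
                   int n_iter, int burn_in, int thin, int hyper_sweeps) {
  Engine g = makeEngine(engineL);
  Data d = makeData(dataL, g);
  const int nth = theta0.size();
  std::vector<double> th(theta0.begin(), theta0.end());

  const int nb = blocks.size();
  std::vector<std::vector<int> > bidx(nb);
  for (int b = 0; b < nb; ++b) bidx[b] = ivec(blocks[b]);

  Arrays ar; ar.init(g);
  computeAll(g, th, ar);
  const int chin = (g.T + 1) * (g.A + 1) * g.S;
  std::vector<double> chi(chin, 1.0), chi_scr(chin, 1.0);
  computeChi(g, ar, chi);
  double chi_term = chiTerm(g, d, chi);
  std::vector<double> fwd(d.n, 0.0), fwd_scr(d.n, 0.0);
  double total_fwd = 0.0;
  for (int i = 0; i < d.n; ++i) { fwd[i] = fwdInd(g, d, th, ar, i); total_fwd += fwd[i]; }
  if (!std::isfinite(total_fwd + chi_term))
    stop("initial parameter values give a non-finite log-likelihood");

  Hyper hyp = buildHyper(g, th);
  if (!hyp.ok) stop("initial loading matrix is singular");

  // individuals whose detection span touches the transitions affected by
  // an update of year-effect row t
  std::vector<std::vector<int> > year_inds(g.T + 1);
  for (int t = 1; t <= g.T; ++t) {
    for (int i = 0; i < d.n; ++i) {
      const int lo = d.entry[i] + 1, hi = d.tlast[i];
      bool hit = (t >= lo && t <= hi);
      if (g.ctype == 2 && t + 1 >= lo && t + 1 <= hi) hit = true;
      if (hit) year_inds[t].push_back(i);
    }
  }

  std::vector<double> scale(nb, 0.2);
  std::vector<double> acc_n(nb, 0.0), acc_sum(nb, 0.0);
  for (int b = 0; b < nb; ++b) if (bidx[b].size() == 1) scale[b] = 0.4;

  const int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix draws(n_keep, nth);
  NumericVector ll_keep(n_keep);
  int keep = 0;

  std::vector<double> th_bak(nth), slice_bak;
  const int ys_trans = g.A * g.S * (g.S + 1), ys_pdet = g.A * g.S, ys_om = g.A;
  std::vector<double> tr_bak, pd_bak, om_bak;

  // S_a = sum_t alpha_t alpha_t' and sum of squared detection effects,
  // refreshed before each hyper phase
  std::vector<double> Sa(g.K * g.K, 0.0);
  double ap_ss = 0.0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    for (int b = 0; b < nb; ++b) {
      const std::vector<int>& ix = bidx[b];
      const int type = block_type[b];
      if (type == 2 || type == 3) continue; // handled in the hyper phase
      // propose
      for (size_t j = 0; j < ix.size(); ++j) th_bak[j] = th[ix[j]];
      double dprior = 0.0;
      if (type == 1) {
        const int t = block_year[b];
        dprior -= -0.5 * alphaRowQuad(g, th, hyp, t);
        if (g.det_year) {
          const double sp = std::exp(th[g.i_logsigp]);
          const double v = th[g.i_alphap0 + t - 1];
          dprior -= -0.5 * v * v / (sp * sp);
        }
      } else {
        for (size_t j = 0; j < ix.size(); ++j)
          dprior -= slotLogprior(prior_code[ix[j]], prior_mean[ix[j]],
                                 prior_sd[ix[j]], th[ix[j]]);
      }
      for (size_t j = 0; j < ix.size(); ++j)
        th[ix[j]] += scale[b] * norm_rand();
      if (type == 1) {
        const int t = block_year[b];
        dprior += -0.5 * alphaRowQuad(g, th, hyp, t);
        if (g.det_year) {
          const double sp = std::exp(th[g.i_logsigp]);
          const double v = th[g.i_alphap0 + t - 1];
          dprior += -0.5 * v * v / (sp * sp);
        }
      } else {
        for (size_t j = 0; j < ix.size(); ++j)
          dprior += slotLogprior(prior_code[ix[j]], prior_mean[ix[j]],
                                 prior_sd[ix[j]], th[ix[j]]);
      }

      double dll = 0.0;
      bool accept = false;
      if (type == 0) {
        tr_bak = ar.trans; pd_bak = ar.pdet; om_bak = ar.ometa;
        computeAll(g, th, ar);
        computeChi(g, ar, chi_scr);
        const double ct_p = chiTerm(g, d, chi_scr);
        double tf_p = 0.0;
        bool fin = std::isfinite(ct_p);
        if (fin) {
          for (int i = 0; i < d.n; ++i) {
            fwd_scr[i] = fwdInd(g, d, th, ar, i);
            tf_p += fwd_scr[i];
            if (!std::isfinite(tf_p)) { fin = false; break; }
          }
        }
        if (fin) {
          dll = (tf_p + ct_p) - (total_fwd + chi_term);
          accept = std::log(unif_rand()) < dll + dprior;
        }
        if (accept) {
          total_fwd = tf_p; chi_term = ct_p;
          std::swap(chi, chi_scr); std::swap(fwd, fwd_scr);
        } else {
          ar.trans = tr_bak; ar.pdet = pd_bak; ar.ometa = om_bak;
          for (size_t j = 0; j < ix.size(); ++j) th[ix[j]] = th_bak[j];
        }
      } else { // year block
        const int t = block_year[b];
        int ylo = t, yhi = (g.ctype == 2) ? t + 1 : t;
        if (ylo < 2) ylo = 2;
        if (yhi > g.T) yhi = g.T;
        const int nys = yhi - ylo + 1;
        bool any_year = nys > 0 && yhi >= 2;
        if (any_year) {
          tr_bak.resize(nys * ys_trans); pd_bak.resize(nys * ys_pdet);
          om_bak.resize(nys * ys_om);
          for (int q = 0; q < nys; ++q) {
            const int y = ylo + q;
            std::copy(ar.trans.begin() + g.tidx(y, 1, 0, 0),
                      ar.trans.begin() + g.tidx(y, 1, 0, 0) + ys_trans,
                      tr_bak.begin() + q * ys_trans);
            std::copy(ar.pdet.begin() + g.pidx(y, 1, 0),
                      ar.pdet.begin() + g.pidx(y, 1, 0) + ys_pdet,
                      pd_bak.begin() + q * ys_pdet);
            std::copy(ar.ometa.begin() + g.oidx(y, 1),
                      ar.ometa.begin() + g.oidx(y, 1) + ys_om,
                      om_bak.begin() + q * ys_om);
            computeYear(g, th, y, ar);
          }
          computeChi(g, ar, chi_scr);
          const double ct_p = chiTerm(g, d, chi_scr);
          double dfwd = 0.0;
          bool fin = std::isfinite(ct_p);
          const std::vector<int>& inds = year_inds[t];
          if (fin) {
            for (size_t q = 0; q < inds.size(); ++q) {
              const int i = inds[q];
              fwd_scr[i] = fwdInd(g, d, th, ar, i);
              dfwd += fwd_scr[i] - fwd[i];
              if (!std::isfinite(dfwd)) { fin = false; break; }
            }
          }
          if (fin) {
            dll = dfwd + (ct_p - chi_term);
            accept = std::log(unif_rand()) < dll + dprior;
          }
          if (accept) {
            total_fwd += dfwd; chi_term = ct_p;
            std::swap(chi, chi_scr);
            for (size_t q = 0; q < inds.size(); ++q) fwd[inds[q]] = fwd_scr[inds[q]];
          } else {
            for (int q = 0; q < nys; ++q) {
              const int y = ylo + q;
              std::copy(tr_bak.begin() + q * ys_trans,
                        tr_bak.begin() + (q + 1) * ys_trans,
                        ar.trans.begin() + g.tidx(y, 1, 0, 0));
              std::copy(pd_bak.begin() + q * ys_pdet,
                        pd_bak.begin() + (q + 1) * ys_pdet,
                        ar.pdet.begin() + g.pidx(y, 1, 0));
              std::copy(om_bak.begin() + q * ys_om,
                        om_bak.begin() + (q + 1) * ys_om,
                        ar.ometa.begin() + g.oidx(y, 1));
            }
            for (size_t j = 0; j < ix.size(); ++j) th[ix[j]] = th_bak[j];
          }
        } else {
          // no within-study transition reads this row: prior-only update
          accept = std::log(unif_rand()) < dprior;
          if (!accept)
            for (size_t j = 0; j < ix.size(); ++j) th[ix[j]] = th_bak[j];
        }
      }
      acc_n[b] += 1.0; acc_sum[b] += accept ? 1.0 : 0.0;
      if (iter <= burn_in) {
        const double target = ix.size() == 1 ? 0.44 : 0.25;
        scale[b] *= std::exp(((accept ? 1.0 : 0.0) - target) /
                             std::pow(acc_n[b], 0.6));
        if (scale[b] < 1e-4) scale[b] = 1e-4;
        if (scale[b] > 10.0) scale[b] = 10.0;
      }
    }

    // hyper phase: covariance working parameters, prior-only conditionals
    std::fill(Sa.begin(), Sa.end(), 0.0);
    for (int t = 1; t <= g.T; ++t)
      for (int j = 0; j < g.K; ++j)
        for (int k = 0; k < g.K; ++k)
          Sa[j * g.K + k] += g.alpha(th, t, j) * g.alpha(th, t, k);
    if (g.det_year) {
      ap_ss = 0.0;
      for (int t = 0; t < g.T; ++t)
        ap_ss += th[g.i_alphap0 + t] * th[g.i_alphap0 + t];
    }
    for (int sweep = 0; sweep < hyper_sweeps; ++sweep) {
      for (int b = 0; b < nb; ++b) {
        const int type = block_type[b];
        if (type != 2 && type != 3) continue;
        const int j = bidx[b][0];
        const double old = th[j];
        double t_cur, t_new;
        if (type == 2) {
          double tr = 0.0;
          for (int q = 0; q < g.K * g.K; ++q) tr += hyp.Omega[q] * Sa[q];
          t_cur = -0.5 * tr - 0.5 * g.T * hyp.logdet +
                  slotLogprior(prior_code[j], prior_mean[j], prior_sd[j], old);
        } else {
          const double sp = std::exp(old);
          t_cur = -g.T * old - 0.5 * ap_ss / (sp * sp) +
                  slotLogprior(prior_code[j], prior_mean[j], prior_sd[j], old);
        }
        th[j] = old + scale[b] * norm_rand();
        bool accept = false;
        Hyper hyp_p;
        if (type == 2) {
          hyp_p = buildHyper(g, th);
          if (hyp_p.ok) {
            double tr = 0.0;
            for (int q = 0; q < g.K * g.K; ++q) tr += hyp_p.Omega[q] * Sa[q];
            t_new = -0.5 * tr - 0.5 * g.T * hyp_p.logdet +
                    slotLogprior(prior_code[j], prior_mean[j], prior_sd[j], th[j]);
            accept = std::log(unif_rand()) < t_new - t_cur;
          }
        } else {
          const double sp = std::exp(th[j]);
          t_new = -g.T * th[j] - 0.5 * ap_ss / (sp * sp) +
                  slotLogprior(prior_code[j], prior_mean[j], prior_sd[j], th[j]);
          accept = std::log(unif_rand()) < t_new - t_cur;
        }
        if (accept) {
          if (type == 2) hyp = hyp_p;
        } else {
          th[j] = old;
        }
        acc_n[b] += 1.0; acc_sum[b] += accept ? 1.0 : 0.0;
        if (iter <= burn_in) {
          scale[b] *= std::exp(((accept ? 1.0 : 0.0) - 0.44) /
                               std::pow(acc_n[b], 0.6));
          if (scale[b] < 1e-4) scale[b] = 1e-4;
          if (scale[b] > 10.0) scale[b] = 10.0;
        }
      }
    }

    if (iter > burn_in && (iter - burn_in) % thin == 0) {
      for (int q = 0; q < nth; ++q) draws(keep, q) = th[q];
      ll_keep[keep] = total_fwd + chi_term;
      ++keep;
    }
  }

  NumericVector acc(nb);
  for (int b = 0; b < nb; ++b) acc[b] = acc_n[b] > 0 ? acc_sum[b] / acc_n[b] : NA_REAL;
  return List::create(
    _["draws"] = draws, _["loglik"] = ll_keep, _["accept"] = acc,
    _["scale"] = NumericVector(scale.begin(), scale.end())
  );
}
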