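#include "phylik.h"
#include <cmath>

using namespace Rcpp;

// ---- calibration densities -------------------------------------------------
// All soft bounds are proper densities on (0, Inf). Units are the caller's
// (the R wrapper converts Ma to internal 100-Ma units before calling).
//
// kind 1 min(tL; beta=par[1]):  mass pL below tL as a power ramp, Pareto tail
//         of shape beta above tL.
// kind 2 max(tU): uniform on (0,tU) carrying 1-pU, power-decay tail above.
// kind 3 joint(tL,tU): uniform plateau carrying 1-pL-pU, power ramp below tL
//         with mass pL, power-decay tail above tU with mass pU. Tails are
//         continuous with the plateau.
// kinds 4-7: fitted densities (lognormal, gamma, skew-normal, zero-truncated
//         normal), optionally truncated above at trunc_hi with log-mass
//         `lognorm` inside the truncation window (computed by the caller).
double cal_logdens_one(int kind, const double *par, double pL, double pU,
                       double lognorm, double trunc_hi, double t) {
  if (t <= 0) return R_NegInf;
  switch (kind) {
  case 1: { // min
    double tL = par[0], beta = par[1];
    double fU = (1.0 - pL) * beta / tL;       // density just above tL
    double thetaL = fU * tL / pL;             // continuity at tL
    if (t < tL)
      return std::log(pL * thetaL) + (thetaL - 1.0) * std::log(t) - thetaL * std::log(tL);
    return std::log((1.0 - pL) * beta) + beta * std::log(tL) - (beta + 1.0) * std::log(t);
  }
  case 2: { // max
    double tU = par[0];
    double h = (1.0 - pU) / tU;
    if (t < tU) return std::log(h);
    double alpha = 1.0 + h * tU / pU;
    return std::log(pU * (alpha - 1.0)) + (alpha - 1.0) * std::log(tU) - alpha * std::log(t);
  }
  case 3: { // joint
    double tL = par[0], tU = par[1];
    double h = (1.0 - pL - pU) / (tU - tL);
    if (t >= tL && t <= tU) return std::log(h);
    if (t < tL) {
      double thetaL = h * tL / pL;
      return std::log(pL * thetaL) + (thetaL - 1.0) * std::log(t) - thetaL * std::log(tL);
    }
    double alpha = 1.0 + h * tU / pU;
    return std::log(pU * (alpha - 1.0)) + (alpha - 1.0) * std::log(tU) - alpha * std::log(t);
  }
  case 4: { // lognormal(meanlog, sdlog)
    if (trunc_hi > 0 && t > trunc_hi) return R_NegInf;
    return R::dlnorm(t, par[0], par[1], 1) - lognorm;
  }
  case 5: { // gamma(shape, rate)
    if (trunc_hi > 0 && t > trunc_hi) return R_NegInf;
    return R::dgamma(t, par[0], 1.0 / par[1], 1) - lognorm;
  }
  case 6: { // skew-normal(xi, omega, alpha)
    if (trunc_hi > 0 && t > trunc_hi) return R_NegInf;
    double z = (t - par[0]) / par[1];
    return M_LN2 + R::dnorm(z, 0.0, 1.0, 1) - std::log(par[1]) +
           R::pnorm(par[2] * z, 0.0, 1.0, 1, 1) - lognorm;
  }
  case 7: { // normal(mean, sd) truncated to (0, trunc_hi)
    if (trunc_hi > 0 && t > trunc_hi) return R_NegInf;
    return R::dnorm(t, par[0], par[1], 1) - lognorm;
  }
  }
  return R_NegInf;
}

// [[Rcpp::export]]
NumericVector cpp_cal_logdens(int kind, NumericVector params, double pL,
                              double pU, double lognorm, double trunc_hi,
                              NumericVector t) {
  NumericVector out(t.size());
  std::vector<double> par(params.begin(), params.end());
  par.resize(4, 0.0);
  for (int i = 0; i < t.size(); ++i)
    out[i] = cal_logdens_one(kind, par.data(), pL, pU, lognorm, trunc_hi, t[i]);
  return out;
}

// ---- birth-death node-age kernel -------------------------------------------
// Density of an interior node age conditional on the root age t1 under a
// birth-death process with complete sampling; lambda=mu and mu=0 limits
// handled in closed form.
double bd_kernel_logdens_one(double t, double t1, double lambda, double mu) {
  if (t <= 0 || t >= t1) return R_NegInf;
  if (mu < 1e-12) { // Yule: truncated exponential
    return std::log(lambda) - lambda * t - std::log(1.0 - std::exp(-lambda * t1));
  }
  if (std::fabs(lambda - mu) < 1e-10) {
    return std::log(1.0 + lambda * t1) - std::log(t1) - 2.0 * std::log(1.0 + lambda * t);
  }
  double r = lambda - mu;
  double E = std::exp(-r * t), E1 = std::exp(-r * t1);
  double p1 = r * r * E / std::pow(lambda - mu * E, 2.0);
  double V = (1.0 - E1) / (lambda - mu * E1);
  return std::log(p1) - std::log(V);
}

// kernel CDF and inverse CDF (closed forms; used by independence proposals)
static double bd_kernel_cdf(double t, double t1, double lambda, double mu) {
  if (t <= 0) return 0.0;
  if (t >= t1) return 1.0;
  if (mu < 1e-12)
    return (1.0 - std::exp(-lambda * t)) / (1.0 - std::exp(-lambda * t1));
  if (std::fabs(lambda - mu) < 1e-10)
    return (t / (1.0 + lambda * t)) / (t1 / (1.0 + lambda * t1));
  double r = lambda - mu;
  double E = std::exp(-r * t), E1 = std::exp(-r * t1);
  double V = (1.0 - E1) / (lambda - mu * E1);
  return ((1.0 - E) / (lambda - mu * E)) / V;
}

static double bd_kernel_icdf(double u, double t1, double lambda, double mu) {
  if (mu < 1e-12)
    return -std::log(1.0 - u * (1.0 - std::exp(-lambda * t1))) / lambda;
  if (std::fabs(lambda - mu) < 1e-10) {
    double cc = u * t1 / (1.0 + lambda * t1);
    return cc / (1.0 - lambda * cc);
  }
  double r = lambda - mu;
  double E1 = std::exp(-r * t1);
  double V = (1.0 - E1) / (lambda - mu * E1);
  double cc = u * V;
  return -std::log((1.0 - cc * lambda) / (1.0 - cc * mu)) / r;
}

// [[Rcpp::export]]
NumericVector cpp_bd_kernel_logdens(NumericVector t, double t1, double lambda,
                                    double mu) {
  NumericVector out(t.size());
  for (int i = 0; i < t.size(); ++i)
    out[i] = bd_kernel_logdens_one(t[i], t1, lambda, mu);
  return out;
}

// ---- dating MCMC -----------------------------------------------------------

struct DatingModel {
  TreeIdx tr;
  int n_tips, n_internal;
  std::vector<int> internal_nodes;  // 0-based node ids, sorted
  std::vector<int> edge_nodes;      // 0-based child node per branch (all but root)
  std::vector<int> node_to_edge;    // node id -> branch index, -1 for root

  // likelihood
  int lik_mode;                     // 0 none, 1 approx, 2 exact
  double beta_power;
  double ell0;
  std::vector<double> bhat, gvec;
  std::vector<std::vector<double> > H;
  IntegerMatrix tipstates;
  std::vector<double> weights, freqs;
  int model_code; double kappa;

  // priors
  std::vector<int> cal_node;        // 0-based
  std::vector<int> cal_kind;
  std::vector<std::vector<double> > cal_par;
  std::vector<double> cal_pL, cal_pU, cal_lognorm, cal_trunc;
  std::vector<int> node_cal;        // node -> calibration index or -1
  double lambda, mu;
  int clock_kind;                   // 0 strict, 1 IR, 2 AR
  double mu_shape, mu_rate, s2_shape, s2_rate;

  double loglik(const std::vector<double> &ages,
                const std::vector<double> &rates, double mu_r) {
    if (lik_mode == 0) return 0.0;
    int nb = (int)edge_nodes.size();
    std::vector<double> b(tr.n_nodes, 0.0);
    for (int e = 0; e < nb; ++e) {
      int nd = edge_nodes[e];
      double dur = ages[tr.parent[nd]] - ages[nd];
      double r = (clock_kind == 0) ? mu_r : rates[e];
      b[nd] = r * dur;
    }
    if (lik_mode == 2)
      return prune_loglik(tr, b, tipstates, weights, model_code, freqs, kappa);
    // quadratic surface around bhat
    double ll = ell0, quad = 0.0;
    std::vector<double> d(nb);
    for (int e = 0; e < nb; ++e) d[e] = b[edge_nodes[e]] - bhat[e];
    for (int e = 0; e < nb; ++e) {
      ll += gvec[e] * d[e];
      double hrow = 0.0;
      const std::vector<double> &He = H[e];
      for (int f = 0; f < nb; ++f) hrow += He[f] * d[f];
      quad += d[e] * hrow;
    }
    return ll + 0.5 * quad;
  }

  double logprior(const std::vector<double> &ages,
                  const std::vector<double> &rates, double mu_r, double s2) {
    double lp = 0.0;
    double troot = ages[tr.root];
    // node ages
    for (size_t k = 0; k < internal_nodes.size(); ++k) {
      int nd = internal_nodes[k];
      int ci = node_cal[nd];
      if (ci >= 0) {
        lp += cal_logdens_one(cal_kind[ci], cal_par[ci].data(), cal_pL[ci],
                              cal_pU[ci], cal_lognorm[ci], cal_trunc[ci],
                              ages[nd]);
      } else if (nd != tr.root) {
        lp += bd_kernel_logdens_one(ages[nd], troot, lambda, mu);
      }
      if (!R_FINITE(lp)) return R_NegInf;
    }
    // rates
    if (clock_kind == 0) {
      lp += R::dgamma(mu_r, mu_shape, 1.0 / mu_rate, 1);
    } else {
      lp += R::dgamma(mu_r, mu_shape, 1.0 / mu_rate, 1);
      lp += R::dgamma(s2, s2_shape, 1.0 / s2_rate, 1);
      if (clock_kind == 1) {
        double ml = std::log(mu_r) - s2 / 2.0, sd = std::sqrt(s2);
        for (size_t e = 0; e < rates.size(); ++e)
          lp += R::dlnorm(rates[e], ml, sd, 1);
      } else {
        for (size_t e = 0; e < rates.size(); ++e) {
          int nd = edge_nodes[e];
          double dt = ages[tr.parent[nd]] - ages[nd];
          if (dt <= 0) return R_NegInf;
          int pnd = tr.parent[nd];
          double parent_rate = (pnd == tr.root) ? mu_r : rates[node_to_edge[pnd]];
          double ml = std::log(parent_rate) - s2 * dt / 2.0;
          lp += R::dlnorm(rates[e], ml, std::sqrt(s2 * dt), 1);
        }
      }
    }
    return lp;
  }
};

// Metropolis-within-Gibbs over node ages (random-walk with reflection inside
// the (oldest child, parent) interval), branch log-rates, hyperparameters,
// plus a whole-tree scale move (ages * c, rates / c). Step sizes auto-tuned
// during burn-in toward 20-40% acceptance.
// [[Rcpp::export]]
List cpp_mcmc(List tree, List lik, List cals, List bdprior, List clock,
              List settings, List init) {
  DatingModel m;
  m.tr = tree_from_list(tree);
  m.n_tips = 0;
  for (int i = 0; i < m.tr.n_nodes; ++i)
    if (m.tr.children[i].empty()) m.n_tips++;
  m.node_to_edge.assign(m.tr.n_nodes, -1);
  for (int i = 0; i < m.tr.n_nodes; ++i) {
    if (!m.tr.children[i].empty()) m.internal_nodes.push_back(i);
    if (i != m.tr.root) {
      m.node_to_edge[i] = (int)m.edge_nodes.size();
      m.edge_nodes.push_back(i);
    }
  }
  m.n_internal = (int)m.internal_nodes.size();
  int nb = (int)m.edge_nodes.size();

  m.lik_mode = as<int>(lik["mode"]);
  m.beta_power = as<double>(lik["beta"]);
  if (m.lik_mode == 1) {
    m.ell0 = as<double>(lik["ell0"]);
    NumericVector bh = lik["bhat"], gv = lik["gradient"];
    NumericMatrix Hm = lik["hessian"];
    IntegerVector en = lik["edge_nodes"]; // 1-based child node per surface column
    // re-order surface columns into this sampler's edge order
    std::vector<int> colof(m.tr.n_nodes, -1);
    for (int j = 0; j < en.size(); ++j) colof[en[j] - 1] = j;
    m.bhat.resize(nb); m.gvec.resize(nb); m.H.assign(nb, std::vector<double>(nb));
    for (int e = 0; e < nb; ++e) {
      int je = colof[m.edge_nodes[e]];
      m.bhat[e] = bh[je]; m.gvec[e] = gv[je];
      for (int f = 0; f < nb; ++f) m.H[e][f] = Hm(je, colof[m.edge_nodes[f]]);
    }
  } else if (m.lik_mode == 2) {
    m.tipstates = as<IntegerMatrix>(lik["tipstates"]);
    NumericVector w = lik["weights"], fq = lik["freqs"];
    m.weights.assign(w.begin(), w.end());
    m.freqs.assign(fq.begin(), fq.end());
    m.model_code = as<int>(lik["model_code"]);
    m.kappa = as<double>(lik["kappa"]);
  }

  IntegerVector cn = cals["node"], ck = cals["kind"];
  NumericMatrix cp = cals["params"];
  NumericVector cpl = cals["pL"], cpu = cals["pU"], cln = cals["lognorm"],
                ctr = cals["trunc_hi"];
  m.node_cal.assign(m.tr.n_nodes, -1);
  for (int i = 0; i < cn.size(); ++i) {
    m.cal_node.push_back(cn[i] - 1);
    m.cal_kind.push_back(ck[i]);
    std::vector<double> par(4, 0.0);
    for (int j = 0; j < cp.ncol(); ++j) par[j] = cp(i, j);
    m.cal_par.push_back(par);
    m.cal_pL.push_back(cpl[i]); m.cal_pU.push_back(cpu[i]);
    m.cal_lognorm.push_back(cln[i]); m.cal_trunc.push_back(ctr[i]);
    m.node_cal[cn[i] - 1] = i;
  }
  m.lambda = as<double>(bdprior["lambda"]);
  m.mu = as<double>(bdprior["mu"]);
  m.clock_kind = as<int>(clock["kind"]);
  m.mu_shape = as<double>(clock["mu_shape"]);
  m.mu_rate = as<double>(clock["mu_rate"]);
  m.s2_shape = as<double>(clock["s2_shape"]);
  m.s2_rate = as<double>(clock["s2_rate"]);

  int n_iter = as<int>(settings["n_iter"]);
  int burnin = as<int>(settings["burnin"]);
  int thin = as<int>(settings["thin"]);
  bool tune = as<bool>(settings["tune"]);

  std::vector<double> ages(m.tr.n_nodes, 0.0);
  NumericVector ia = init["ages"]; // length n_nodes, tips 0
  for (int i = 0; i < m.tr.n_nodes; ++i) ages[i] = ia[i];
  double mu_r = as<double>(init["mu_r"]);
  double s2 = as<double>(init["s2"]);
  std::vector<double> rates(nb, mu_r);
  if (m.clock_kind > 0) {
    NumericVector ir = init["rates"];
    for (int e = 0; e < nb; ++e) rates[e] = ir[e];
  }

  double cur_ll = m.loglik(ages, rates, mu_r);
  double cur_lp = m.logprior(ages, rates, mu_r, s2);
  if (!R_FINITE(cur_lp)) stop("invalid starting state: prior density is zero");

  // step sizes
  std::vector<double> age_step(m.tr.n_nodes, 0.0);
  for (size_t k = 0; k < m.internal_nodes.size(); ++k)
    age_step[m.internal_nodes[k]] = std::max(1e-3, 0.1 * ages[m.tr.root]);
  double rate_step = 0.5, mu_step = 0.5, s2_step = 0.5, scale_step = 0.2,
         nc_step = 0.6, comp_step = 1.0;
  std::vector<double> age_acc(m.tr.n_nodes, 0.0), age_try(m.tr.n_nodes, 0.0);
  double racc = 0, rtry = 0, macc = 0, mtry = 0, sacc = 0, stry = 0,
         cacc = 0, ctry = 0, nacc = 0, ntry = 0, pacc = 0, ptry = 0;

  int n_keep = (n_iter - burnin) / thin;
  NumericMatrix out_ages(n_keep, m.n_internal);
  NumericMatrix out_rates((m.clock_kind > 0) ? n_keep : 0,
                          (m.clock_kind > 0) ? nb : 0);
  NumericVector out_mu(n_keep), out_s2(n_keep), out_ll(n_keep), out_lp(n_keep);

  RNGScope scope;
  int kept = 0;
  for (int it = 0; it < n_iter; ++it) {
    // --- node ages
    for (size_t k = 0; k < m.internal_nodes.size(); ++k) {
      int nd = m.internal_nodes[k];
      double lo = 0.0;
      for (size_t c = 0; c < m.tr.children[nd].size(); ++c)
        lo = std::max(lo, ages[m.tr.children[nd][c]]);
      double hi = (nd == m.tr.root) ? R_PosInf : ages[m.tr.parent[nd]];
      double t0 = ages[nd];
      double t1;
      double log_hastings = 0.0;
      bool uncal = (m.node_cal[nd] < 0) && (nd != m.tr.root);
      if (uncal && unif_rand() < 0.5) {
        // independence proposal from the birth-death kernel truncated to
        // the node's current valid interval: decorrelates ages when the
        // likelihood is weak (prior-only runs, low stepping-stone rungs)
        double troot = ages[m.tr.root];
        double Flo = bd_kernel_cdf(lo, troot, m.lambda, m.mu);
        double Fhi = R_FINITE(hi) ? bd_kernel_cdf(hi, troot, m.lambda, m.mu) : 1.0;
        if (Fhi - Flo < 1e-12) continue;
        double u = Flo + unif_rand() * (Fhi - Flo);
        t1 = bd_kernel_icdf(u, troot, m.lambda, m.mu);
        log_hastings = bd_kernel_logdens_one(t0, troot, m.lambda, m.mu) -
                       bd_kernel_logdens_one(t1, troot, m.lambda, m.mu);
      } else {
        t1 = t0 + age_step[nd] * (unif_rand() * 2.0 - 1.0);
        for (int rfl = 0; rfl < 100; ++rfl) {
          if (t1 < lo) t1 = 2.0 * lo - t1;
          else if (R_FINITE(hi) && t1 > hi) t1 = 2.0 * hi - t1;
          else break;
        }
      }
      if (t1 <= lo || (R_FINITE(hi) && t1 >= hi)) continue;
      ages[nd] = t1;
      double ll = m.loglik(ages, rates, mu_r);
      double lp = m.logprior(ages, rates, mu_r, s2);
      double dl = m.beta_power * (ll - cur_ll) + lp - cur_lp + log_hastings;
      age_try[nd] += 1;
      if (R_FINITE(lp) && std::log(unif_rand()) < dl) {
        cur_ll = ll; cur_lp = lp; age_acc[nd] += 1;
      } else {
        ages[nd] = t0;
      }
    }
    // --- rates
    if (m.clock_kind == 0) {
      double r0 = mu_r;
      mu_r = r0 * std::exp(mu_step * (unif_rand() - 0.5));
      double ll = m.loglik(ages, rates, mu_r);
      double lp = m.logprior(ages, rates, mu_r, s2);
      double dl = m.beta_power * (ll - cur_ll) + lp - cur_lp +
                  std::log(mu_r / r0); // log-scale RW Jacobian
      mtry += 1;
      if (R_FINITE(lp) && std::log(unif_rand()) < dl) { cur_ll = ll; cur_lp = lp; macc += 1; }
      else mu_r = r0;
    } else {
      for (int e = 0; e < nb; ++e) {
        double r0 = rates[e];
        double log_hastings;
        if (unif_rand() < 0.5) {
          // multiplicative random walk
          rates[e] = r0 * std::exp(rate_step * (unif_rand() - 0.5));
          log_hastings = std::log(rates[e] / r0);
        } else {
          // independence proposal from the (conditional) rate prior: keeps
          // the rates decorrelated when the likelihood power is small
          // (stepping-stone rungs near the prior)
          int nd = m.edge_nodes[e];
          double ml_prop, sd_prop;
          if (m.clock_kind == 1) {
            ml_prop = std::log(mu_r) - s2 / 2.0;
            sd_prop = std::sqrt(s2);
          } else {
            int pnd = m.tr.parent[nd];
            double dt = ages[pnd] - ages[nd];
            double parent_rate = (pnd == m.tr.root) ? mu_r
                                 : rates[m.node_to_edge[pnd]];
            ml_prop = std::log(parent_rate) - s2 * dt / 2.0;
            sd_prop = std::sqrt(s2 * dt);
          }
          rates[e] = std::exp(ml_prop + sd_prop * norm_rand());
          log_hastings = R::dlnorm(r0, ml_prop, sd_prop, 1) -
                         R::dlnorm(rates[e], ml_prop, sd_prop, 1);
        }
        double ll = m.loglik(ages, rates, mu_r);
        double lp = m.logprior(ages, rates, mu_r, s2);
        double dl = m.beta_power * (ll - cur_ll) + lp - cur_lp + log_hastings;
        rtry += 1;
        if (R_FINITE(lp) && std::log(unif_rand()) < dl) { cur_ll = ll; cur_lp = lp; racc += 1; }
        else rates[e] = r0;
      }
      // hyperparameters touch only the prior, so refresh them several
      // times per sweep to keep their autocorrelation low
      for (int hrep = 0; hrep < 3; ++hrep) {
        { // mean rate (prior-only term under IR/AR)
          double r0 = mu_r;
          mu_r = r0 * std::exp(mu_step * (unif_rand() - 0.5));
          double lp = m.logprior(ages, rates, mu_r, s2);
          double dl = lp - cur_lp + std::log(mu_r / r0);
          mtry += 1;
          if (R_FINITE(lp) && std::log(unif_rand()) < dl) { cur_lp = lp; macc += 1; }
          else mu_r = r0;
        }
        { // rate variance
          double v0 = s2;
          s2 = v0 * std::exp(s2_step * (unif_rand() - 0.5));
          double lp = m.logprior(ages, rates, mu_r, s2);
          double dl = lp - cur_lp + std::log(s2 / v0);
          stry += 1;
          if (R_FINITE(lp) && std::log(unif_rand()) < dl) { cur_lp = lp; sacc += 1; }
          else s2 = v0;
        }
      }
    }
    // --- compensated node moves (relaxed clocks): slide a node age and
    // rescale the adjacent branch rates so branch lengths (and hence the
    // likelihood) are exactly preserved; acceptance needs only the prior
    // and the rate Jacobian prod(dur/dur'). Breaks the local age-rate
    // ridge that throttles mixing when the likelihood is informative.
    if (m.clock_kind > 0) {
      for (size_t k = 0; k < m.internal_nodes.size(); ++k) {
        int nd = m.internal_nodes[k];
        double lo = 0.0;
        for (size_t c = 0; c < m.tr.children[nd].size(); ++c)
          lo = std::max(lo, ages[m.tr.children[nd][c]]);
        double hi = (nd == m.tr.root) ? R_PosInf : ages[m.tr.parent[nd]];
        double t0 = ages[nd];
        double t1 = t0 + comp_step * age_step[nd] * (unif_rand() * 2.0 - 1.0);
        for (int rfl = 0; rfl < 100; ++rfl) {
          if (t1 < lo) t1 = 2.0 * lo - t1;
          else if (R_FINITE(hi) && t1 > hi) t1 = 2.0 * hi - t1;
          else break;
        }
        if (t1 <= lo || (R_FINITE(hi) && t1 >= hi)) continue;
        std::vector<double> rates2(rates);
        double log_jac = 0.0;
        bool ok = true;
        if (nd != m.tr.root) {
          double d0 = ages[m.tr.parent[nd]] - t0, d1 = ages[m.tr.parent[nd]] - t1;
          if (d1 <= 0) ok = false;
          else { rates2[m.node_to_edge[nd]] *= d0 / d1; log_jac += std::log(d0 / d1); }
        }
        for (size_t c = 0; ok && c < m.tr.children[nd].size(); ++c) {
          int ch = m.tr.children[nd][c];
          double d0 = t0 - ages[ch], d1 = t1 - ages[ch];
          if (d1 <= 0) { ok = false; break; }
          rates2[m.node_to_edge[ch]] *= d0 / d1;
          log_jac += std::log(d0 / d1);
        }
        if (!ok) continue;
        double t_keep = ages[nd];
        ages[nd] = t1;
        double lp = m.logprior(ages, rates2, mu_r, s2);
        double dl = lp - cur_lp + log_jac;   // likelihood is unchanged
        ptry += 1;
        if (R_FINITE(lp) && std::log(unif_rand()) < dl) {
          rates = rates2; cur_lp = lp; pacc += 1;
        } else {
          ages[nd] = t_keep;
        }
      }
    }
    // --- non-centered sigma2 move (relaxed clocks): hold the standardized
    // log-rate increments fixed and rescale them with sigma2', so rates and
    // sigma2 move together; in the increment coordinates the prior terms
    // cancel and the acceptance is beta*dloglik + dlog p(s2) + log(s2'/s2)
    if (m.clock_kind > 0) {
      double v0 = s2;
      double v1 = v0 * std::exp(nc_step * (unif_rand() - 0.5));
      std::vector<double> rates2(rates);
      // preorder = reverse postorder guarantees parents before children
      for (int idx = m.tr.n_nodes - 1; idx >= 0; --idx) {
        int nd = m.tr.postorder[idx];
        if (nd == m.tr.root) continue;
        int e = m.node_to_edge[nd];
        double dt = (m.clock_kind == 1) ? 1.0 : (ages[m.tr.parent[nd]] - ages[nd]);
        if (dt <= 0) { rates2 = rates; v1 = v0; break; }
        int pnd = m.tr.parent[nd];
        double par0 = (m.clock_kind == 1 || pnd == m.tr.root) ? mu_r
                      : rates[m.node_to_edge[pnd]];
        double par1 = (m.clock_kind == 1 || pnd == m.tr.root) ? mu_r
                      : rates2[m.node_to_edge[pnd]];
        double z = (std::log(rates[e]) - std::log(par0) + v0 * dt / 2.0) /
                   std::sqrt(v0 * dt);
        rates2[e] = std::exp(std::log(par1) - v1 * dt / 2.0 +
                             std::sqrt(v1 * dt) * z);
      }
      if (v1 != v0) {
        double ll = m.loglik(ages, rates2, mu_r);
        double dl = m.beta_power * (ll - cur_ll) +
                    R::dgamma(v1, m.s2_shape, 1.0 / m.s2_rate, 1) -
                    R::dgamma(v0, m.s2_shape, 1.0 / m.s2_rate, 1) +
                    std::log(v1 / v0);
        ntry += 1;
        if (R_FINITE(dl) && std::log(unif_rand()) < dl) {
          rates = rates2; s2 = v1;
          cur_ll = ll;
          cur_lp = m.logprior(ages, rates, mu_r, s2);
          nacc += 1;
        }
      }
    }
    // --- whole-tree scale move: t*c, r/c (Jacobian c^(n_ages - n_rates - 1))
    {
      double c = std::exp(scale_step * (unif_rand() - 0.5));
      std::vector<double> ages2(ages);
      for (size_t k = 0; k < m.internal_nodes.size(); ++k)
        ages2[m.internal_nodes[k]] *= c;
      std::vector<double> rates2(rates);
      int n_down = 1; // mu_r
      double mu2 = mu_r / c;
      if (m.clock_kind > 0) {
        for (int e = 0; e < nb; ++e) rates2[e] /= c;
        n_down += nb;
      }
      double ll = m.loglik(ages2, rates2, mu2);
      double lp = m.logprior(ages2, rates2, mu2, s2);
      double dl = m.beta_power * (ll - cur_ll) + lp - cur_lp +
                  (m.n_internal - n_down) * std::log(c);
      ctry += 1;
      if (R_FINITE(lp) && std::log(unif_rand()) < dl) {
        ages = ages2; rates = rates2; mu_r = mu2;
        cur_ll = ll; cur_lp = lp; cacc += 1;
      }
    }
    // --- tuning
    if (tune && it < burnin && (it + 1) % 100 == 0) {
      for (size_t k = 0; k < m.internal_nodes.size(); ++k) {
        int nd = m.internal_nodes[k];
        if (age_try[nd] >= 20) {
          double a = age_acc[nd] / age_try[nd];
          if (a > 0.4) age_step[nd] *= 1.4;
          else if (a < 0.2) age_step[nd] /= 1.4;
          age_acc[nd] = age_try[nd] = 0;
        }
      }
      if (rtry >= 20) { double a = racc / rtry; if (a > 0.4) rate_step *= 1.4; else if (a < 0.2) rate_step /= 1.4; racc = rtry = 0; }
      if (mtry >= 20) { double a = macc / mtry; if (a > 0.4) mu_step *= 1.4; else if (a < 0.2) mu_step /= 1.4; macc = mtry = 0; }
      if (stry >= 20) { double a = sacc / stry; if (a > 0.4) s2_step *= 1.4; else if (a < 0.2) s2_step /= 1.4; sacc = stry = 0; }
      if (ctry >= 20) { double a = cacc / ctry; if (a > 0.4) scale_step *= 1.4; else if (a < 0.2) scale_step /= 1.4; cacc = ctry = 0; }
      if (ntry >= 20) { double a = nacc / ntry; if (a > 0.4) nc_step *= 1.4; else if (a < 0.2) nc_step /= 1.4; nacc = ntry = 0; }
      if (ptry >= 20) { double a = pacc / ptry; if (a > 0.4) comp_step *= 1.4; else if (a < 0.2) comp_step /= 1.4; pacc = ptry = 0; }
    }
    // --- store
    if (it >= burnin && (it - burnin) % thin == 0 && kept < n_keep) {
      for (int k = 0; k < m.n_internal; ++k)
        out_ages(kept, k) = ages[m.internal_nodes[k]];
      if (m.clock_kind > 0)
        for (int e = 0; e < nb; ++e) out_rates(kept, e) = rates[e];
      out_mu[kept] = mu_r; out_s2[kept] = s2;
      out_ll[kept] = cur_ll; out_lp[kept] = cur_lp;
      kept++;
    }
  }

  double age_try_tot = 0, age_acc_tot = 0;
  for (size_t k = 0; k < m.internal_nodes.size(); ++k) {
    age_try_tot += age_try[m.internal_nodes[k]];
    age_acc_tot += age_acc[m.internal_nodes[k]];
  }
  IntegerVector keep_nodes(m.n_internal);
  for (int k = 0; k < m.n_internal; ++k) keep_nodes[k] = m.internal_nodes[k] + 1;
  IntegerVector edge_nodes_out(nb);
  for (int e = 0; e < nb; ++e) edge_nodes_out[e] = m.edge_nodes[e] + 1;
  return List::create(
      _["ages"] = out_ages, _["rates"] = out_rates, _["mu_r"] = out_mu,
      _["s2"] = out_s2, _["loglik"] = out_ll, _["logprior"] = out_lp,
      _["internal_nodes"] = keep_nodes, _["edge_nodes"] = edge_nodes_out,
      _["accept"] = NumericVector::create(
          _["ages"] = age_try_tot > 0 ? age_acc_tot / age_try_tot : NA_REAL,
          _["scale"] = ctry > 0 ? cacc / ctry : NA_REAL));
}
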