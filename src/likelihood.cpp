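#include "phylik.h"
#include <cmath>

using namespace Rcpp;

TreeIdx tree_from_list(List tree) {
  TreeIdx tr;
  tr.n_nodes = as<int>(tree["n_nodes"]);
  tr.root = as<int>(tree["root"]) - 1;
  List ch = tree["children"];
  IntegerVector po = tree["postorder"];
  IntegerVector pa = tree["parent"];
  IntegerVector tiprow = tree["tip_row"];
  tr.children.resize(tr.n_nodes);
  for (int i = 0; i < tr.n_nodes; ++i) {
    IntegerVector ci = ch[i];
    for (int j = 0; j < ci.size(); ++j) tr.children[i].push_back(ci[j] - 1);
  }
  tr.postorder.resize(tr.n_nodes);
  tr.parent.resize(tr.n_nodes);
  tr.tip_row.resize(tr.n_nodes);
  for (int i = 0; i < tr.n_nodes; ++i) {
    tr.postorder[i] = po[i] - 1;
    tr.parent[i] = pa[i] - 1;   // 0 on R side -> -1 (root)
    tr.tip_row[i] = tiprow[i] - 1;
  }
  return tr;
}

// P(b) and dP/db for the supported models. b is the expected number of
// substitutions per site on the branch (rate matrix normalized to mean rate 1).
void fill_P(int model_code, const std::vector<double> &freqs, double kappa,
            double b, int S, double *P, double *dP) {
  if (b < 0) b = 0;
  if (model_code == 0) {
    // equal-input: P_ij = e*I + (1-e) pi_j, e = exp(-beta b), beta = 1/(1-sum pi^2)
    double ss = 0.0;
    for (int i = 0; i < S; ++i) ss += freqs[i] * freqs[i];
    double beta = 1.0 / (1.0 - ss);
    double e = std::exp(-beta * b);
    for (int i = 0; i < S; ++i)
      for (int j = 0; j < S; ++j) {
        double pij = (1.0 - e) * freqs[j] + (i == j ? e : 0.0);
        P[i * S + j] = pij;
        if (dP) dP[i * S + j] = beta * e * (freqs[j] - (i == j ? 1.0 : 0.0));
      }
  } else {
    // HKY, states A C G T; purines {0,2}, pyrimidines {1,3}
    const double piA = freqs[0], piC = freqs[1], piG = freqs[2], piT = freqs[3];
    const double piR = piA + piG, piY = piC + piT;
    double mean = 2.0 * kappa * (piA * piG + piC * piT) + 2.0 * piR * piY;
    double beta = 1.0 / mean;
    double e2 = std::exp(-beta * b);
    for (int j = 0; j < 4; ++j) {
      double Pi = (j == 0 || j == 2) ? piR : piY;
      double Aj = 1.0 + Pi * (kappa - 1.0);
      double eA = std::exp(-beta * b * Aj);
      for (int i = 0; i < 4; ++i) {
        bool sameGroup = ((i == 0 || i == 2) == (j == 0 || j == 2));
        double pij, dij;
        if (i == j) {
          pij = freqs[j] + freqs[j] * (1.0 / Pi - 1.0) * e2 +
                ((Pi - freqs[j]) / Pi) * eA;
          dij = -beta * freqs[j] * (1.0 / Pi - 1.0) * e2 -
                beta * Aj * ((Pi - freqs[j]) / Pi) * eA;
        } else if (sameGroup) {
          pij = freqs[j] + freqs[j] * (1.0 / Pi - 1.0) * e2 -
                (freqs[j] / Pi) * eA;
          dij = -beta * freqs[j] * (1.0 / Pi - 1.0) * e2 +
                beta * Aj * (freqs[j] / Pi) * eA;
        } else {
          pij = freqs[j] * (1.0 - e2);
          dij = beta * freqs[j] * e2;
        }
        P[i * 4 + j] = pij;
        if (dP) dP[i * 4 + j] = dij;
      }
    }
  }
}

// Felsenstein pruning over site patterns, with per-node scaling.
double prune_loglik(const TreeIdx &tr, const std::vector<double> &brlen,
                    const IntegerMatrix &tipstates,
                    const std::vector<double> &weights,
                    int model_code, const std::vector<double> &freqs,
                    double kappa) {
  const int S = (int)freqs.size();
  const int npat = tipstates.ncol();
  std::vector<std::vector<double> > D(tr.n_nodes);
  std::vector<double> logscale(npat, 0.0);
  std::vector<double> P(S * S), M(S * npat);

  for (int idx = 0; idx < tr.n_nodes; ++idx) {
    int nd = tr.postorder[idx];
    D[nd].assign(S * npat, 1.0);
    if (tr.children[nd].empty()) {
      int row = tr.tip_row[nd];
      for (int p = 0; p < npat; ++p) {
        int st = tipstates(row, p);
        if (st != NA_INTEGER) {
          for (int s = 0; s < S; ++s) D[nd][p * S + s] = (s == st - 1) ? 1.0 : 0.0;
        }
      }
    } else {
      for (size_t c = 0; c < tr.children[nd].size(); ++c) {
        int ch = tr.children[nd][c];
        fill_P(model_code, freqs, kappa, brlen[ch], S, P.data(), NULL);
        const double *Dc = D[ch].data();
        double *Dn = D[nd].data();
        if (S == 4) {   // unrolled hot path for nucleotide models
          for (int p = 0; p < npat; ++p) {
            const double d0 = Dc[p * 4], d1 = Dc[p * 4 + 1],
                         d2 = Dc[p * 4 + 2], d3 = Dc[p * 4 + 3];
            for (int i = 0; i < 4; ++i)
              Dn[p * 4 + i] *= P[i * 4] * d0 + P[i * 4 + 1] * d1 +
                               P[i * 4 + 2] * d2 + P[i * 4 + 3] * d3;
          }
        } else {
          for (int p = 0; p < npat; ++p) {
            for (int i = 0; i < S; ++i) {
              double m = 0.0;
              for (int j = 0; j < S; ++j) m += P[i * S + j] * Dc[p * S + j];
              Dn[p * S + i] *= m;
            }
          }
        }
        D[ch].clear(); D[ch].shrink_to_fit();
      }
      for (int p = 0; p < npat; ++p) {
        double mx = 0.0;
        for (int s = 0; s < S; ++s) if (D[nd][p * S + s] > mx) mx = D[nd][p * S + s];
        if (mx > 0 && mx < 1e-100) {
          for (int s = 0; s < S; ++s) D[nd][p * S + s] /= mx;
          logscale[p] += std::log(mx);
        } else if (mx <= 0) {
          return R_NegInf;
        }
      }
    }
  }
  double ll = 0.0;
  for (int p = 0; p < npat; ++p) {
    double lp = 0.0;
    for (int s = 0; s < S; ++s) lp += freqs[s] * D[tr.root][p * S + s];
    if (lp <= 0) return R_NegInf;
    ll += weights[p] * (std::log(lp) + logscale[p]);
  }
  return ll;
}

// [[Rcpp::export]]
double cpp_prune_loglik(List tree, NumericVector brlen, IntegerMatrix tipstates,
                        NumericVector weights, int model_code,
                        NumericVector freqs, double kappa) {
  TreeIdx tr = tree_from_list(tree);
  std::vector<double> bl(brlen.begin(), brlen.end());
  std::vector<double> w(weights.begin(), weights.end());
  std::vector<double> fr(freqs.begin(), freqs.end());
  return prune_loglik(tr, bl, tipstates, w, model_code, fr, kappa);
}

// Log-likelihood plus its analytic gradient with respect to every branch
// length (indexed by child node). Uses down (post-order) partials, up
// (pre-order) partials, and the closed-form dP/db of each model; scale
// factors cancel in the per-branch ratio so only the loglik needs absolute
// scaling.
// [[Rcpp::export]]
List cpp_prune_loglik_grad(List tree, NumericVector brlen,
                           IntegerMatrix tipstates, NumericVector weights,
                           int model_code, NumericVector freqs, double kappa) {
  TreeIdx tr = tree_from_list(tree);
  const int S = freqs.size();
  const int npat = tipstates.ncol();
  std::vector<double> fr(freqs.begin(), freqs.end());
  std::vector<std::vector<double> > D(tr.n_nodes), Mmsg(tr.n_nodes);
  std::vector<double> logscale(npat, 0.0);
  std::vector<double> P(S * S), dP(S * S);

  // down pass, keeping all partials and messages
  for (int idx = 0; idx < tr.n_nodes; ++idx) {
    int nd = tr.postorder[idx];
    D[nd].assign(S * npat, 1.0);
    if (tr.children[nd].empty()) {
      int row = tr.tip_row[nd];
      for (int p = 0; p < npat; ++p) {
        int st = tipstates(row, p);
        if (st != NA_INTEGER)
          for (int s = 0; s < S; ++s) D[nd][p * S + s] = (s == st - 1) ? 1.0 : 0.0;
      }
    } else {
      for (size_t c = 0; c < tr.children[nd].size(); ++c) {
        int ch = tr.children[nd][c];
        fill_P(model_code, fr, kappa, brlen[ch], S, P.data(), NULL);
        Mmsg[ch].assign(S * npat, 0.0);
        for (int p = 0; p < npat; ++p)
          for (int i = 0; i < S; ++i) {
            double m = 0.0;
            for (int j = 0; j < S; ++j) m += P[i * S + j] * D[ch][p * S + j];
            Mmsg[ch][p * S + i] = m;
            D[nd][p * S + i] *= m;
          }
      }
      for (int p = 0; p < npat; ++p) {
        double mx = 0.0;
        for (int s = 0; s < S; ++s) if (D[nd][p * S + s] > mx) mx = D[nd][p * S + s];
        if (mx > 0) {
          for (int s = 0; s < S; ++s) D[nd][p * S + s] /= mx;
          logscale[p] += std::log(mx);
          // keep messages consistent with the scaled partials they feed
        }
      }
    }
  }

  double ll = 0.0;
  for (int p = 0; p < npat; ++p) {
    double lp = 0.0;
    for (int s = 0; s < S; ++s) lp += fr[s] * D[tr.root][p * S + s];
    ll += weights[p] * (std::log(lp) + logscale[p]);
  }

  // up pass: Ubar[nd] = partial likelihood of everything outside subtree(nd),
  // evaluated at the states of nd's parent end, including root frequencies.
  std::vector<std::vector<double> > Ubar(tr.n_nodes);
  Ubar[tr.root].assign(S * npat, 0.0);
  for (int p = 0; p < npat; ++p)
    for (int s = 0; s < S; ++s) Ubar[tr.root][p * S + s] = fr[s];

  NumericVector grad(tr.n_nodes);
  std::vector<double> uraw(S);
  for (int idx = tr.n_nodes - 1; idx >= 0; --idx) {
    int nd = tr.postorder[idx];
    if (tr.children[nd].empty()) continue;
    for (size_t c = 0; c < tr.children[nd].size(); ++c) {
      int ch = tr.children[nd][c];
      fill_P(model_code, fr, kappa, brlen[ch], S, P.data(), dP.data());
      Ubar[ch].assign(S * npat, 0.0);
      double g = 0.0;
      for (int p = 0; p < npat; ++p) {
        // Ubar_raw at parent end of branch ch
        for (int i = 0; i < S; ++i) {
          double u = Ubar[nd][p * S + i];
          for (size_t s = 0; s < tr.children[nd].size(); ++s) {
            if (s == c) continue;
            u *= Mmsg[tr.children[nd][s]][p * S + i];
          }
          uraw[i] = u;
        }
        double num = 0.0, den = 0.0;
        for (int i = 0; i < S; ++i) {
          double dm = 0.0;
          for (int j = 0; j < S; ++j) dm += dP[i * S + j] * D[ch][p * S + j];
          num += uraw[i] * dm;
          den += uraw[i] * Mmsg[ch][p * S + i];
        }
        if (den > 0) g += weights[p] * num / den;
        // recurse: Ubar at child end, rescaled per pattern for stability
        double mx = 0.0;
        for (int j = 0; j < S; ++j) {
          double v = 0.0;
          for (int i = 0; i < S; ++i) v += uraw[i] * P[i * S + j];
          Ubar[ch][p * S + j] = v;
          if (v > mx) mx = v;
        }
        if (mx > 0 && mx < 1e-100)
          for (int j = 0; j < S; ++j) Ubar[ch][p * S + j] /= mx;
      }
      grad[ch] = g;
    }
  }
  return List::create(_["loglik"] = ll, _["gradient"] = grad);
}
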