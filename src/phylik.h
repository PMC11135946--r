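#ifndef CHRONODATE_PHYLIK_H
#define CHRONODATE_PHYLIK_H

#include <Rcpp.h>
#include <vector>

// Tree in index form. Nodes are 1-based on the R side; converted to 0-based here.
struct TreeIdx {
  int n_nodes;
  int root;                              // 0-based
  std::vector<std::vector<int> > children; // 0-based child indices, empty for tips
  std::vector<int> postorder;            // 0-based, children before parents
  std::vector<int> parent;               // 0-based, -1 for root
  std::vector<int> tip_row;              // 0-based row into tip-state matrix, -1 for internal
};

TreeIdx tree_from_list(Rcpp::List tree);

// Substitution models: code 0 = equal-input (F81-type; covers JC and Poisson+F
// via the stationary frequencies), code 1 = HKY (4 states, A C G T order).
void fill_P(int model_code, const std::vector<double> &freqs, double kappa,
            double b, int S, double *P, double *dP);

double prune_loglik(const TreeIdx &tr, const std::vector<double> &brlen,
                    const Rcpp::IntegerMatrix &tipstates,
                    const std::vector<double> &weights,
                    int model_code, const std::vector<double> &freqs,
                    double kappa);

double cal_logdens_one(int kind, const double *par, double pL, double pU,
                       double lognorm, double trunc_hi, double t);

double bd_kernel_logdens_one(double t, double t1, double lambda, double mu);

#endif
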