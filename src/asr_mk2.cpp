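// Two-state CTMC (Mk2) pruning likelihood and Metropolis sampling of the
// transition rates under exponential priors, with power-posterior tempering
// (beta) for stepping-stone marginal-likelihood estimation.
//
// States: 0 = animal-associated (A), 1 = protist-associated (P),
// 2 = unknown ('?', uninformative partial).  q_ap is the A->P rate per unit
// branch length, q_pa the reverse.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// closed-form 2-state transition probabilities
static inline void pmat(double qap, double qpa, double t, double P[2][2]) {
  double q = qap + qpa;
  if (q <= 0 || t <= 0) {
    P[0][0] = P[1][1] = 1.0; P[0][1] = P[1][0] = 0.0;
    return;
  }
  double piA = qpa / q, piP = qap / q;
  double e = std::exp(-q * t);
  P[0][0] = piA + piP * e;
  P[0][1] = piP * (1.0 - e);
  P[1][0] = piA * (1.0 - e);
  P[1][1] = piP + piA * e;
}

struct Mk2Tree {
  int ntip, ntot;
  std::vector<std::vector<int>> children;
  std::vector<double> blen;     // branch length above each node (0 at root)
  std::vector<int> postorder;   // internal nodes, children before parents
  std::vector<int> tipstate;    // 0/1/2
};

static double mk2_loglik(const Mk2Tree& T, double qap, double qpa,
                         bool root_uniform) {
  std::vector<double> fA(T.ntot), fP(T.ntot);
  double logscale = 0.0;
  for (int i = 0; i < T.ntip; ++i) {
    fA[i] = (T.tipstate[i] == 0 || T.tipstate[i] == 2) ? 1.0 : 0.0;
    fP[i] = (T.tipstate[i] == 1 || T.tipstate[i] == 2) ? 1.0 : 0.0;
  }
  double P[2][2];
  for (size_t k = 0; k < T.postorder.size(); ++k) {
    int i = T.postorder[k];
    double a = 1.0, p = 1.0;
    for (size_t c = 0; c < T.children[i].size(); ++c) {
      int ch = T.children[i][c];
      pmat(qap, qpa, T.blen[ch], P);
      a *= P[0][0] * fA[ch] + P[0][1] * fP[ch];
      p *= P[1][0] * fA[ch] + P[1][1] * fP[ch];
    }
    double m = std::max(a, p);
    if (m <= 0) return -std::numeric_limits<double>::infinity();
    fA[i] = a / m; fP[i] = p / m;
    logscale += std::log(m);
  }
  int root = T.ntip;
  double q = qap + qpa, piA, piP;
  if (root_uniform || q <= 0) { piA = piP = 0.5; }
  else { piA = qpa / q; piP = qap / q; }
  double L = piA * fA[root] + piP * fP[root];
  if (L <= 0) return -std::numeric_limits<double>::infinity();
  return std::log(L) + logscale;
}

static Mk2Tree build_tree(List tree) {
  Mk2Tree T;
  T.ntip = as<int>(tree["ntip"]);
  T.ntot = as<int>(tree["ntot"]);
  List ch = tree["children"];
  T.children.resize(T.ntot);
  for (int i = 0; i < T.ntot; ++i) {
    IntegerVector ci = ch[i];
    T.children[i].assign(ci.begin(), ci.end());
  }
  NumericVector bl = tree["blen"];
  T.blen.assign(bl.begin(), bl.end());
  IntegerVector po = tree["postorder"];
  T.postorder.assign(po.begin(), po.end());
  IntegerVector ts = tree["tipstate"];
  T.tipstate.assign(ts.begin(), ts.end());
  return T;
}

// [[Rcpp::export]]
double mk2_loglik_cpp(List tree, double qap, double qpa, bool root_uniform) {
  Mk2Tree T = build_tree(tree);
  return mk2_loglik(T, qap, qpa, root_uniform);
}

// Metropolis chain over (log q_ap, log q_pa) -- or a single shared rate when
// equal_rates -- targeting prior(q) * L(q)^beta.
// [[Rcpp::export]]
List mk2_mcmc_cpp(List tree, double beta, bool equal_rates, bool root_uniform,
                  int n_sweeps, int burn, int thin,
                  double prior_rate_ap, double prior_rate_pa,
                  double init_ap, double init_pa) {
  Mk2Tree T = build_tree(tree);
  double qap = init_ap, qpa = equal_rates ? init_ap : init_pa;
  double ll = mk2_loglik(T, qap, qpa, root_uniform);
  auto logprior = [&](double a, double p) {
    double lp = R::dexp(a, 1.0 / prior_rate_ap, 1);
    if (!equal_rates) lp += R::dexp(p, 1.0 / prior_rate_pa, 1);
    return lp;
  };
  double lp = logprior(qap, qpa);
  double sc = 0.8;
  double att = 0, acc = 0;
  int nkeep = (n_sweeps - burn) / thin;
  NumericMatrix out(std::max(nkeep, 0), 3);
  int stored = 0;
  int npar = equal_rates ? 1 : 2;
  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (int j = 0; j < npar; ++j) {
      double a_new = qap, p_new = qpa;
      double lhr;
      if (equal_rates) {
        a_new = qap * std::exp(sc * (unif_rand() - 0.5));
        p_new = a_new;
        lhr = std::log(a_new / qap);
      } else if (j == 0) {
        a_new = qap * std::exp(sc * (unif_rand() - 0.5));
        lhr = std::log(a_new / qap);
      } else {
        p_new = qpa * std::exp(sc * (unif_rand() - 0.5));
        lhr = std::log(p_new / qpa);
      }
      double ll_new = mk2_loglik(T, a_new, p_new, root_uniform);
      double lp_new = logprior(a_new, p_new);
      double lr = beta * (ll_new - ll) + (lp_new - lp) + lhr;
      att += 1;
      if (std::log(unif_rand()) < lr) {
        qap = a_new; qpa = p_new; ll = ll_new; lp = lp_new; acc += 1;
      }
    }
    if (sweep < burn && (sweep + 1) % 100 == 0) {
      double rate = acc / att;
      sc = std::min(std::max(sc * std::exp(0.7 * (rate - 0.3)), 1e-3), 20.0);
      att = acc = 0;
    }
    if (sweep >= burn && (sweep - burn + 1) % thin == 0 && stored < nkeep) {
      out(stored, 0) = qap;
      out(stored, 1) = qpa;
      out(stored, 2) = ll;
      ++stored;
    }
  }
  return List::create(_["trace"] = out,
                      _["accept"] = att > 0 ? acc / att : NA_REAL,
                      _["last"] = NumericVector::create(qap, qpa));
}
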