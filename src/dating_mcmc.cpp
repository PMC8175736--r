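// Metropolis-within-Gibbs core for the relaxed-clock dating model.
//
// State: internal node ages t (Ma), rates r (per node for the AR clock,
// per branch for IR), hyperparameters mu and sigma2.  The age prior is a
// soft-uniform density at each calibrated node plus a sequential
// conditional-uniform density 1/(t_parent - L) at every other internal
// node, L being the largest fixed age below it (calibrated descendants
// visible through uncalibrated paths, minimum-only bounds, leaf age 0).
// The likelihood is the quadratic expansion g'z + z'Hz/2 per partition,
// z = b - b_hat.
//
// All prior contributions are kept as per-node / per-branch terms and
// updated incrementally per move (full refreshes cap floating-point
// drift); the likelihood maintains z and Hz so a move touching |S|
// branches costs O(|S| * nbranch).
//
// Moves per sweep: reflected uniform slide of each non-root internal age
// inside (max child age, parent age) with a per-node adaptive width;
// multiplicative slide of the root age above its oldest child;
// multiplicative updates of every rate and of mu and sigma2; and a
// whole-tree mixing move scaling ages by c and rates (and mu) by 1/c with
// Jacobian factor c^(n_ages - n_rates - 1).  Adaptation runs during
// burn-in only (target ~30% acceptance; the stationary distribution is
// untouched after freezing).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();
static const double AGE_EPS = 1e-9;

struct Model {
  int ntip, ntot, root, nbranch;
  std::vector<int> parent;                  // -1 at root
  std::vector<std::vector<int>> children;
  std::vector<int> internals;               // internal node ids
  std::vector<int> bnode;                   // branch -> child node
  std::vector<int> node2b;                  // node -> branch (-1 at root)
  // calibrations
  std::vector<int> ctype;                   // 0 none, 1 soft box, 2 min-only
  std::vector<double> tmin, tmax, pl, pu, logh, theta, lam;
  std::vector<std::vector<int>> refs;
  std::vector<double> cst;
  std::vector<std::vector<int>> aff_age;    // age-term indices hit by a move of i
  // clock
  bool ar; double tau0;
  double mu_shape, mu_scale, s2_shape, s2_scale;
  // likelihood
  bool use_lik; int npart;
  std::vector<std::vector<double>> bhat, g, H; // H row-major nbranch*nbranch

  // state
  std::vector<double> t, r, lr;
  double mu, s2;
  std::vector<double> at;                   // age prior term per internal node
  std::vector<double> rp;                   // rate prior term per branch
  double rp_root;                           // AR root-rate term (0 for IR)
  std::vector<double> b;
  std::vector<std::vector<double>> z, Hz;
  double lp_age, lp_rate, lp_hyper, loglik;

  double soft_logpdf(int i, double x) const {
    if (x <= 0) return NEG_INF;
    if (x < tmin[i]) {
      if (pl[i] <= 0) return NEG_INF;
      return std::log(pl[i]) + std::log(theta[i]) +
             (theta[i] - 1.0) * std::log(x) - theta[i] * std::log(tmin[i]);
    }
    if (x > tmax[i]) {
      if (pu[i] <= 0) return NEG_INF;
      return std::log(pu[i]) + std::log(lam[i]) - lam[i] * (x - tmax[i]);
    }
    return logh[i];
  }

  // age-prior term of internal node i: ordering vs children plus either the
  // calibration density or the sequential-uniform density
  double term_age(int i) const {
    for (size_t c = 0; c < children[i].size(); ++c)
      if (t[i] - t[children[i][c]] <= AGE_EPS) return NEG_INF;
    if (ctype[i] == 1) return soft_logpdf(i, t[i]);
    double L = cst[i];
    for (size_t m = 0; m < refs[i].size(); ++m)
      L = std::max(L, t[refs[i][m]]);
    if (t[i] <= L) return NEG_INF;
    double w = t[parent[i]] - L;
    if (w <= 0) return NEG_INF;
    return -std::log(w);
  }

  double term_rate(int j) const {
    if (ar) {
      int c = bnode[j];
      double v = s2 * (t[parent[c]] - t[c]);
      if (v <= 0) return NEG_INF;
      return R::dnorm(lr[c], lr[parent[c]] - v / 2.0, std::sqrt(v), 1) - lr[c];
    }
    if (s2 <= 0) return NEG_INF;
    return R::dnorm(lr[j], std::log(mu) - s2 / 2.0, std::sqrt(s2), 1) - lr[j];
  }

  double term_rate_root() const {
    if (!ar) return 0.0;
    double s0 = s2 * tau0;
    if (s0 <= 0) return NEG_INF;
    return R::dnorm(lr[root], std::log(mu) - s0 / 2.0, std::sqrt(s0), 1) - lr[root];
  }

  void refresh_age_prior() {
    lp_age = 0.0;
    for (size_t k = 0; k < internals.size(); ++k) {
      at[internals[k]] = term_age(internals[k]);
      lp_age += at[internals[k]];
    }
  }

  void refresh_rate_prior() {
    rp_root = term_rate_root();
    lp_rate = rp_root;
    for (int j = 0; j < nbranch; ++j) { rp[j] = term_rate(j); lp_rate += rp[j]; }
  }

  double hyper_log_prior() const {
    return R::dgamma(mu, mu_shape, mu_scale, 1) +
           R::dgamma(s2, s2_shape, s2_scale, 1);
  }

  double branch_len(int j) const {
    int c = bnode[j];
    double dur = t[parent[c]] - t[c];
    double rate = ar ? 0.5 * (r[c] + r[parent[c]]) : r[j];
    return dur * rate;
  }

  void refresh_lik() {
    if (!use_lik) { loglik = 0.0; return; }
    for (int j = 0; j < nbranch; ++j) b[j] = branch_len(j);
    loglik = 0.0;
    for (int p = 0; p < npart; ++p) {
      for (int j = 0; j < nbranch; ++j) z[p][j] = b[j] - bhat[p][j];
      for (int i = 0; i < nbranch; ++i) {
        double acc = 0.0;
        const double* Hi = &H[p][(size_t)i * nbranch];
        for (int j = 0; j < nbranch; ++j) acc += Hi[j] * z[p][j];
        Hz[p][i] = acc;
        loglik += g[p][i] * z[p][i] + 0.5 * z[p][i] * acc;
      }
    }
  }

  double delta_loglik(const std::vector<int>& S,
                      const std::vector<double>& newb) const {
    if (!use_lik) return 0.0;
    double d = 0.0;
    for (int p = 0; p < npart; ++p) {
      double lin = 0.0, quad = 0.0;
      for (size_t a = 0; a < S.size(); ++a) {
        int i = S[a];
        double di = newb[a] - b[i];
        lin += di * (g[p][i] + Hz[p][i]);
        const double* Hi = &H[p][(size_t)i * nbranch];
        for (size_t c = 0; c < S.size(); ++c)
          quad += di * Hi[S[c]] * (newb[c] - b[S[c]]);
      }
      d += lin + 0.5 * quad;
    }
    return d;
  }

  void apply_delta(const std::vector<int>& S, const std::vector<double>& newb) {
    if (!use_lik) return;
    for (int p = 0; p < npart; ++p)
      for (size_t a = 0; a < S.size(); ++a) {
        int i = S[a];
        double di = newb[a] - b[i];
        z[p][i] += di;
        for (int k = 0; k < nbranch; ++k)
          Hz[p][k] += H[p][(size_t)k * nbranch + i] * di;
      }
    for (size_t a = 0; a < S.size(); ++a) b[S[a]] = newb[a];
  }

  void touching(int i, std::vector<int>& S) const {
    S.clear();
    if (node2b[i] >= 0) S.push_back(node2b[i]);
    for (size_t c = 0; c < children[i].size(); ++c)
      S.push_back(node2b[children[i][c]]);
  }
};

struct MoveStats { double att = 0, acc = 0; };

static inline double tuned(double sc, double rate, double target,
                           double lo, double hi) {
  sc *= std::exp(0.7 * (rate - target));
  return std::min(std::max(sc, lo), hi);
}

// [[Rcpp::export]]
List date_mcmc_cpp(List tree, List calinfo, List clock, List lik,
                   List settings, NumericVector init_ages, double init_mu,
                   double init_s2) {
  Model M;
  M.ntip = as<int>(tree["ntip"]);
  M.ntot = as<int>(tree["ntot"]);
  M.root = M.ntip; // 0-based: tips 0..ntip-1, root = ntip
  IntegerVector par = tree["parent"];
  M.parent.assign(par.begin(), par.end());
  List ch = tree["children"];
  M.children.resize(M.ntot);
  for (int i = 0; i < M.ntot; ++i) {
    IntegerVector ci = ch[i];
    M.children[i].assign(ci.begin(), ci.end());
  }
  IntegerVector bn = tree["bnode"];
  M.bnode.assign(bn.begin(), bn.end());
  M.nbranch = M.bnode.size();
  M.node2b.assign(M.ntot, -1);
  for (int j = 0; j < M.nbranch; ++j) M.node2b[M.bnode[j]] = j;
  for (int i = 0; i < M.ntot; ++i)
    if (!M.children[i].empty()) M.internals.push_back(i);

  IntegerVector ct = calinfo["type"];
  M.ctype.assign(ct.begin(), ct.end());
  NumericVector v1 = calinfo["tmin"], v2 = calinfo["tmax"],
                v3 = calinfo["pl"], v4 = calinfo["pu"];
  M.tmin.assign(v1.begin(), v1.end());
  M.tmax.assign(v2.begin(), v2.end());
  M.pl.assign(v3.begin(), v3.end());
  M.pu.assign(v4.begin(), v4.end());
  M.logh.assign(M.ntot, 0.0);
  M.theta.assign(M.ntot, 0.0);
  M.lam.assign(M.ntot, 0.0);
  for (int i = 0; i < M.ntot; ++i)
    if (M.ctype[i] == 1) {
      double h = (1.0 - M.pl[i] - M.pu[i]) / (M.tmax[i] - M.tmin[i]);
      M.logh[i] = std::log(h);
      M.theta[i] = M.pl[i] > 0 ? h * M.tmin[i] / M.pl[i] : 0.0;
      M.lam[i] = M.pu[i] > 0 ? h / M.pu[i] : 0.0;
    }
  List rf = tree["refs"];
  M.refs.resize(M.ntot);
  for (int i = 0; i < M.ntot; ++i) {
    IntegerVector ri = rf[i];
    M.refs[i].assign(ri.begin(), ri.end());
  }
  NumericVector cs = tree["cst"];
  M.cst.assign(cs.begin(), cs.end());

  // age-term dependency lists: moving node i touches its own term, its
  // parent's (ordering / seq width), its internal children's (seq width and
  // ordering live in the child term? ordering vs children lives in i's own
  // term; the child's seq density references t[i]) and, when i is
  // calibrated, every seq node whose boundary references i.
  M.aff_age.resize(M.ntot);
  {
    std::vector<std::vector<int>> rev(M.ntot);
    for (size_t k = 0; k < M.internals.size(); ++k) {
      int i = M.internals[k];
      for (size_t m = 0; m < M.refs[i].size(); ++m)
        rev[M.refs[i][m]].push_back(i);
    }
    for (size_t k = 0; k < M.internals.size(); ++k) {
      int i = M.internals[k];
      std::vector<int> a;
      a.push_back(i);
      if (M.parent[i] >= 0) a.push_back(M.parent[i]);
      for (size_t c = 0; c < M.children[i].size(); ++c) {
        int cc = M.children[i][c];
        if (!M.children[cc].empty() && M.ctype[cc] != 1) a.push_back(cc);
      }
      for (size_t m = 0; m < rev[i].size(); ++m) a.push_back(rev[i][m]);
      std::sort(a.begin(), a.end());
      a.erase(std::unique(a.begin(), a.end()), a.end());
      M.aff_age[i] = a;
    }
  }

  M.ar = as<int>(clock["ar"]) == 1;
  M.tau0 = as<double>(clock["tau0"]);
  M.mu_shape = as<double>(clock["mu_shape"]);
  M.mu_scale = as<double>(clock["mu_scale"]);
  M.s2_shape = as<double>(clock["s2_shape"]);
  M.s2_scale = as<double>(clock["s2_scale"]);

  M.use_lik = as<bool>(lik["use"]);
  M.npart = 0;
  if (M.use_lik) {
    List lb = lik["bhat"], lg = lik["g"], lH = lik["H"];
    M.npart = lb.size();
    for (int p = 0; p < M.npart; ++p) {
      NumericVector bb = lb[p], gg = lg[p];
      NumericMatrix HH = lH[p];
      M.bhat.push_back(std::vector<double>(bb.begin(), bb.end()));
      M.g.push_back(std::vector<double>(gg.begin(), gg.end()));
      std::vector<double> Hrow((size_t)M.nbranch * M.nbranch);
      for (int i = 0; i < M.nbranch; ++i)
        for (int j = 0; j < M.nbranch; ++j)
          Hrow[(size_t)i * M.nbranch + j] = HH(i, j);
      M.H.push_back(Hrow);
    }
    M.z.assign(M.npart, std::vector<double>(M.nbranch));
    M.Hz.assign(M.npart, std::vector<double>(M.nbranch));
    M.b.assign(M.nbranch, 0.0);
  }

  int burn = as<int>(settings["burn"]);
  int every = as<int>(settings["every"]);
  int nsamp = as<int>(settings["nsamp"]);
  bool mixing = as<bool>(settings["mixing"]);
  int n_mix = as<int>(settings["n_mix"]);

  M.t.assign(init_ages.begin(), init_ages.end());
  M.mu = init_mu;
  M.s2 = init_s2;
  int nrate = M.ar ? M.ntot : M.nbranch;
  M.r.assign(nrate, init_mu);
  M.lr.assign(nrate, std::log(init_mu));
  M.at.assign(M.ntot, 0.0);
  M.rp.assign(M.nbranch, 0.0);

  M.refresh_age_prior();
  M.refresh_rate_prior();
  M.lp_hyper = M.hyper_log_prior();
  M.refresh_lik();
  if (!std::isfinite(M.lp_age) || !std::isfinite(M.lp_rate))
    stop("infeasible starting state");

  int nint = (int)M.internals.size();
  std::vector<double> sc_age(M.ntot, 0.5); // fraction of the local window
  double sc_root = 0.3, sc_rate = 0.5, sc_mu = 0.3, sc_s2 = 0.8,
         sc_mix = 0.1, sc_rsc = 0.2;
  std::vector<MoveStats> st_node(M.ntot);
  MoveStats st_age, st_root, st_rate, st_mu, st_s2, st_mix, st_rsc;
  const double target = 0.3;

  NumericMatrix out_ages(nsamp, nint), out_rates(nsamp, nrate);
  NumericVector out_mu(nsamp), out_s2(nsamp), out_ll(nsamp), out_lp(nsamp);

  std::vector<int> S, Sall;
  std::vector<double> newb, newterm, newball;
  long total_sweeps = (long)burn + (long)every * nsamp;
  int stored = 0;

  for (long sweep = 0; sweep < total_sweeps; ++sweep) {
    bool in_burn = sweep < burn;
    // -- node ages --------------------------------------------------------
    for (int k = 0; k < nint; ++k) {
      int i = M.internals[k];
      double told = M.t[i], lhr = 0.0, tnew;
      double lo = 0.0;
      for (size_t c = 0; c < M.children[i].size(); ++c)
        lo = std::max(lo, M.t[M.children[i][c]]);
      if (i == M.root) {
        double w = std::exp(sc_root * (unif_rand() - 0.5));
        tnew = lo + (told - lo) * w;
        lhr = std::log(w);
        st_root.att += 1;
      } else {
        double hi = M.t[M.parent[i]];
        double w = sc_age[i] * (hi - lo);
        tnew = told + w * (unif_rand() - 0.5);
        for (int guard = 0; guard < 100 && (tnew < lo || tnew > hi); ++guard) {
          if (tnew < lo) tnew = 2 * lo - tnew;
          if (tnew > hi) tnew = 2 * hi - tnew;
        }
        st_age.att += 1;
        st_node[i].att += 1;
      }
      M.t[i] = tnew;
      const std::vector<int>& A = M.aff_age[i];
      newterm.resize(A.size());
      double d_age = 0.0;
      for (size_t a = 0; a < A.size(); ++a) {
        newterm[a] = M.term_age(A[a]);
        d_age += newterm[a] - M.at[A[a]];
      }
      double d_rate = 0.0, dll = 0.0;
      bool ok = std::isfinite(d_age);
      std::vector<double> newrp;
      if (ok) {
        M.touching(i, S);
        if (M.ar) {
          newrp.resize(S.size());
          for (size_t a = 0; a < S.size(); ++a) {
            newrp[a] = M.term_rate(S[a]);
            d_rate += newrp[a] - M.rp[S[a]];
          }
          ok = std::isfinite(d_rate);
        }
        if (ok && M.use_lik) {
          newb.resize(S.size());
          for (size_t a = 0; a < S.size(); ++a) newb[a] = M.branch_len(S[a]);
          dll = M.delta_loglik(S, newb);
        }
      }
      double lrr = ok ? d_age + d_rate + dll + lhr : NEG_INF;
      if (std::log(unif_rand()) < lrr) {
        for (size_t a = 0; a < A.size(); ++a) M.at[A[a]] = newterm[a];
        if (M.ar) for (size_t a = 0; a < S.size(); ++a) M.rp[S[a]] = newrp[a];
        M.lp_age += d_age; M.lp_rate += d_rate; M.loglik += dll;
        if (M.use_lik) M.apply_delta(S, newb);
        if (i == M.root) st_root.acc += 1;
        else { st_age.acc += 1; st_node[i].acc += 1; }
      } else {
        M.t[i] = told;
      }
    }
    // -- rates ------------------------------------------------------------
    for (int j = 0; j < nrate; ++j) {
      double rold = M.r[j], lrold = M.lr[j];
      double rnew = rold * std::exp(sc_rate * (unif_rand() - 0.5));
      st_rate.att += 1;
      M.r[j] = rnew;
      M.lr[j] = std::log(rnew);
      double d_rate = 0.0, dll = 0.0;
      double new_root = M.rp_root;
      if (M.ar) {
        M.touching(j, S); // node j's adjacent branches
        newterm.resize(S.size());
        for (size_t a = 0; a < S.size(); ++a) {
          newterm[a] = M.term_rate(S[a]);
          d_rate += newterm[a] - M.rp[S[a]];
        }
        if (j == M.root) {
          new_root = M.term_rate_root();
          d_rate += new_root - M.rp_root;
        }
      } else {
        S.assign(1, j);
        newterm.resize(1);
        newterm[0] = M.term_rate(j);
        d_rate = newterm[0] - M.rp[j];
      }
      bool ok = std::isfinite(d_rate);
      if (ok && M.use_lik) {
        if (!M.ar) { /* S already {j} */ }
        newb.resize(S.size());
        for (size_t a = 0; a < S.size(); ++a) newb[a] = M.branch_len(S[a]);
        dll = M.delta_loglik(S, newb);
      }
      double lrr = ok ? d_rate + dll + std::log(rnew / rold) : NEG_INF;
      if (std::log(unif_rand()) < lrr) {
        for (size_t a = 0; a < S.size(); ++a) M.rp[S[a]] = newterm[a];
        M.rp_root = new_root;
        M.lp_rate += d_rate; M.loglik += dll;
        if (M.use_lik) M.apply_delta(S, newb);
        st_rate.acc += 1;
      } else {
        M.r[j] = rold; M.lr[j] = lrold;
      }
    }
    // -- hyperparameters --------------------------------------------------
    {
      double old = M.mu;
      double prop = old * std::exp(sc_mu * (unif_rand() - 0.5));
      st_mu.att += 1;
      M.mu = prop;
      if (M.ar) { // mu enters only the root-rate term
        double new_root = M.term_rate_root();
        double lpH = M.hyper_log_prior();
        double lrr = (new_root - M.rp_root) + (lpH - M.lp_hyper) +
                     std::log(prop / old);
        if (std::isfinite(new_root) && std::log(unif_rand()) < lrr) {
          M.lp_rate += new_root - M.rp_root;
          M.rp_root = new_root; M.lp_hyper = lpH; st_mu.acc += 1;
        } else M.mu = old;
      } else {
        double lp_old = M.lp_rate;
        std::vector<double> rp_old = M.rp;
        double rr_old = M.rp_root;
        M.refresh_rate_prior();
        double lpH = M.hyper_log_prior();
        double lrr = (M.lp_rate - lp_old) + (lpH - M.lp_hyper) +
                     std::log(prop / old);
        if (std::isfinite(M.lp_rate) && std::log(unif_rand()) < lrr) {
          M.lp_hyper = lpH; st_mu.acc += 1;
        } else { M.mu = old; M.rp = rp_old; M.rp_root = rr_old; M.lp_rate = lp_old; }
      }
    }
    {
      double old = M.s2;
      double prop = old * std::exp(sc_s2 * (unif_rand() - 0.5));
      st_s2.att += 1;
      M.s2 = prop;
      double lp_old = M.lp_rate;
      std::vector<double> rp_old = M.rp;
      double rr_old = M.rp_root;
      M.refresh_rate_prior();
      double lpH = M.hyper_log_prior();
      double lrr = (M.lp_rate - lp_old) + (lpH - M.lp_hyper) +
                   std::log(prop / old);
      if (std::isfinite(M.lp_rate) && std::log(unif_rand()) < lrr) {
        M.lp_hyper = lpH; st_s2.acc += 1;
      } else { M.s2 = old; M.rp = rp_old; M.rp_root = rr_old; M.lp_rate = lp_old; }
    }
    // -- whole-tree mixing moves ------------------------------------------
    // (i) scale ages by c, rates and mu by 1/c (branch lengths invariant;
    // this is the slow posterior direction, so it is attempted several
    // times per sweep); (ii) scale rates and mu jointly by c (ages fixed).
    if (mixing) for (int rep = 0; rep < n_mix; ++rep) {
      double c = std::exp(sc_mix * (unif_rand() - 0.5));
      st_mix.att += 1;
      std::vector<double> t_old = M.t, r_old = M.r, lr_old = M.lr;
      std::vector<double> at_old = M.at, rp_old = M.rp;
      double mu_old = M.mu, rr_old = M.rp_root;
      double lpA_old = M.lp_age, lpR_old = M.lp_rate, lpH_old = M.lp_hyper;
      double lc = std::log(c);
      for (int k = 0; k < nint; ++k) M.t[M.internals[k]] *= c;
      for (int j = 0; j < nrate; ++j) { M.r[j] /= c; M.lr[j] -= lc; }
      M.mu /= c;
      double lhr = (nint - nrate - 1) * lc;
      M.refresh_age_prior();
      M.refresh_rate_prior();
      double lpH = M.hyper_log_prior();
      // branch lengths are invariant: durations scale by c, rates by 1/c
      double lrr = (M.lp_age - lpA_old) + (M.lp_rate - lpR_old) +
                   (lpH - lpH_old) + lhr;
      if (std::isfinite(M.lp_age) && std::isfinite(M.lp_rate) &&
          std::log(unif_rand()) < lrr) {
        M.lp_hyper = lpH;
        st_mix.acc += 1;
      } else {
        M.t = t_old; M.r = r_old; M.lr = lr_old; M.mu = mu_old;
        M.at = at_old; M.rp = rp_old; M.rp_root = rr_old;
        M.lp_age = lpA_old; M.lp_rate = lpR_old; M.lp_hyper = lpH_old;
      }
    }
    if (mixing) {
      double c = std::exp(sc_rsc * (unif_rand() - 0.5));
      st_rsc.att += 1;
      std::vector<double> r_old = M.r, lr_old = M.lr, rp_old = M.rp;
      double mu_old = M.mu, rr_old = M.rp_root, lpR_old = M.lp_rate;
      double lc = std::log(c);
      for (int j = 0; j < nrate; ++j) { M.r[j] *= c; M.lr[j] += lc; }
      M.mu *= c;
      double lhr = (nrate + 1) * lc;
      M.refresh_rate_prior();
      double lpH = M.hyper_log_prior();
      double dll = 0.0;
      bool ok = std::isfinite(M.lp_rate);
      if (ok && M.use_lik) {
        // all branch lengths scale by c
        Sall.resize(M.nbranch); newball.resize(M.nbranch);
        for (int j = 0; j < M.nbranch; ++j) { Sall[j] = j; newball[j] = M.b[j] * c; }
        dll = M.delta_loglik(Sall, newball);
      }
      double lrr = ok ? (M.lp_rate - lpR_old) + (lpH - M.lp_hyper) + dll + lhr
                      : NEG_INF;
      if (ok && std::log(unif_rand()) < lrr) {
        M.lp_hyper = lpH; M.loglik += dll;
        if (M.use_lik) M.apply_delta(Sall, newball);
        st_rsc.acc += 1;
      } else {
        M.r = r_old; M.lr = lr_old; M.mu = mu_old;
        M.rp = rp_old; M.rp_root = rr_old; M.lp_rate = lpR_old;
      }
    }
    // -- adaptation (burn-in only) / drift refresh ------------------------
    if (in_burn && (sweep + 1) % 200 == 0) {
      for (int k = 0; k < nint; ++k) {
        int i = M.internals[k];
        if (i == M.root || st_node[i].att == 0) continue;
        sc_age[i] = tuned(sc_age[i], st_node[i].acc / st_node[i].att, target,
                          1e-4, 1.0);
        st_node[i].att = st_node[i].acc = 0;
      }
      if (st_root.att > 0) {
        sc_root = tuned(sc_root, st_root.acc / st_root.att, target, 1e-4, 20.0);
        st_root.att = st_root.acc = 0;
      }
      if (st_rate.att > 0) {
        sc_rate = tuned(sc_rate, st_rate.acc / st_rate.att, target, 1e-3, 20.0);
        st_rate.att = st_rate.acc = 0;
      }
      if (st_mu.att > 0) {
        sc_mu = tuned(sc_mu, st_mu.acc / st_mu.att, target, 1e-3, 20.0);
        st_mu.att = st_mu.acc = 0;
      }
      if (st_s2.att > 0) {
        sc_s2 = tuned(sc_s2, st_s2.acc / st_s2.att, target, 1e-3, 20.0);
        st_s2.att = st_s2.acc = 0;
      }
      if (st_mix.att > 0) {
        sc_mix = tuned(sc_mix, st_mix.acc / st_mix.att, target, 1e-4, 5.0);
        st_mix.att = st_mix.acc = 0;
      }
      if (st_rsc.att > 0) {
        sc_rsc = tuned(sc_rsc, st_rsc.acc / st_rsc.att, target, 1e-4, 5.0);
        st_rsc.att = st_rsc.acc = 0;
      }
      st_age.att = st_age.acc = 0;
    }
    if ((sweep + 1) % 20000 == 0) {
      M.refresh_lik();
      M.refresh_age_prior();
      M.refresh_rate_prior();
      M.lp_hyper = M.hyper_log_prior();
      Rcpp::checkUserInterrupt();
    }
    // -- record -----------------------------------------------------------
    if (!in_burn && ((sweep - burn + 1) % every == 0) && stored < nsamp) {
      for (int k = 0; k < nint; ++k) out_ages(stored, k) = M.t[M.internals[k]];
      for (int j = 0; j < nrate; ++j) out_rates(stored, j) = M.r[j];
      out_mu[stored] = M.mu;
      out_s2[stored] = M.s2;
      out_ll[stored] = M.loglik;
      out_lp[stored] = M.lp_age + M.lp_rate + M.lp_hyper + M.loglik;
      ++stored;
    }
  }

  NumericVector acc = NumericVector::create(
    _["age"] = st_age.att > 0 ? st_age.acc / st_age.att : NA_REAL,
    _["root"] = st_root.att > 0 ? st_root.acc / st_root.att : NA_REAL,
    _["rate"] = st_rate.att > 0 ? st_rate.acc / st_rate.att : NA_REAL,
    _["mu"] = st_mu.att > 0 ? st_mu.acc / st_mu.att : NA_REAL,
    _["sigma2"] = st_s2.att > 0 ? st_s2.acc / st_s2.att : NA_REAL,
    _["mixing"] = st_mix.att > 0 ? st_mix.acc / st_mix.att : NA_REAL,
    _["rate_scale"] = st_rsc.att > 0 ? st_rsc.acc / st_rsc.att : NA_REAL);
  NumericVector scales = NumericVector::create(
    _["root"] = sc_root, _["rate"] = sc_rate, _["mu"] = sc_mu,
    _["sigma2"] = sc_s2, _["mixing"] = sc_mix, _["rate_scale"] = sc_rsc);

  return List::create(_["ages"] = out_ages, _["rates"] = out_rates,
                      _["mu"] = out_mu, _["sigma2"] = out_s2,
                      _["loglik"] = out_ll, _["logpost"] = out_lp,
                      _["accept"] = acc, _["scales"] = scales);
}
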