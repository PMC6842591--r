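// Germline-rooted Felsenstein pruning for 61-state codon models, plus the
// eigendecomposition machinery used to turn a generator Q into transition
// probabilities P(t) = exp(Qt). The models here are nonreversible, so Q is
// decomposed with a general (complex) eigensolver; when the eigenvector
// matrix is ill-conditioned the code falls back to a Pade matrix exponential
// per branch. Branch-length optimization caches the per-edge P matrices so a
// univariate probe only rebuilds the pair belonging to the probed branch.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct Eig {
  arma::cx_mat V, Vi;
  arma::cx_vec d;
  arma::mat Q;
  bool ok;
};

static Eig eig_from_list(const List& e) {
  Eig out;
  out.V = as<arma::cx_mat>(e["V"]);
  out.Vi = as<arma::cx_mat>(e["Vi"]);
  out.d = as<arma::cx_vec>(e["d"]);
  out.Q = as<arma::mat>(e["Q"]);
  out.ok = as<bool>(e["ok"]);
  return out;
}

// Decompose a generator once so that P(t) along every branch costs only two
// 61x61 complex products.
// [[Rcpp::export]]
List cpp_eig_q(const arma::mat& Q) {
  arma::cx_vec d;
  arma::cx_mat V;
  bool ok = arma::eig_gen(d, V, Q);
  arma::cx_mat Vi;
  if (ok) ok = arma::inv(Vi, V);
  if (ok) {
    arma::cx_mat I = V * Vi;
    double err = arma::abs(I - arma::eye<arma::cx_mat>(Q.n_rows, Q.n_rows)).max();
    if (!(err < 1e-8)) ok = false;
  }
  if (!ok) {
    Vi = arma::cx_mat(Q.n_rows, Q.n_rows, arma::fill::zeros);
    V = Vi;
    d = arma::cx_vec(Q.n_rows, arma::fill::zeros);
  }
  return List::create(_["V"] = V, _["Vi"] = Vi, _["d"] = d,
                      _["Q"] = Q, _["ok"] = ok);
}

static arma::mat pmat(const Eig& e, double t) {
  arma::mat P;
  if (e.ok) {
    arma::cx_mat E = e.V * arma::diagmat(arma::exp(e.d * t)) * e.Vi;
    P = arma::real(E);
  } else {
    P = arma::expmat(e.Q * t);
  }
  P.transform([](double x) { return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x); });
  return P;
}

// [[Rcpp::export]]
arma::mat cpp_pmat(const List& eig, double t) {
  return pmat(eig_from_list(eig), t);
}

// Lineage data in engine form (see prep_lineage() on the R side):
// tips   n_tips x S codon indices, 0-based, -1 = missing
// germ   S germline codon indices (root state)
// mask   S region codes, 0 = FWR, 1 = CDR
// edges  E x 2 (parent, child) node ids, postorder; tips are 0..n_tips-1
struct LinData {
  arma::imat tips;
  arma::ivec germ, mask;
  arma::imat edges;
  int n_nodes, root;
};

static LinData lin_from_list(const List& l) {
  LinData d;
  d.tips = as<arma::imat>(l["tips"]);
  d.germ = as<arma::ivec>(l["germ"]);
  d.mask = as<arma::ivec>(l["mask"]);
  d.edges = as<arma::imat>(l["edges"]);
  d.n_nodes = as<int>(l["n_nodes"]);
  d.root = as<int>(l["root"]);
  return d;
}

// Pruning with precomputed per-edge transition matrices.
static double prune_ll(const std::vector<arma::mat>& PF,
                       const std::vector<arma::mat>& PC,
                       const LinData& L, int root_mode,
                       const arma::vec& pi) {
  const int S = L.germ.n_elem;
  const int T = L.tips.n_rows;
  const int K = 61;
  const int E = L.edges.n_rows;

  std::vector<arma::mat> part(L.n_nodes);
  std::vector<bool> touched(L.n_nodes, false);
  arma::vec slog(S, arma::fill::zeros);

  for (int e = 0; e < E; ++e) {
    int p = L.edges(e, 0), c = L.edges(e, 1);
    arma::mat Lc;
    if (c < T) {
      Lc.zeros(K, S);
      for (int s = 0; s < S; ++s) {
        int st = L.tips(c, s);
        if (st < 0) Lc.col(s).ones(); else Lc(st, s) = 1.0;
      }
    } else {
      if (!touched[c]) stop("postorder violated: child partial missing");
      Lc = part[c];
    }
    arma::mat MF = PF[e] * Lc;
    arma::mat MC = PC[e] * Lc;
    if (!touched[p]) {
      part[p].ones(K, S);
      touched[p] = true;
    }
    for (int s = 0; s < S; ++s) {
      part[p].col(s) %= (L.mask[s] == 0) ? MF.col(s) : MC.col(s);
      double m = part[p].col(s).max();
      if (m > 0.0 && m < 1e-200) {
        part[p].col(s) /= m;
        slog[s] += std::log(m);
      }
    }
    if (c >= T) part[c].reset();
  }
  if (!touched[L.root]) stop("root partial never formed (empty tree?)");

  double ll = 0.0;
  for (int s = 0; s < S; ++s) {
    double v = part[L.root](L.germ[s], s);
    if (root_mode == 1) v *= pi[L.germ[s]];
    if (v <= 0.0) return -std::numeric_limits<double>::infinity();
    ll += std::log(v) + slog[s];
  }
  return ll;
}

static void build_P(const Eig& eF, const Eig& eC, const NumericVector& bl,
                    std::vector<arma::mat>& PF, std::vector<arma::mat>& PC) {
  const int E = bl.size();
  PF.resize(E);
  PC.resize(E);
  for (int e = 0; e < E; ++e) {
    PF[e] = pmat(eF, bl[e]);
    PC[e] = pmat(eC, bl[e]);
  }
}

// [[Rcpp::export]]
double cpp_lineage_loglik(const List& eigF, const List& eigC,
                          const List& lin, const NumericVector& bl,
                          int root_mode, const arma::vec& pi) {
  Eig eF = eig_from_list(eigF), eC = eig_from_list(eigC);
  LinData L = lin_from_list(lin);
  std::vector<arma::mat> PF, PC;
  build_P(eF, eC, bl, PF, PC);
  return prune_ll(PF, PC, L, root_mode, pi);
}

// Sum of lineage log-likelihoods under one shared pair of region matrices.
// [[Rcpp::export]]
NumericVector cpp_repertoire_loglik(const List& eigF, const List& eigC,
                                    const List& lins, const List& bls,
                                    int root_mode, const arma::vec& pi) {
  Eig eF = eig_from_list(eigF), eC = eig_from_list(eigC);
  const int n = lins.size();
  NumericVector out(n);
  std::vector<arma::mat> PF, PC;
  for (int i = 0; i < n; ++i) {
    LinData L = lin_from_list(lins[i]);
    NumericVector bl = bls[i];
    build_P(eF, eC, bl, PF, PC);
    out[i] = prune_ll(PF, PC, L, root_mode, pi);
  }
  return out;
}

// Brent's univariate minimizer on [a, b] (no derivatives).
template <typename F>
static double brent_min(F f, double a, double b, double tol, double& fmin) {
  const double gold = 0.3819660112501051;
  double x = a + gold * (b - a), w = x, v = x;
  double fx = f(x), fw = fx, fv = fx;
  double d = 0.0, e = 0.0;
  for (int iter = 0; iter < 60; ++iter) {
    double m = 0.5 * (a + b);
    double tol1 = tol * std::fabs(x) + 1e-10;
    double tol2 = 2.0 * tol1;
    if (std::fabs(x - m) <= tol2 - 0.5 * (b - a)) break;
    double p = 0, q = 0, r = 0;
    bool use_golden = true;
    if (std::fabs(e) > tol1) {
      r = (x - w) * (fx - fv);
      q = (x - v) * (fx - fw);
      p = (x - v) * q - (x - w) * r;
      q = 2.0 * (q - r);
      if (q > 0) p = -p;
      q = std::fabs(q);
      double etemp = e;
      e = d;
      if (!(std::fabs(p) >= std::fabs(0.5 * q * etemp) || p <= q * (a - x) ||
            p >= q * (b - x))) {
        use_golden = false;
        d = p / q;
        double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (m > x) ? tol1 : -tol1;
      }
    }
    if (use_golden) {
      e = (x < m) ? b - x : a - x;
      d = gold * e;
    }
    double u = (std::fabs(d) >= tol1) ? x + d : x + ((d > 0) ? tol1 : -tol1);
    double fu = f(u);
    if (fu <= fx) {
      if (u < x) b = x; else a = x;
      v = w; fv = fw; w = x; fw = fx; x = u; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu <= fw || w == x) {
        v = w; fv = fw; w = u; fw = fu;
      } else if (fu <= fv || v == x || v == w) {
        v = u; fv = fu;
      }
    }
  }
  fmin = fx;
  return x;
}

// Coordinate sweeps over branch lengths of one lineage: per branch, a Brent
// minimization of the negative log-likelihood with every other edge's P
// matrices cached. Returns the optimized lengths and final log-likelihood.
// [[Rcpp::export]]
List cpp_branch_sweep(const List& eigF, const List& eigC, const List& lin,
                      NumericVector bl, int root_mode, const arma::vec& pi,
                      int n_sweeps, double max_bl, double tol) {
  Eig eF = eig_from_list(eigF), eC = eig_from_list(eigC);
  LinData L = lin_from_list(lin);
  const int E = bl.size();
  std::vector<arma::mat> PF, PC;
  build_P(eF, eC, bl, PF, PC);
  double ll = prune_ll(PF, PC, L, root_mode, pi);

  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    double ll_start = ll;
    for (int e = 0; e < E; ++e) {
      double cur = bl[e];
      auto f = [&](double t) {
        PF[e] = pmat(eF, t);
        PC[e] = pmat(eC, t);
        return -prune_ll(PF, PC, L, root_mode, pi);
      };
      double hi = std::min(max_bl, std::max(0.5, cur * 5.0 + 0.1));
      double fbest;
      double tbest = brent_min(f, 0.0, hi, tol, fbest);
      if (-fbest >= ll) {
        bl[e] = tbest;
        ll = -fbest;
        PF[e] = pmat(eF, tbest);
        PC[e] = pmat(eC, tbest);
      } else {
        PF[e] = pmat(eF, cur);
        PC[e] = pmat(eC, cur);
      }
    }
    if (ll - ll_start < 1e-4) break;
  }
  return List::create(_["bl"] = bl, _["ll"] = ll);
}
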