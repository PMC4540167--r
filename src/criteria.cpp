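// Hot loops for design search: log-determinant criterion pairs, rook-clique
// local search, and the simulated-annealing scheme. All evaluations index
// into precomputed full-candidate-set matrices; R owns every convention
// (tie-breaks, tolerances) that is not purely arithmetic.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// log det of the trend block F'C^-1F / sigma2 and of the covariance block
// M_nu[k,l] = tr(C^-1 dC_k C^-1 dC_l)/2 for the design given by 0-based idx.
// Returns {ldb, ldn}; -inf components signal singularity.
static void crit_pair(const arma::uvec& id, const arma::mat& C,
                      const std::vector<arma::mat>& dC, const arma::mat& F,
                      double sigma2, double& ldb, double& ldn) {
  const arma::uword n = id.n_elem, s = dC.size();
  arma::mat Cs = C.submat(id, id);
  arma::mat Ci;
  if (!arma::inv_sympd(Ci, Cs)) { ldb = ldn = -arma::datum::inf; return; }
  arma::mat Fs = F.rows(id);
  arma::mat Mb = Fs.t() * Ci * Fs / sigma2;
  double sign;
  if (!arma::log_det(ldb, sign, Mb) || sign <= 0) ldb = -arma::datum::inf;
  std::vector<arma::mat> A(s);
  for (arma::uword k = 0; k < s; ++k) A[k] = Ci * dC[k].submat(id, id);
  arma::mat Mnu(s, s);
  for (arma::uword k = 0; k < s; ++k)
    for (arma::uword l = k; l < s; ++l) {
      double v = 0.5 * arma::accu(A[k] % A[l].t());
      Mnu(k, l) = Mnu(l, k) = v;
    }
  if (!arma::log_det(ldn, sign, Mnu) || sign <= 0) ldn = -arma::datum::inf;
  (void)n;
}

static std::vector<arma::mat> as_mat_list(const List& dC) {
  std::vector<arma::mat> out;
  for (int k = 0; k < dC.size(); ++k) out.push_back(as<arma::mat>(dC[k]));
  return out;
}

static double jval(double ldb, double ldn, double alpha) {
  if (alpha >= 1.0) return ldb;
  if (alpha <= 0.0) return ldn;
  if (!std::isfinite(ldb) || !std::isfinite(ldn)) return -arma::datum::inf;
  return alpha * ldb + (1.0 - alpha) * ldn;
}

// [[Rcpp::export]]
NumericVector critPairCpp(IntegerVector idx, const arma::mat& C, List dC,
                          const arma::mat& F, double sigma2) {
  arma::uvec id = as<arma::uvec>(idx);
  std::vector<arma::mat> d = as_mat_list(dC);
  double ldb, ldn;
  crit_pair(id, C, d, F, sigma2, ldb, ldn);
  return NumericVector::create(_["c_beta"] = ldb, _["c_nu"] = ldn);
}

// [[Rcpp::export]]
NumericMatrix critPairBatchCpp(IntegerMatrix designs, const arma::mat& C,
                               List dC, const arma::mat& F, double sigma2) {
  std::vector<arma::mat> d = as_mat_list(dC);
  const int m = designs.nrow(), n = designs.ncol();
  NumericMatrix out(m, 2);
  arma::uvec id(n);
  for (int r = 0; r < m; ++r) {
    for (int j = 0; j < n; ++j) id(j) = designs(r, j);
    double ldb, ldn;
    crit_pair(id, C, d, F, sigma2, ldb, ldn);
    out(r, 0) = ldb; out(r, 1) = ldn;
  }
  colnames(out) = CharacterVector::create("c_beta", "c_nu");
  return out;
}

// One full local search: scan design positions in order, try each rook
// neighbour not already in the design, keep strict improvements, repeat
// until a complete pass improves nothing. neigh is Q x maxdeg, -1 padded.
static double local_opt(arma::uvec& id, std::vector<bool>& in_design,
                        const arma::mat& C, const std::vector<arma::mat>& dC,
                        const arma::mat& F, double sigma2,
                        const IntegerMatrix& neigh, double alpha,
                        double J_cur, long& evals) {
  const arma::uword n = id.n_elem;
  const int maxdeg = neigh.ncol();
  bool improved = true;
  while (improved) {
    improved = false;
    for (arma::uword i = 0; i < n; ++i) {
      int site = id(i);
      for (int t = 0; t < maxdeg; ++t) {
        int y = neigh(site, t);
        if (y < 0) break;
        if (in_design[y]) continue;
        arma::uword old = id(i);
        id(i) = y;
        double ldb, ldn;
        crit_pair(id, C, dC, F, sigma2, ldb, ldn);
        ++evals;
        double J_try = jval(ldb, ldn, alpha);
        if (J_try > J_cur) {
          in_design[old] = false; in_design[y] = true;
          J_cur = J_try;
          improved = true;
          break;            // move on to the next design position
        }
        id(i) = old;
      }
    }
  }
  return J_cur;
}

// [[Rcpp::export]]
List localOptCpp(IntegerVector idx, const arma::mat& C, List dC,
                 const arma::mat& F, double sigma2, IntegerMatrix neigh,
                 double alpha) {
  arma::uvec id = as<arma::uvec>(idx);
  std::vector<arma::mat> d = as_mat_list(dC);
  std::vector<bool> in_design(C.n_rows, false);
  for (arma::uword i = 0; i < id.n_elem; ++i) in_design[id(i)] = true;
  long evals = 0;
  double ldb, ldn;
  crit_pair(id, C, d, F, sigma2, ldb, ldn);
  ++evals;
  double J = local_opt(id, in_design, C, d, F, sigma2, neigh, alpha,
                       jval(ldb, ldn, alpha), evals);
  return List::create(_["idx"] = IntegerVector(id.begin(), id.end()),
                      _["value"] = J, _["j_evaluations"] = (double)evals);
}

static int runif_int(int m) {            // uniform on 0..m-1 via R's RNG
  int v = (int)std::floor(unif_rand() * m);
  return v >= m ? m - 1 : v;
}

// Simulated annealing for max J_alpha: two-point replacement proposals,
// local search on each proposal, Metropolis acceptance with probability
// exp((e' - e)/T) for worse moves, geometric cooling applied only when the
// state did not change. Uses R's RNG; seed with set.seed() before calling.
// [[Rcpp::export]]
List saCpp(const arma::mat& C, List dC, const arma::mat& F, double sigma2,
           IntegerMatrix neigh, int n, double alpha, double T0, double r,
           int Nmax, IntegerVector init, bool trace) {
  RNGScope scope;
  std::vector<arma::mat> d = as_mat_list(dC);
  const int Q = C.n_rows;
  long evals = 0;
  arma::uvec cur(n);
  std::vector<bool> in_cur(Q, false);
  if (init.size() == 0) {                // uniform random initial design
    for (int i = 0; i < n; ++i) {
      int v;
      do { v = runif_int(Q); } while (in_cur[v]);
      cur(i) = v; in_cur[v] = true;
    }
  } else {
    for (int i = 0; i < n; ++i) { cur(i) = init[i]; in_cur[init[i]] = true; }
  }
  double ldb, ldn;
  crit_pair(cur, C, d, F, sigma2, ldb, ldn);
  ++evals;
  double e_cur = jval(ldb, ldn, alpha);
  arma::uvec best = cur;
  double e_best = e_cur;
  double T = T0;
  long accepted = 0;
  NumericMatrix tr(trace ? Nmax : 0, 4);
  for (int k = 0; k < Nmax; ++k) {
    // Step 1: replace two random design points by two uniform outside draws
    arma::uvec cand = cur;
    std::vector<bool> in_cand = in_cur;
    int i1 = runif_int(n);
    int i2 = runif_int(n - 1); if (i2 >= i1) ++i2;
    in_cand[cand(i1)] = false; in_cand[cand(i2)] = false;
    int y1, y2;
    do { y1 = runif_int(Q); } while (in_cur[y1]);
    do { y2 = runif_int(Q); } while (in_cur[y2] || y2 == y1);
    cand(i1) = y1; cand(i2) = y2;
    in_cand[y1] = true; in_cand[y2] = true;
    // Step 2: local optimization around the proposal
    crit_pair(cand, C, d, F, sigma2, ldb, ldn);
    ++evals;
    double e_cand = local_opt(cand, in_cand, C, d, F, sigma2, neigh, alpha,
                              jval(ldb, ldn, alpha), evals);
    // Step 3: best-solution tracking
    if (e_cand > e_best) { e_best = e_cand; best = cand; }
    // Step 4: Metropolis acceptance
    bool accept = e_cand > e_cur ||
                  unif_rand() < std::exp((e_cand - e_cur) / T);
    bool changed = false;
    if (accept) {
      changed = arma::any(arma::sort(cand) != arma::sort(cur));
      cur = cand; in_cur = in_cand; e_cur = e_cand;
      ++accepted;
    }
    // Step 5: cool only when the state did not change
    if (!changed) T *= r;
    if (trace) { tr(k, 0) = e_cand; tr(k, 1) = accept ? 1 : 0; tr(k, 2) = e_best; tr(k, 3) = T; }
  }
  return List::create(_["best"] = IntegerVector(best.begin(), best.end()),
                      _["best_value"] = e_best,
                      _["final"] = IntegerVector(cur.begin(), cur.end()),
                      _["j_evaluations"] = (double)evals,
                      _["accepted"] = (double)accepted,
                      _["trace"] = tr);
}
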