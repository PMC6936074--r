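#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Depth-first search over parent assignments pr(i) for variants 1..N on a
// square lower-triangular VAF matrix.  Node 0 is the founder (allele
// frequency 1 by convention).  Three modes share the engine:
//   0 = greedy  : candidates at each level ordered by descending clone
//                 frequency C_{(i-1),k}; the first complete valid tree wins
//                 (backtracking = advancing the per-level cursor).
//   1 = exhaustive: traverse every branch, keep the maximum-likelihood tree.
//   2 = random  : candidate order shuffled with R's RNG; first valid tree.
// Branches are pruned when the likelihood factor drops to <= tol (the
// product cannot recover: every later factor is at most 1) or when the
// child-frequency sum exceeds the parent's VAF by more than negtol (Eq. 2
// style invalidity, relaxed for noisy data).

namespace {

struct Engine {
  int N;
  const NumericMatrix& F;
  const std::vector<std::vector<int> >& cand; // allowed parents per variant
  const std::vector<std::vector<int> >& req;  // required ancestors per variant
  double tol, negtol, budget;
  int mode;
  double explored;
  bool budget_hit;
  std::vector<int> pr;                      // pr[v-1] in 0..N, -1 = unset
  std::vector<std::vector<double> > S;      // S[r][k]: sum of F(r, j-1) over
                                            // placed children j<=r+1 of k
  std::vector<int> best_pr;
  double best_ll;
  bool have_best;

  Engine(const NumericMatrix& F_, const std::vector<std::vector<int> >& cand_,
         const std::vector<std::vector<int> >& req_, int mode_, double tol_,
         double negtol_, double budget_)
      : N(F_.nrow()), F(F_), cand(cand_), req(req_), tol(tol_),
        negtol(negtol_), budget(budget_), mode(mode_), explored(0.0),
        budget_hit(false), pr(N, -1),
        S(N, std::vector<double>(N + 1, 0.0)), best_ll(R_NegInf),
        have_best(false) {}

  double fval(int r, int k) const { return k == 0 ? 1.0 : F(r, k - 1); }

  bool req_ok(int v, int k) const {
    const std::vector<int>& rq = req[v - 1];
    if (rq.empty()) return true;
    std::vector<char> anc(N + 1, 0);
    int cur = k;
    while (cur != 0) {
      anc[cur] = 1;
      cur = pr[cur - 1];
    }
    for (size_t a = 0; a < rq.size(); ++a) {
      int u = rq[a];
      if (u < 1 || u > N || !anc[u]) return false;
    }
    return true;
  }

  bool eq2_ok(int v, int k) const {
    for (int r = v - 1; r < N; ++r)
      if (S[r][k] + F(r, v - 1) > fval(r, k) + negtol + 1e-9) return false;
    return true;
  }

  void commit(int v, int k) {
    for (int r = v - 1; r < N; ++r) S[r][k] += F(r, v - 1);
    pr[v - 1] = k;
  }

  void uncommit(int v, int k) {
    for (int r = v - 1; r < N; ++r) S[r][k] -= F(r, v - 1);
    pr[v - 1] = -1;
  }

  // returns true when the search should unwind completely
  bool dfs(int v, double ll) {
    if (v > N) {
      if (!have_best || ll > best_ll + 1e-12) {
        best_ll = ll;
        best_pr = pr;
        have_best = true;
      }
      return mode != 1;
    }
    const std::vector<int>& cv = cand[v - 1];
    int m = (int)cv.size();
    std::vector<double> key(m);
    std::vector<int> idx(m);
    for (int j = 0; j < m; ++j) {
      key[j] = (v >= 2) ? fval(v - 2, cv[j]) - S[v - 2][cv[j]] : 0.0;
      idx[j] = j;
    }
    if (mode == 2) {
      for (int j = m - 1; j > 0; --j) {
        int t = (int)std::floor(unif_rand() * (j + 1));
        if (t > j) t = j;
        std::swap(idx[j], idx[t]);
      }
    } else {
      std::stable_sort(idx.begin(), idx.end(), [&](int a, int b) {
        if (key[a] != key[b]) return key[a] > key[b];
        return cv[a] < cv[b];
      });
    }
    for (int j = 0; j < m; ++j) {
      int k = cv[idx[j]];
      double c = key[idx[j]];
      if (v >= 2 && c <= tol) continue;
      if (!req_ok(v, k)) continue;
      if (!eq2_ok(v, k)) continue;
      explored += 1.0;
      if (explored > budget) {
        budget_hit = true;
        return true;
      }
      commit(v, k);
      double nll = ll + ((v >= 2) ? std::log(c) : 0.0);
      bool stop;
      if (mode == 1 && have_best && nll <= best_ll + 1e-12) {
        stop = false; // factors are <= 1, so nll bounds the final score
      } else {
        stop = dfs(v + 1, nll);
      }
      uncommit(v, k);
      if (stop) return true;
    }
    return false;
  }
};

// A birth order is statically infeasible when some variant's required
// ancestor is born at or after the variant itself: no parent assignment
// can put a later-born node on an earlier node's root path.
bool order_feasible(const std::vector<std::vector<int> >& req) {
  for (size_t i = 0; i < req.size(); ++i)
    for (size_t a = 0; a < req[i].size(); ++a)
      if (req[i][a] > (int)i) return false;  // 1-based pos vs 0-based level
  return true;
}

std::vector<std::vector<int> > as_vecvec(const List& x) {
  std::vector<std::vector<int> > out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    IntegerVector v = x[i];
    out[i].assign(v.begin(), v.end());
  }
  return out;
}

} // namespace

// Score every within-group permutation of the greedy permutation search
// in one pass.  Sref is the truncated square matrix with the current
// group's variants in reference (ascending) order occupying the last
// `block_len` positions; `base` is the group's observed row in that
// reference column order.  Permutations are enumerated in lexicographic
// order; the return value is the greedy-search log likelihood of each
// (−Inf when no valid tree exists).  Constraint sets are given per
// reference position and remapped for every permutation; `restricted`
// marks positions whose parent set is constrained (the founder becomes
// the fallback when no allowed parent is born earlier).
// [[Rcpp::export]]
NumericVector cpp_gp_score_perms(NumericMatrix Sref, NumericVector base,
                                 int block_start, int block_len,
                                 List cand, List req,
                                 LogicalVector restricted, double tol,
                                 double negtol, double budget) {
  int N = Sref.ncol();
  if (Sref.nrow() != N || base.size() != N)
    stop("reference matrix must be square with a matching base row");
  std::vector<std::vector<int> > cand_ref = as_vecvec(cand);
  std::vector<std::vector<int> > req_ref = as_vecvec(req);
  bool has_constraints = false;
  for (int i = 0; i < N; ++i)
    if (restricted[i] || !req_ref[i].empty()) has_constraints = true;

  double nperm = 1.0;
  for (int j = 2; j <= block_len; ++j) nperm *= j;
  if (nperm > 4.2e7)
    stop("mutation group of size ", block_len,
         " is infeasible for permutation search");
  NumericVector scores((R_xlen_t)nperm);

  NumericMatrix S = clone(Sref);
  std::vector<int> p(block_len);
  for (int j = 0; j < block_len; ++j) p[j] = j;
  std::vector<int> cur_of_ref(N + 1);
  for (int i = 0; i <= N; ++i) cur_of_ref[i] = i;

  // default (unconstrained) candidate sets
  std::vector<std::vector<int> > cand_def(N), req_empty(N);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k <= i; ++k) cand_def[i].push_back(k);

  std::vector<std::vector<int> > cand_cur(N), req_cur(N);
  R_xlen_t r = 0;
  do {
    // rewrite the block rows under this permutation
    for (int j = 0; j < block_len; ++j) {
      int row = block_start + j;
      for (int c = 0; c < N; ++c) {
        double v;
        if (c < block_start) v = base[c];
        else {
          int jj = c - block_start;   // block slot -> ref column
          v = base[block_start + p[jj]];
        }
        S(row, c) = (c <= row) ? v : 0.0;
      }
    }
    const std::vector<std::vector<int> >* cd = &cand_def;
    const std::vector<std::vector<int> >* rq = &req_empty;
    if (has_constraints) {
      for (int j = 0; j < block_len; ++j)
        cur_of_ref[block_start + p[j] + 1] = block_start + j + 1;  // 1-based
      for (int i = 0; i < N; ++i) {
        int ref_i = (i < block_start) ? i : block_start + p[i - block_start];
        req_cur[i].clear();
        for (size_t a = 0; a < req_ref[ref_i].size(); ++a)
          req_cur[i].push_back(cur_of_ref[req_ref[ref_i][a]]);
        cand_cur[i].clear();
        if (!restricted[ref_i]) {
          cand_cur[i] = cand_def[i];
        } else {
          for (size_t a = 0; a < cand_ref[ref_i].size(); ++a) {
            int m = cur_of_ref[cand_ref[ref_i][a]];
            if (m >= 1 && m <= i) cand_cur[i].push_back(m);
          }
          std::sort(cand_cur[i].begin(), cand_cur[i].end());
          if (cand_cur[i].empty()) cand_cur[i].push_back(0);
        }
      }
      cd = &cand_cur;
      rq = &req_cur;
    }
    if (has_constraints && !order_feasible(*rq)) {
      scores[r++] = R_NegInf;
    } else {
      Engine e(S, *cd, *rq, 0, tol, negtol, budget);
      e.dfs(1, 0.0);
      scores[r++] = e.have_best ? e.best_ll : R_NegInf;
    }
  } while (std::next_permutation(p.begin(), p.end()));
  return scores;
}

// [[Rcpp::export]]
List cpp_tree_search(NumericMatrix F, List cand, List req, int mode,
                     double tol, double negtol, double budget) {
  int N = F.ncol();
  if (F.nrow() != N) stop("F must be square");
  if ((int)cand.size() != N || (int)req.size() != N)
    stop("candidate/required lists must have one entry per variant");
  std::vector<std::vector<int> > cv = as_vecvec(cand), rv = as_vecvec(req);
  if (!order_feasible(rv)) {
    return List::create(_["pr"] = IntegerVector(N, NA_INTEGER),
                        _["status"] = 1, _["loglik"] = R_NegInf,
                        _["explored"] = 0.0);
  }
  Engine e(F, cv, rv, mode, tol, negtol, budget);
  if (N > 0) e.dfs(1, 0.0);
  int status = e.budget_hit ? 2 : (e.have_best ? 0 : 1);
  IntegerVector pr(N, NA_INTEGER);
  if (e.have_best)
    for (int i = 0; i < N; ++i) pr[i] = e.best_pr[i];
  return List::create(_["pr"] = pr, _["status"] = status,
                      _["loglik"] = e.have_best ? e.best_ll : R_NegInf,
                      _["explored"] = e.explored);
}
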