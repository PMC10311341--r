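#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// Maximum-weight clique over a match-compatibility graph.  The objective
// is the sum of vertex weights plus the sum of (auxiliary) edge weights
// inside the clique.  Exact branch-and-bound with an admissible bound:
// each candidate can contribute at most its vertex weight plus half of
// its positive edge weights to remaining candidates (every edge is
// counted once from each endpoint).  Ties in score are broken toward
// larger cliques, then toward the lexicographically smallest vertex set
// (in original vertex order), so the result is deterministic.

struct CliqueSearch {
  int n;
  std::vector<double> w;                 // vertex weights (ordered)
  std::vector<std::vector<uint64_t>> adj; // bitset adjacency (ordered ids)
  std::vector<std::vector<double>> ew;   // edge weights (ordered ids)
  std::vector<int> orig;                 // ordered id -> original id
  std::vector<int> uu, vv;               // vertex -> position labels
  std::vector<double> half_pos;          // 0.5 * sum of positive incident edges
  int max_u = 0, max_v = 0;
  int nwords;
  double best_score;
  std::vector<int> best_set;             // original ids, sorted
  double eps = 1e-9;
  long long nodes = 0;
  long long node_budget;

  bool better(double score, const std::vector<int>& set_orig) const {
    if (score > best_score + eps) return true;
    if (score < best_score - eps) return false;
    if ((int)set_orig.size() != (int)best_set.size())
      return set_orig.size() > best_set.size();
    return std::lexicographical_compare(set_orig.begin(), set_orig.end(),
                                        best_set.begin(), best_set.end());
  }

  void consider(double score, const std::vector<int>& cur) {
    std::vector<int> so;
    so.reserve(cur.size());
    for (int v : cur) so.push_back(orig[v]);
    std::sort(so.begin(), so.end());
    if (better(score, so)) { best_score = score; best_set = so; }
  }

  void expand(std::vector<int>& cur, double cur_score,
              std::vector<uint64_t>& cand) {
    if (++nodes > node_budget)
      stop("clique search exceeded node budget; use the greedy fallback");
    // collect candidate list in order
    std::vector<int> clist;
    for (int wdi = 0; wdi < nwords; ++wdi) {
      uint64_t word = cand[wdi];
      while (word) {
        int b = __builtin_ctzll(word);
        clist.push_back(wdi * 64 + b);
        word &= word - 1;
      }
    }
    if (clist.empty()) { consider(cur_score, cur); return; }
    // admissible bound: any clique extension uses at most one candidate
    // per A-position (and per B-position); each vertex can contribute at
    // most its weight, its exact edges to the current clique, and half of
    // its positive incident edge weights
    std::vector<double> umax(max_u + 1, 0.0), vmax(max_v + 1, 0.0);
    for (int v : clist) {
      double gain = w[v] + half_pos[v];
      for (int c : cur) gain += ew[v][c];
      if (gain > umax[uu[v]]) umax[uu[v]] = gain;
      if (gain > vmax[vv[v]]) vmax[vv[v]] = gain;
    }
    double bu = 0.0, bv = 0.0;
    for (double g : umax) bu += g;
    for (double g : vmax) bv += g;
    double bound = cur_score + (bu < bv ? bu : bv);
    if (bound < best_score - eps) return;
    consider(cur_score, cur);
    std::vector<uint64_t> cand2(nwords);
    for (size_t idx = 0; idx < clist.size(); ++idx) {
      int v = clist[idx];
      // candidates after v only (avoid revisiting permutations)
      double add = w[v];
      for (int c : cur) add += ew[v][c];
      for (int wdi = 0; wdi < nwords; ++wdi) cand2[wdi] = cand[wdi] & adj[v][wdi];
      // restrict to vertices after v in the ordering
      for (size_t j = 0; j <= idx; ++j) {
        int u = clist[j];
        cand2[u / 64] &= ~(1ULL << (u % 64));
      }
      cur.push_back(v);
      expand(cur, cur_score + add, cand2);
      cur.pop_back();
      // remove v from cand for subsequent branches
      cand[v / 64] &= ~(1ULL << (v % 64));
    }
  }
};

// [[Rcpp::export(name = ".cpp_max_weight_clique")]]
List cpp_max_weight_clique(NumericVector vw, IntegerMatrix adj,
                           NumericMatrix ew, IntegerVector ulab,
                           IntegerVector vlab, bool greedy = false,
                           double node_budget = 5e7) {
  int n = vw.size();
  if (n == 0) return List::create(_["vertices"] = IntegerVector(0),
                                  _["score"] = 0.0);
  // order vertices by decreasing potential for better pruning
  std::vector<double> pot(n, 0.0);
  for (int i = 0; i < n; ++i) {
    pot[i] = vw[i];
    for (int j = 0; j < n; ++j) if (ew(i, j) > 0) pot[i] += 0.5 * ew(i, j);
  }
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return pot[a] > pot[b]; });
  std::vector<int> rank(n);
  for (int i = 0; i < n; ++i) rank[ord[i]] = i;

  CliqueSearch cs;
  cs.n = n;
  cs.nwords = (n + 63) / 64;
  cs.node_budget = (long long)node_budget;
  cs.w.resize(n);
  cs.orig.resize(n);
  cs.adj.assign(n, std::vector<uint64_t>(cs.nwords, 0));
  cs.ew.assign(n, std::vector<double>(n, 0.0));
  cs.uu.resize(n); cs.vv.resize(n); cs.half_pos.assign(n, 0.0);
  for (int i = 0; i < n; ++i) {
    cs.w[rank[i]] = vw[i];
    cs.orig[rank[i]] = i;
    cs.uu[rank[i]] = ulab[i];
    cs.vv[rank[i]] = vlab[i];
    if (ulab[i] > cs.max_u) cs.max_u = ulab[i];
    if (vlab[i] > cs.max_v) cs.max_v = vlab[i];
  }
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      if (i != j && adj(i, j)) {
        int a = rank[i], b = rank[j];
        cs.adj[a][b / 64] |= (1ULL << (b % 64));
        cs.ew[a][b] = ew(i, j);
        if (ew(i, j) > 0) cs.half_pos[a] += 0.5 * ew(i, j);
      }
    }
  cs.best_score = 0.0; // empty clique is always admissible

  // deterministic greedy pass: repeatedly add the best marginal-gain
  // candidate; used as the answer in greedy mode and as the initial
  // incumbent (for early pruning) in exact mode
  {
    std::vector<uint64_t> cand(cs.nwords, 0);
    for (int i = 0; i < n; ++i) cand[i / 64] |= (1ULL << (i % 64));
    std::vector<int> cur;
    double score = 0.0;
    while (true) {
      int bestv = -1; double bestg = 0.0;
      for (int v = 0; v < n; ++v) {
        if (!(cand[v / 64] & (1ULL << (v % 64)))) continue;
        double g = cs.w[v];
        for (int c : cur) g += cs.ew[v][c];
        if (bestv < 0 || g > bestg + 1e-12) { bestv = v; bestg = g; }
      }
      if (bestv < 0 || bestg <= 1e-12) break;
      cur.push_back(bestv);
      score += bestg;
      for (int wdi = 0; wdi < cs.nwords; ++wdi) cand[wdi] &= cs.adj[bestv][wdi];
    }
    cs.consider(score, cur);
  }
  if (!greedy) {
    std::vector<uint64_t> cand(cs.nwords, 0);
    for (int i = 0; i < n; ++i) cand[i / 64] |= (1ULL << (i % 64));
    std::vector<int> cur;
    cs.expand(cur, 0.0, cand);
  }

  IntegerVector out(cs.best_set.size());
  for (size_t i = 0; i < cs.best_set.size(); ++i) out[i] = cs.best_set[i] + 1;
  return List::create(_["vertices"] = out, _["score"] = cs.best_score);
}

// Monotone (sequence-order-preserving) alignment of two position sets by
// dynamic programming over an affinity matrix, with a linear gap penalty
// and free end gaps (global in the sense that every position competes for
// matching; unmatched positions cost nothing at the ends).
// Deterministic traceback preference: diagonal, then up, then left.

// [[Rcpp::export(name = ".cpp_dp_align")]]
List cpp_dp_align(NumericMatrix S, double gap) {
  int n = S.nrow(), m = S.ncol();
  NumericMatrix H(n + 1, m + 1);
  IntegerMatrix T(n + 1, m + 1); // 0 stop, 1 diag, 2 up, 3 left
  for (int i = 1; i <= n; ++i) { H(i, 0) = 0.0; T(i, 0) = 2; }
  for (int j = 1; j <= m; ++j) { H(0, j) = 0.0; T(0, j) = 3; }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diag = H(i - 1, j - 1) + S(i - 1, j - 1);
      double up = H(i - 1, j) + ((j == m) ? 0.0 : gap);
      double left = H(i, j - 1) + ((i == n) ? 0.0 : gap);
      double best = diag; int t = 1;
      if (up > best + 1e-12) { best = up; t = 2; }
      if (left > best + 1e-12) { best = left; t = 3; }
      H(i, j) = best; T(i, j) = t;
    }
  }
  // traceback from (n, m)
  std::vector<int> mi, mj;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int t = T(i, j);
    if (t == 1) { mi.push_back(i); mj.push_back(j); --i; --j; }
    else if (t == 2) { --i; }
    else { --j; }
  }
  std::reverse(mi.begin(), mi.end());
  std::reverse(mj.begin(), mj.end());
  IntegerMatrix M(mi.size(), 2);
  for (size_t k = 0; k < mi.size(); ++k) { M(k, 0) = mi[k]; M(k, 1) = mj[k]; }
  return List::create(_["matches"] = M, _["score"] = H(n, m));
}
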