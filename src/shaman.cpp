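// MCMC contact shuffling preserving per-end degrees and the contact
// distance distribution, plus k-nearest-neighbour scoring utilities.

#include <Rcpp.h>
#include <queue>
#include <cmath>
#include <map>
#include <random>
#include <algorithm>
using namespace Rcpp;

// log2-spaced distance bin from 1 kb; bin 0 is reserved for trans
static inline int dist_bin(double d) {
  if (d < 1000.0) d = 1000.0;
  return 1 + (int)std::floor(std::log2(d / 1000.0));
}

// Partner-swap MCMC on a contact pool. Ends keep their genomic identity so
// per-end degrees are preserved exactly; a proposal swaps the second ends
// of two contacts drawn from the same category (same chromosome for cis,
// the trans pool for trans) and is accepted by Metropolis on the change of
// sum_b |h_b - H_b| between the current and the target (input) distance
// histogram. Trans proposals that would create a cis contact are rejected.
// [[Rcpp::export]]
List shuffle_cpp(IntegerVector chr1, NumericVector pos1,
                 IntegerVector chr2, NumericVector pos2,
                 int sweeps, double beta, int seed) {
  int n = chr1.size();
  std::vector<int> c1(chr1.begin(), chr1.end());
  std::vector<int> c2(chr2.begin(), chr2.end());
  std::vector<double> p1(pos1.begin(), pos1.end());
  std::vector<double> p2(pos2.begin(), pos2.end());

  // categories: cis -> chromosome id, trans -> -1
  std::vector<int> cat(n);
  int nbin = 2;
  for (int i = 0; i < n; i++) {
    cat[i] = (c1[i] == c2[i]) ? c1[i] : -1;
    if (cat[i] >= 0) nbin = std::max(nbin, dist_bin(std::fabs(p2[i] - p1[i])) + 1);
  }
  nbin += 8;  // headroom for swaps creating longer distances
  std::vector<double> H(nbin + 1, 0.0), h(nbin + 1, 0.0);
  auto bin_of = [&](int i) {
    return cat[i] < 0 ? 0 : dist_bin(std::fabs(p2[i] - p1[i]));
  };
  for (int i = 0; i < n; i++) { H[bin_of(i)] += 1; h[bin_of(i)] += 1; }

  std::map<int, std::vector<int> > by_cat;
  for (int i = 0; i < n; i++) by_cat[cat[i]].push_back(i);

  std::mt19937 rng(seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::uniform_int_distribution<int> pick(0, n - 1);

  double score = 0.0;  // current sum |h - H| (starts at 0)
  long long n_prop = 0, n_acc = 0;
  long long total = (long long)sweeps * n;
  for (long long t = 0; t < total; t++) {
    int i = pick(rng);
    std::vector<int>& pool = by_cat[cat[i]];
    if (pool.size() < 2) continue;
    int j = pool[(int)(unif(rng) * pool.size())];
    if (j == i) continue;
    n_prop++;
    // proposed: (p1[i], p2[j]) and (p1[j], p2[i])
    if (cat[i] < 0) {
      // trans: stay trans after the swap
      if (c1[i] == c2[j] || c1[j] == c2[i]) continue;
      n_acc++;
      std::swap(p2[i], p2[j]);
      std::swap(c2[i], c2[j]);
      continue;
    }
    int bi = dist_bin(std::fabs(p2[i] - p1[i]));
    int bj = dist_bin(std::fabs(p2[j] - p1[j]));
    int bi2 = dist_bin(std::fabs(p2[j] - p1[i]));
    int bj2 = dist_bin(std::fabs(p2[i] - p1[j]));
    if (bi2 > nbin || bj2 > nbin) continue;
    // delta of sum |h - H| from moving one count bi->bi2 and bj->bj2
    double delta = 0.0;
    std::map<int, double> dh;
    dh[bi] -= 1; dh[bj] -= 1; dh[bi2] += 1; dh[bj2] += 1;
    for (std::map<int, double>::iterator it = dh.begin(); it != dh.end(); ++it) {
      double hb = h[it->first], Hb = H[it->first];
      delta += std::fabs(hb + it->second - Hb) - std::fabs(hb - Hb);
    }
    if (delta <= 0 || unif(rng) < std::exp(-beta * delta)) {
      n_acc++;
      h[bi] -= 1; h[bj] -= 1; h[bi2] += 1; h[bj2] += 1;
      score += delta;
      std::swap(p2[i], p2[j]);
    }
  }
  double tv = 0.0;
  for (int b = 0; b <= nbin; b++) tv += std::fabs(h[b] - H[b]);
  tv /= (2.0 * n);
  return List::create(_["pos1"] = NumericVector(p1.begin(), p1.end()),
                      _["pos2"] = NumericVector(p2.begin(), p2.end()),
                      _["chr1"] = IntegerVector(c1.begin(), c1.end()),
                      _["chr2"] = IntegerVector(c2.begin(), c2.end()),
                      _["tv"] = tv, _["n_proposals"] = (double)n_prop,
                      _["n_accepted"] = (double)n_acc);
}

struct KnnFinder {
  // points sorted by x; exact kNN by expanding a window over x
  std::vector<double> x, y;
  std::vector<int> ord;
  KnnFinder(const NumericVector& px, const NumericVector& py) {
    int n = px.size();
    x.resize(n); y.resize(n); ord.resize(n);
    for (int i = 0; i < n; i++) ord[i] = i;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      return px[a] < px[b];
    });
    for (int i = 0; i < n; i++) { x[i] = px[ord[i]]; y[i] = py[ord[i]]; }
  }
  // k nearest squared-distance list (ascending) and optionally indices
  void query(double qx, double qy, int k, std::vector<double>& out,
             int skip_orig = -1, std::vector<int>* idx_out = 0) const {
    int n = x.size();
    k = std::min(k, n - (skip_orig >= 0 ? 1 : 0));
    std::priority_queue<std::pair<double, int> > heap;  // max-heap on d2
    int lo = (int)(std::lower_bound(x.begin(), x.end(), qx) - x.begin());
    int hi = lo;
    lo--;
    while (true) {
      bool can_lo = lo >= 0, can_hi = hi < n;
      if (!can_lo && !can_hi) break;
      double worst = heap.size() == (size_t)k ? heap.top().first : R_PosInf;
      double dlo = can_lo ? (qx - x[lo]) * (qx - x[lo]) : R_PosInf;
      double dhi = can_hi ? (x[hi] - qx) * (x[hi] - qx) : R_PosInf;
      if (heap.size() == (size_t)k && dlo > worst && dhi > worst) break;
      int i = dlo <= dhi ? lo-- : hi++;
      if (ord[i] == skip_orig) continue;
      double d2 = (qx - x[i]) * (qx - x[i]) + (qy - y[i]) * (qy - y[i]);
      if (heap.size() < (size_t)k) heap.push(std::make_pair(d2, ord[i]));
      else if (d2 < heap.top().first) { heap.pop(); heap.push(std::make_pair(d2, ord[i])); }
    }
    out.clear();
    if (idx_out) idx_out->clear();
    while (!heap.empty()) {
      out.push_back(heap.top().first);
      if (idx_out) idx_out->push_back(heap.top().second);
      heap.pop();
    }
    std::reverse(out.begin(), out.end());
    if (idx_out) std::reverse(idx_out->begin(), idx_out->end());
  }
};

// two-sample KS D statistic between sorted samples
static double ks_d(const std::vector<double>& a, const std::vector<double>& b) {
  size_t i = 0, j = 0;
  double d = 0.0;
  while (i < a.size() && j < b.size()) {
    if (a[i] <= b[j]) i++; else j++;
    double fa = (double)i / a.size(), fb = (double)j / b.size();
    if (std::fabs(fa - fb) > d) d = std::fabs(fa - fb);
  }
  return d;
}

// KNN/KS enrichment scores: for every query contact, the signed KS D
// between its k-nearest-neighbour distance samples in the observed and in
// the shuffled pool, scaled to [-100, 100]; positive when observed
// neighbours are nearer (enrichment). self_in_obs marks queries that are
// themselves members of the observed pool (the point itself is excluded).
// [[Rcpp::export]]
NumericVector knn_score_cpp(NumericVector qx, NumericVector qy,
                            NumericVector ox, NumericVector oy,
                            NumericVector sx, NumericVector sy,
                            int k, bool self_in_obs,
                            IntegerVector self_index) {
  KnnFinder obs(ox, oy), shuf(sx, sy);
  int nq = qx.size();
  NumericVector score(nq);
  std::vector<double> da, db;
  for (int i = 0; i < nq; i++) {
    int skip = self_in_obs ? self_index[i] : -1;
    obs.query(qx[i], qy[i], k, da, skip);
    shuf.query(qx[i], qy[i], k, db, -1);
    if (da.empty() || db.empty()) { score[i] = 0; continue; }
    double d = ks_d(da, db);
    double ma = 0, mb = 0;
    for (size_t t = 0; t < da.size(); t++) ma += std::sqrt(da[t]);
    for (size_t t = 0; t < db.size(); t++) mb += std::sqrt(db[t]);
    ma /= da.size(); mb /= db.size();
    double s = 100.0 * d * (ma < mb ? 1.0 : (ma > mb ? -1.0 : 0.0));
    score[i] = std::max(-100.0, std::min(100.0, s));
  }
  return score;
}

// index (1-based) of the nearest point in (px, py) for every query
// [[Rcpp::export]]
IntegerVector nn1_cpp(NumericVector qx, NumericVector qy,
                      NumericVector px, NumericVector py) {
  KnnFinder f(px, py);
  int nq = qx.size();
  IntegerVector out(nq);
  std::vector<double> d; std::vector<int> idx;
  for (int i = 0; i < nq; i++) {
    f.query(qx[i], qy[i], 1, d, -1, &idx);
    out[i] = idx.empty() ? NA_INTEGER : idx[0] + 1;
  }
  return out;
}
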