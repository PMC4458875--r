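// Hot kernels for summit clustering and the bootstrap null loop.
//
// A "point" is (chrom, summit, set). Chrom and summit are packed into one
// 64-bit key (chrom << 32 | summit), so a sort plus a gap scan yields the
// single-linkage clusters: a gap > window between consecutive keys (which
// includes any chromosome change) closes a cluster.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Pt {
  int64_t key;
  int set;
};

inline int64_t pack(int chrom, int summit) {
  return (static_cast<int64_t>(chrom) << 32) | static_cast<uint32_t>(summit);
}

// number of single-linkage clusters whose member-set mask is full
int count_full_clusters(std::vector<Pt>& pts, int n_sets, int window) {
  if (pts.empty()) return 0;
  std::sort(pts.begin(), pts.end(),
            [](const Pt& a, const Pt& b) { return a.key < b.key; });
  const unsigned full = (1u << n_sets) - 1u;
  int count = 0;
  unsigned mask = 0;
  for (size_t i = 0; i < pts.size(); ++i) {
    if (i > 0 && pts[i].key - pts[i - 1].key > window) {
      if (mask == full) ++count;
      mask = 0;
    }
    mask |= (1u << pts[i].set);
  }
  if (mask == full) ++count;
  return count;
}

} // namespace

// [[Rcpp::export]]
int cluster_full_count(IntegerVector chrom, IntegerVector summit,
                       IntegerVector set_id, int n_sets, int window) {
  const int n = chrom.size();
  if (summit.size() != n || set_id.size() != n)
    stop("chrom, summit and set_id must have equal length");
  if (n_sets < 1 || n_sets > 31) stop("n_sets must be in 1..31");
  std::vector<Pt> pts(n);
  for (int i = 0; i < n; ++i) {
    if (set_id[i] < 0 || set_id[i] >= n_sets) stop("set_id out of range");
    pts[i] = {pack(chrom[i], summit[i]), set_id[i]};
  }
  return count_full_clusters(pts, n_sets, window);
}

// Bootstrap null statistics for the multi-set overlap test. Iteration i
// keeps actual set (i mod n_sets) and replaces every other set by a draw of
// matching size from the pool of union-peak summits; the statistic is the
// number of clusters containing all sets. Uses R's RNG (seed with
// set.seed() in R for reproducibility).
// [[Rcpp::export]]
List boot_overlap_null(IntegerVector pool_chrom, IntegerVector pool_summit,
                       List set_chrom, List set_summit,
                       int window, int n_iter, bool replace) {
  const int n_sets = set_chrom.size();
  if (n_sets < 2 || n_sets > 31) stop("need 2..31 sets");
  const int n_pool = pool_chrom.size();
  std::vector<std::vector<Pt>> sets(n_sets);
  size_t total = 0;
  for (int s = 0; s < n_sets; ++s) {
    IntegerVector ch = set_chrom[s], su = set_summit[s];
    if (ch.size() != su.size()) stop("set chrom/summit length mismatch");
    sets[s].resize(ch.size());
    for (int i = 0; i < ch.size(); ++i) sets[s][i] = {pack(ch[i], su[i]), s};
    total += ch.size();
    if (!replace && ch.size() > n_pool)
      stop("set larger than pool in without-replacement mode");
  }
  IntegerVector stats(n_iter), rotation(n_iter);
  std::vector<Pt> pts;
  pts.reserve(total);
  for (int it = 0; it < n_iter; ++it) {
    const int keep = it % n_sets;
    pts.clear();
    pts.insert(pts.end(), sets[keep].begin(), sets[keep].end());
    for (int s = 0; s < n_sets; ++s) {
      if (s == keep) continue;
      IntegerVector idx =
          Rcpp::sample(n_pool, static_cast<int>(sets[s].size()), replace);
      for (int j = 0; j < idx.size(); ++j) {
        const int k = idx[j] - 1;
        pts.push_back({pack(pool_chrom[k], pool_summit[k]), s});
      }
    }
    stats[it] = count_full_clusters(pts, n_sets, window);
    rotation[it] = keep;
  }
  return List::create(_["stats"] = stats, _["rotation"] = rotation);
}

// PWM scan over an integer-encoded sequence (A=1,C=2,G=3,T=4; 0 = ambiguous,
// never matches). Returns 1-based start positions and scores of windows
// scoring >= thr.
// [[Rcpp::export]]
List pwm_scan_hits(IntegerVector enc, NumericMatrix lom, double thr) {
  const int n = enc.size(), L = lom.ncol();
  if (lom.nrow() != 4) stop("log-odds matrix must have 4 rows");
  std::vector<int> pos;
  std::vector<double> score;
  for (int i = 0; i + L <= n; ++i) {
    double s = 0;
    bool ok = true;
    for (int j = 0; j < L; ++j) {
      const int b = enc[i + j];
      if (b < 1 || b > 4) { ok = false; break; }
      s += lom(b - 1, j);
    }
    if (ok && s >= thr) { pos.push_back(i + 1); score.push_back(s); }
  }
  return List::create(_["pos"] = wrap(pos), _["score"] = wrap(score));
}
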