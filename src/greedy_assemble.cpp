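#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Greedy overlap assembler: repeatedly merge the pair of contigs with the
// longest exact suffix-prefix overlap >= min_overlap. Contained contigs are
// absorbed. Ties broken lexicographically on (left string, right string),
// which makes the result deterministic and independent of input order.

// Longest k with suffix(a, k) == prefix(b, k), k <= min(la, lb) - 1.
static int best_overlap(const std::string &a, const std::string &b,
                        int min_overlap) {
  int kmax = (int)std::min(a.size(), b.size()) - 1;
  for (int k = kmax; k >= min_overlap; --k) {
    if (a.compare(a.size() - k, k, b, 0, k) == 0) return k;
  }
  return 0;
}

// [[Rcpp::export(name = ".greedy_assemble_cpp")]]
CharacterVector greedy_assemble_cpp(CharacterVector reads, int min_overlap) {
  std::vector<std::string> contigs;
  contigs.reserve(reads.size());
  for (R_xlen_t i = 0; i < reads.size(); ++i)
    contigs.push_back(as<std::string>(reads[i]));

  // sort for determinism, then absorb contained/duplicate reads
  std::sort(contigs.begin(), contigs.end());
  std::vector<bool> alive(contigs.size(), true);
  for (size_t i = 0; i < contigs.size(); ++i) {
    if (!alive[i]) continue;
    for (size_t j = 0; j < contigs.size(); ++j) {
      if (i == j || !alive[j] || !alive[i]) continue;
      if (contigs[j].size() > contigs[i].size() ||
          (contigs[j].size() == contigs[i].size() && j < i)) {
        if (contigs[j].find(contigs[i]) != std::string::npos)
          alive[i] = false;
      }
    }
  }
  std::vector<std::string> pool;
  for (size_t i = 0; i < contigs.size(); ++i)
    if (alive[i]) pool.push_back(contigs[i]);

  size_t n = pool.size();
  std::vector<bool> act(n, true);
  // ov[i][j]: best suffix(i)-prefix(j) overlap
  std::vector<std::vector<int> > ov(n, std::vector<int>(n, 0));
  for (size_t i = 0; i < n; ++i)
    for (size_t j = 0; j < n; ++j)
      if (i != j) ov[i][j] = best_overlap(pool[i], pool[j], min_overlap);

  while (true) {
    int best = 0;
    long bi = -1, bj = -1;
    for (size_t i = 0; i < n; ++i) {
      if (!act[i]) continue;
      for (size_t j = 0; j < n; ++j) {
        if (i == j || !act[j]) continue;
        int k = ov[i][j];
        if (k < min_overlap) continue;
        if (k > best ||
            (k == best && bi >= 0 &&
             (pool[i] < pool[bi] ||
              (pool[i] == pool[bi] && pool[j] < pool[bj])))) {
          best = k; bi = (long)i; bj = (long)j;
        }
      }
    }
    if (bi < 0) break;
    size_t la = pool[bi].size();
    std::string merged = pool[bi] + pool[bj].substr(best);
    act[bj] = false;
    pool[bi] = merged;
    // Absorb contigs newly contained in the merged one. Active contigs were
    // not contained in either part, so any new containment must span the
    // junction at position la; searching a window there is enough.
    for (size_t j = 0; j < n; ++j) {
      if (!act[j] || j == (size_t)bi) continue;
      size_t lj = pool[j].size();
      if (lj > merged.size()) continue;
      size_t wstart = la > lj ? la - lj : 0;
      size_t wlen = std::min(merged.size() - wstart, 2 * lj);
      if (merged.compare(wstart, wlen, pool[j]) == 0 ||
          merged.substr(wstart, wlen).find(pool[j]) != std::string::npos)
        act[j] = false;
    }
    // recompute overlaps involving the merged contig
    for (size_t j = 0; j < n; ++j) {
      if (!act[j] || j == (size_t)bi) continue;
      ov[bi][j] = best_overlap(pool[bi], pool[j], min_overlap);
      ov[j][bi] = best_overlap(pool[j], pool[bi], min_overlap);
    }
  }

  std::vector<std::string> out;
  for (size_t i = 0; i < n; ++i)
    if (act[i]) out.push_back(pool[i]);
  std::sort(out.begin(), out.end());
  return wrap(out);
}
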