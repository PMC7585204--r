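#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Direct-repeat search on a circular genome.
//
// A direct repeat is an unordered pair of same-strand copies
// [i, i+len) and [i+d, i+d+len) (positions mod L) with len >= min_len,
// Hamming mismatches m satisfying 4*m <= len (at most one mismatch per
// four nucleotides), copies non-overlapping on the circle
// (len <= min(d, L-d)), and inclusion-maximal among valid intervals at the
// same copy offset d. Two independent routines below implement this
// definition; the scan-based one is the production path, the anchor-pair
// one the brute-force cross-check.

struct RepeatHit {
  int posA, posB, len, mism;
};

static inline bool base_match(char a, char b) {
  return a == b && a != 'N';
}

static void normalize_pair(int i, int d, int len, int mism, int L,
                           std::vector<RepeatHit>& out) {
  int a = ((i % L) + L) % L;
  int b = (a + d) % L;
  if (b < a) std::swap(a, b);
  out.push_back({a, b, len, mism});
}

static DataFrame hits_to_df(std::vector<RepeatHit>& hits) {
  std::sort(hits.begin(), hits.end(), [](const RepeatHit& x, const RepeatHit& y) {
    if (x.posA != y.posA) return x.posA < y.posA;
    if (x.posB != y.posB) return x.posB < y.posB;
    return x.len < y.len;
  });
  hits.erase(std::unique(hits.begin(), hits.end(),
                         [](const RepeatHit& x, const RepeatHit& y) {
                           return x.posA == y.posA && x.posB == y.posB &&
                                  x.len == y.len && x.mism == y.mism;
                         }),
             hits.end());
  int n = hits.size();
  IntegerVector posA(n), posB(n), len(n), mism(n);
  for (int k = 0; k < n; ++k) {
    posA[k] = hits[k].posA; posB[k] = hits[k].posB;
    len[k] = hits[k].len;  mism[k] = hits[k].mism;
  }
  return DataFrame::create(_["posA"] = posA, _["posB"] = posB,
                           _["length"] = len, _["mismatches"] = mism);
}

// Production finder: per copy offset d, prefix sums of t_k = 1 - 4*m_k turn
// the validity condition into P(j) >= P(i-1); the rightmost valid end for
// each start is found with a sliding max-deque plus binary search, and
// inclusion-maximality reduces to a single ascending sweep over right ends.
// [[Rcpp::export(name = ".find_repeats_scan")]]
DataFrame find_repeats_scan(std::string seq, int min_len = 8, int denom = 4) {
  int L = seq.size();
  if (L < 2 * min_len) stop("genome shorter than twice the minimum repeat length");
  std::vector<RepeatHit> hits;
  int ext = 2 * L + L / 2 + 2;           // scan starts in [0, 2L), ends < ext
  std::vector<int> P(ext + 1);
  std::vector<int> deque_idx(ext + 2);

  for (int d = 1; d <= L / 2; ++d) {
    int cap = std::min(d, L - d);
    if (cap < min_len) continue;
    // prefix sums of +1 (match) / -(denom-1) (mismatch)
    P[0] = 0;
    for (int k = 0; k < ext; ++k) {
      bool mm = !base_match(seq[k % L], seq[(k + d) % L]);
      P[k + 1] = P[k] + (mm ? -(denom - 1) : 1);
    }
    // survived[i] = 1 if [i, jmax(i)] is maximal in the ascending sweep
    std::vector<int> jmax(2 * L, -1);
    std::vector<char> alive(2 * L, 0);
    int head = 0, tail = 0;             // deque over indices j (P[j+1] values)
    int inserted_to = -1;
    int best_end = -1;
    for (int i = 0; i < 2 * L; ++i) {
      int lo = i + min_len - 1;         // smallest admissible end
      int hi = i + cap - 1;             // largest admissible end
      // push window ends up to hi
      while (inserted_to < hi) {
        ++inserted_to;
        int j = inserted_to;
        if (j >= ext) break;
        int pj = P[j + 1];
        while (tail > head && P[deque_idx[tail - 1] + 1] <= pj) --tail;
        deque_idx[tail++] = j;
      }
      // expire ends below lo
      while (head < tail && deque_idx[head] < lo) ++head;
      if (head == tail) continue;
      int thr = P[i];
      // deque has decreasing P front->back; rightmost j with P(j) >= thr
      if (P[deque_idx[head] + 1] < thr) continue;
      int a = head, b = tail - 1, ans = head;
      while (a <= b) {
        int mid = (a + b) / 2;
        if (P[deque_idx[mid] + 1] >= thr) { ans = mid; a = mid + 1; }
        else b = mid - 1;
      }
      int j = deque_idx[ans];
      if (j > hi) continue;             // safety; deque never exceeds hi
      jmax[i] = j;
      if (j > best_end) { alive[i] = 1; best_end = j; }
    }
    for (int i = 0; i < L; ++i) {
      if (!alive[i]) continue;
      if (i + L < 2 * L) {
        if (!alive[i + L] || jmax[i + L] != jmax[i] + L) continue;
      }
      if (2 * d == L && i >= L / 2) continue;   // antipodal offset: one rep
      int len = jmax[i] - i + 1;
      int mism = (len - (P[jmax[i] + 1] - P[i])) / denom;
      normalize_pair(i, d, len, mism, L, hits);
    }
  }
  return hits_to_df(hits);
}

// Brute-force oracle: every (start, offset) anchor is scanned by direct
// character comparison, every valid interval end is recorded, and
// inclusion-maximality is decided by explicit pairwise containment checks
// (with the circle handled by +/- L shifts).
// [[Rcpp::export(name = ".find_repeats_bruteforce")]]
DataFrame find_repeats_bruteforce(std::string seq, int min_len = 8, int denom = 4) {
  int L = seq.size();
  if (L < 2 * min_len) stop("genome shorter than twice the minimum repeat length");
  std::vector<RepeatHit> hits;
  for (int d = 1; d <= L / 2; ++d) {
    int cap = std::min(d, L - d);
    if (cap < min_len) continue;
    // candidate = longest valid interval per start (any valid interval is
    // contained in the longest valid one sharing its start)
    std::vector<int> cstart, cend, cmism;
    for (int i = 0; i < 2 * L; ++i) {
      int mism = 0, best_len = -1, best_mism = 0;
      for (int len = 1; len <= cap; ++len) {
        int k = i + len - 1;
        if (!base_match(seq[k % L], seq[(k + d) % L])) ++mism;
        if (denom * mism > cap) break;  // no longer extensible to validity
        if (len >= min_len && denom * mism <= len) {
          best_len = len; best_mism = mism;
        }
      }
      if (best_len > 0) {
        cstart.push_back(i); cend.push_back(i + best_len - 1);
        cmism.push_back(best_mism);
      }
    }
    int n = cstart.size();
    for (int u = 0; u < n; ++u) {
      if (cstart[u] >= L) continue;     // canonical representative
      bool contained = false;
      for (int v = 0; v < n && !contained; ++v) {
        if (v == u) continue;
        for (int shift = -L; shift <= L && !contained; shift += L) {
          int s2 = cstart[v] + shift, e2 = cend[v] + shift;
          if (s2 <= cstart[u] && cend[u] <= e2 &&
              !(s2 == cstart[u] && e2 == cend[u])) {
            contained = true;
          }
        }
      }
      if (contained) continue;
      // identical interval duplicated at +L: keep the [0, L) representative
      if (2 * d == L && cstart[u] >= L / 2) continue;
      normalize_pair(cstart[u], d, cend[u] - cstart[u] + 1, cmism[u], L, hits);
    }
  }
  return hits_to_df(hits);
}
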