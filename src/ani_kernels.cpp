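// MinHash sketching and fragment-based ANI kernels.
//
// Sketches are the s smallest distinct 64-bit hashes of canonical k-mers
// (numeric minimum of the 2-bit packed forward k-mer and its reverse
// complement, which matches lexicographic order under A<C<G<T). Hashes are
// finalised with splitmix64 seeded by a fixed sketch seed and truncated to
// 53 bits so they round-trip exactly through R doubles.
//
// fragment_ani cuts the query into consecutive non-overlapping fragments,
// anchors each fragment on the reference by voting over shared k-anchor-mer
// diagonals, and scores the anchored window. Substitution-only alignments
// are resolved by exact Hamming identity on the winning diagonal; fragments
// scoring below a shortcut threshold there fall through to a banded,
// match-maximising DP (linear gap penalty) that tolerates indels. ANI is
// the mean identity of mapped fragments, AF the mapped fraction. Reference
// anchor tables can be prebuilt once and reused across queries.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>
#include <queue>
#include <unordered_set>
#include <unordered_map>

using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

static inline int base2bit(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// Enumerate packed k-mers; windows containing non-ACGT are skipped.
template <typename F>
static void for_each_kmer(const std::string& s, int k, F cb) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  uint64_t fwd = 0, rc = 0;
  int run = 0;
  const int shift = 2 * (k - 1);
  for (size_t i = 0; i < s.size(); ++i) {
    int b = base2bit(s[i]);
    if (b < 0) { run = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - b) << shift);
    if (++run >= k) cb(fwd, rc, (long)(i + 1 - k));
  }
}

// [[Rcpp::export]]
NumericVector cpp_minhash_sketch(std::string seq, int k, int s, double seed) {
  if ((int)seq.size() < k) stop("sequence shorter than k");
  const uint64_t hseed = (uint64_t)seed;
  std::priority_queue<uint64_t> heap;  // max-heap of the s smallest
  std::unordered_set<uint64_t> seen;
  for_each_kmer(seq, k, [&](uint64_t fwd, uint64_t rc, long) {
    uint64_t canon = std::min(fwd, rc);
    uint64_t h = splitmix64(canon ^ hseed) >> 11;  // 53 bits
    if ((int)heap.size() < s) {
      if (seen.insert(h).second) heap.push(h);
    } else if (h < heap.top() && seen.find(h) == seen.end()) {
      seen.erase(heap.top());
      heap.pop();
      seen.insert(h);
      heap.push(h);
    }
  });
  std::vector<double> out;
  out.reserve(heap.size());
  while (!heap.empty()) { out.push_back((double)heap.top()); heap.pop(); }
  std::sort(out.begin(), out.end());
  return wrap(out);
}

// Mash-style Jaccard estimate: among the bottom s distinct hashes of the
// union of two sketches, the fraction present in both.
// [[Rcpp::export]]
double cpp_sketch_jaccard(NumericVector a, NumericVector b, int s) {
  size_t i = 0, j = 0;
  int taken = 0, shared = 0;
  while (taken < s && (i < (size_t)a.size() || j < (size_t)b.size())) {
    if (j >= (size_t)b.size() || (i < (size_t)a.size() && a[i] < b[j])) {
      ++i; ++taken;
    } else if (i >= (size_t)a.size() || b[j] < a[i]) {
      ++j; ++taken;
    } else {
      ++i; ++j; ++taken; ++shared;
    }
  }
  if (taken == 0) return 0.0;
  return (double)shared / (double)taken;
}

// ---- anchor index ---------------------------------------------------------

struct AnchorIndex {
  std::string seq;
  int k;
  // k-mer code -> [begin, end) range into pos
  std::unordered_map<uint64_t, std::pair<int, int> > ranges;
  std::vector<int> pos;
};

static AnchorIndex* build_index(const std::string& seq, int k) {
  AnchorIndex* idx = new AnchorIndex();
  idx->seq = seq;
  idx->k = k;
  std::vector<std::pair<uint64_t, int> > v;
  v.reserve(seq.size());
  for_each_kmer(seq, k, [&](uint64_t fwd, uint64_t, long p) {
    v.push_back(std::make_pair(fwd, (int)p));
  });
  std::sort(v.begin(), v.end());
  idx->pos.reserve(v.size());
  idx->ranges.reserve(v.size());
  size_t i = 0;
  while (i < v.size()) {
    size_t j = i;
    while (j < v.size() && v[j].first == v[i].first) ++j;
    idx->ranges[v[i].first] =
        std::make_pair((int)idx->pos.size(), (int)(idx->pos.size() + (j - i)));
    for (size_t t = i; t < j; ++t) idx->pos.push_back(v[t].second);
    i = j;
  }
  return idx;
}

// [[Rcpp::export]]
SEXP cpp_anchor_index(std::string seq, int k) {
  XPtr<AnchorIndex> p(build_index(seq, k), true);
  return p;
}

// ---- fragment scoring -----------------------------------------------------

static const int NEGI = -1000000000;

// Banded semi-global DP maximising matches with linear gap penalty: the
// query fragment aligns end-to-end, reference-window overhangs are free.
// The window starts ~band before the anchored origin, so the band covers
// reference offsets j - i in [0, 2b]. Returns best matches.
static int banded_matches(const char* q, int qlen, const char* w, int wlen,
                          int band) {
  const int width = 2 * band + 1;
  std::vector<int> prev(width, 0), cur(width, NEGI);
  for (int i = 1; i <= qlen; ++i) {
    for (int d = 0; d < width; ++d) {
      int j = i + d;
      if (j < 1 || j > wlen) { cur[d] = NEGI; continue; }
      char qc = q[i - 1];
      int m = (qc == w[j - 1] && base2bit(qc) >= 0) ? 1 : 0;
      int v = prev[d] + m;
      if (d + 1 < width && prev[d + 1] - 1 > v) v = prev[d + 1] - 1;
      if (d - 1 >= 0 && cur[d - 1] - 1 > v) v = cur[d - 1] - 1;
      cur[d] = v;
    }
    std::swap(prev, cur);
  }
  int best = 0;
  for (int d = 0; d < width; ++d)
    if (prev[d] > best) best = prev[d];
  return best;
}

// exact match count of fragment vs reference at a fixed diagonal
static int diagonal_matches(const char* q, int qlen, const std::string& ref,
                            long diag) {
  int m = 0;
  for (int i = 0; i < qlen; ++i) {
    long j = diag + i;
    if (j < 0 || j >= (long)ref.size()) continue;
    if (q[i] == ref[j] && base2bit(q[i]) >= 0) ++m;
  }
  return m;
}

// identity of one fragment against the indexed reference; < 0 = unmapped
static double score_fragment(const char* frag, int flen,
                             const AnchorIndex& idx, int band,
                             int min_anchors, double hamming_accept) {
  // anchors are sampled every ANCHOR_STRIDE bp (minimizer-style thinning);
  // votes only locate the diagonal, identities come from the full sequence
  const long ANCHOR_STRIDE = 3;
  std::unordered_map<long, int> votes;
  std::string fs(frag, flen);
  for_each_kmer(fs, idx.k, [&](uint64_t fwd, uint64_t, long i) {
    if (i % ANCHOR_STRIDE != 0) return;
    std::unordered_map<uint64_t, std::pair<int, int> >::const_iterator it =
        idx.ranges.find(fwd);
    if (it == idx.ranges.end()) return;
    int b = it->second.first, e = it->second.second;
    if (e - b > 16) e = b + 16;  // cap repeats
    for (int t = b; t < e; ++t)
      votes[(long)idx.pos[t] - i] += 1;
  });
  if (votes.empty()) return -1.0;
  // modal exact diagonal
  long best_diag = 0;
  int best_v = 0, total_near = 0;
  for (std::unordered_map<long, int>::iterator it = votes.begin();
       it != votes.end(); ++it)
    if (it->second > best_v) { best_v = it->second; best_diag = it->first; }
  for (std::unordered_map<long, int>::iterator it = votes.begin();
       it != votes.end(); ++it)
    if (std::labs(it->first - best_diag) <= band) total_near += it->second;
  if (total_near < min_anchors) return -1.0;
  int dm = diagonal_matches(frag, flen, idx.seq, best_diag);
  double hid = (double)dm / flen;
  if (hid >= hamming_accept) return hid;
  // fall through to the banded DP around the modal diagonal
  long ws = best_diag - band;
  if (ws < 0) ws = 0;
  long wlen = (long)flen + 2L * band;
  if (ws + wlen > (long)idx.seq.size()) wlen = (long)idx.seq.size() - ws;
  if (wlen < flen) return hid;  // window truncated at the reference edge
  int bm = banded_matches(frag, flen, idx.seq.c_str() + ws, (int)wlen, band);
  double did = (double)bm / flen;
  if (did > 1.0) did = 1.0;
  return did > hid ? did : hid;
}

static List fragment_ani_core(const CharacterVector& query_seqs,
                              const AnchorIndex& idx, int fragment_len,
                              int band, int min_anchors,
                              double hamming_accept) {
  int n_frag = 0, n_mapped = 0;
  double id_sum = 0.0;
  std::vector<double> ids;
  for (int qi = 0; qi < query_seqs.size(); ++qi) {
    std::string q = as<std::string>(query_seqs[qi]);
    int nq = (int)q.size();
    for (int f0 = 0; f0 + fragment_len <= nq; f0 += fragment_len) {
      ++n_frag;
      double id = score_fragment(q.c_str() + f0, fragment_len, idx, band,
                                 min_anchors, hamming_accept);
      if (id < 0) continue;
      ++n_mapped;
      id_sum += id;
      ids.push_back(id);
    }
  }
  return List::create(_["n_fragments"] = n_frag,
                      _["n_mapped"] = n_mapped,
                      _["identity_sum"] = id_sum,
                      _["identities"] = wrap(ids));
}

// [[Rcpp::export]]
List cpp_fragment_ani(CharacterVector query_seqs, std::string ref,
                      int fragment_len, int k_anchor, int band,
                      int min_anchors, double hamming_accept) {
  AnchorIndex* idx = build_index(ref, k_anchor);
  List out = fragment_ani_core(query_seqs, *idx, fragment_len, band,
                               min_anchors, hamming_accept);
  delete idx;
  return out;
}

// [[Rcpp::export]]
List cpp_fragment_ani_indexed(CharacterVector query_seqs, SEXP index,
                              int fragment_len, int band, int min_anchors,
                              double hamming_accept) {
  XPtr<AnchorIndex> idx(index);
  return fragment_ani_core(query_seqs, *idx, fragment_len, band,
                           min_anchors, hamming_accept);
}

// [[Rcpp::export]]
int cpp_anchor_index_k(SEXP index) {
  XPtr<AnchorIndex> idx(index);
  return idx->k;
}
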