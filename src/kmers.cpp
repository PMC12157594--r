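// Canonical k-mer sets and segment similarity scoring.
//
// K-mers are encoded 2 bits per base (A=0, C=1, G=2, T=3); a k-mer and
// its reverse complement collapse to the canonical (smaller) encoding, so
// membership is strand-neutral. Windows containing non-ACGT characters
// are skipped.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
using namespace Rcpp;

typedef std::unordered_set<uint64_t> KmerSet;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// enumerate canonical k-mers of seq, calling f(kmer) for each valid window
template <typename F>
static void each_canonical(const std::string& seq, int k, F f) {
  int n = seq.size();
  if (n < k) return;
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rev = 0;
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int code = base_code(seq[i]);
    if (code < 0) { valid = 0; fwd = rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)code) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - code) << (2 * (k - 1)));
    if (++valid >= k) f(std::min(fwd, rev));
  }
}

static void decode_kmer(uint64_t enc, int k, char* out) {
  static const char bases[] = "ACGT";
  for (int i = k - 1; i >= 0; --i) {
    out[i] = bases[enc & 3ULL];
    enc >>= 2;
  }
}

// [[Rcpp::export]]
SEXP cpp_kmer_build(CharacterVector seqs, int k, int min_count) {
  if (k < 1 || k > 32) stop("k must be between 1 and 32");
  std::unordered_map<uint64_t, int> counts;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    each_canonical(s, k, [&](uint64_t km) { counts[km]++; });
  }
  KmerSet* set = new KmerSet();
  set->reserve(counts.size());
  for (const auto& kv : counts)
    if (kv.second >= min_count) set->insert(kv.first);
  XPtr<KmerSet> ptr(set, true);
  return ptr;
}

// [[Rcpp::export]]
double cpp_kmer_size(SEXP ptr) {
  XPtr<KmerSet> set(ptr);
  return (double)set->size();
}

// [[Rcpp::export]]
CharacterVector cpp_kmer_dump(SEXP ptr, int k) {
  XPtr<KmerSet> set(ptr);
  std::vector<uint64_t> v(set->begin(), set->end());
  std::sort(v.begin(), v.end());
  CharacterVector out(v.size());
  std::vector<char> buf(k + 1, '\0');
  for (size_t i = 0; i < v.size(); ++i) {
    decode_kmer(v[i], k, buf.data());
    out[i] = std::string(buf.data(), k);
  }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_kmer_contains(SEXP ptr, CharacterVector kmers, int k) {
  XPtr<KmerSet> set(ptr);
  LogicalVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    if ((int)s.size() != k) stop("query k-mer length differs from set k");
    bool found = false;
    each_canonical(s, k, [&](uint64_t km) { found = set->count(km) > 0; });
    out[i] = found;
  }
  return out;
}

// Containment score of non-overlapping segments of each sequence: the
// fraction of the segment's distinct canonical k-mers present in the
// read k-mer set. Segments shorter than k (only possible for the final
// segment) and segments with no valid k-mer score 0.
// [[Rcpp::export]]
DataFrame cpp_segment_scores(SEXP ptr, CharacterVector seqs, int k,
                             int segment_size) {
  XPtr<KmerSet> set(ptr);
  std::vector<int> hap_idx, seg_idx, seg_start, seg_len, n_kmers;
  std::vector<double> score;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    int n = s.size();
    int nseg = (n + segment_size - 1) / segment_size;
    for (int j = 0; j < nseg; ++j) {
      int lo = j * segment_size;
      int len = std::min(segment_size, n - lo);
      KmerSet local;
      each_canonical(s.substr(lo, len), k, [&](uint64_t km) {
        local.insert(km);
      });
      int inter = 0;
      for (uint64_t km : local) if (set->count(km)) ++inter;
      hap_idx.push_back(i + 1);
      seg_idx.push_back(j + 1);
      seg_start.push_back(lo);
      seg_len.push_back(len);
      n_kmers.push_back((int)local.size());
      score.push_back(local.empty() ? 0.0 : (double)inter / local.size());
    }
  }
  return DataFrame::create(
    _["haplotype"] = wrap(hap_idx), _["segment_index"] = wrap(seg_idx),
    _["seg_start"] = wrap(seg_start), _["seg_len"] = wrap(seg_len),
    _["n_kmers"] = wrap(n_kmers), _["score"] = wrap(score));
}
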