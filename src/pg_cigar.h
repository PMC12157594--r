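#ifndef PG_CIGAR_H
#define PG_CIGAR_H

#include <Rcpp.h>
#include <string>
#include <vector>

struct CigOp { int len; char op; };

inline std::vector<CigOp> parse_cigar(const std::string& cig) {
  std::vector<CigOp> ops;
  int len = 0;
  for (char c : cig) {
    if (c >= '0' && c <= '9') {
      len = len * 10 + (c - '0');
    } else {
      if (len <= 0) Rcpp::stop("malformed CIGAR '" + cig + "'");
      ops.push_back({len, c});
      len = 0;
    }
  }
  if (len != 0) Rcpp::stop("malformed CIGAR '" + cig + "'");
  return ops;
}

// Left-align an insertion of `ins` occurring between ref positions p-1 and
// p; returns the shifted p, rotating `ins` in place.
inline int leftalign_ins(const std::string& ref, int p, std::string& ins) {
  int L = ins.size();
  while (p > 0 && ref[p - 1] == ins[L - 1]) {
    ins = std::string(1, ref[p - 1]) + ins.substr(0, L - 1);
    --p;
  }
  return p;
}

// Left-align a deletion of reference positions [p, p+L).
inline int leftalign_del(const std::string& ref, int p, int L) {
  while (p > 0 && ref[p - 1] == ref[p + L - 1]) --p;
  return p;
}

#endif
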