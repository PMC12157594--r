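#include <Rcpp.h>
#include <cstdint>
#include "pg_cigar.h"
using namespace Rcpp;

// CIGAR parsing shared by ingest, candidate discovery and the encoder.
// Supported ops after normalization: M, I, D, S.

// [[Rcpp::export]]
CharacterVector cpp_normalize_cigars(CharacterVector cigars) {
  CharacterVector out(cigars.size());
  for (R_xlen_t i = 0; i < cigars.size(); ++i) {
    std::string cig = as<std::string>(cigars[i]);
    std::vector<CigOp> ops = parse_cigar(cig);
    std::vector<CigOp> norm;
    for (CigOp o : ops) {
      char op = o.op;
      if (op == '=' || op == 'X') op = 'M';
      if (op == 'H') continue;  // hard clip: absent sequence
      if (op != 'M' && op != 'I' && op != 'D' && op != 'S')
        stop("unsupported CIGAR op '" + std::string(1, op) + "' in '" + cig + "'");
      if (!norm.empty() && norm.back().op == op) norm.back().len += o.len;
      else norm.push_back({o.len, op});
    }
    std::string s;
    for (CigOp o : norm) s += std::to_string(o.len) + o.op;
    out[i] = s;
  }
  return out;
}

// query length (M+I+S) and reference span (M+D) per CIGAR
// [[Rcpp::export]]
List cpp_cigar_info(CharacterVector cigars) {
  IntegerVector qlen(cigars.size()), rspan(cigars.size());
  for (R_xlen_t i = 0; i < cigars.size(); ++i) {
    std::vector<CigOp> ops = parse_cigar(as<std::string>(cigars[i]));
    int q = 0, r = 0;
    for (CigOp o : ops) {
      if (o.op == 'M' || o.op == 'I' || o.op == 'S') q += o.len;
      if (o.op == 'M' || o.op == 'D') r += o.len;
    }
    qlen[i] = q; rspan[i] = r;
  }
  return List::create(_["qlen"] = qlen, _["rspan"] = rspan);
}

// Walk read alignments against one contig, emitting normalized per-read
// variant events (anchored, left-aligned) and per-position aligned depth.
// `starts` are 0-based contig-local. Events at candidate positions where the
// anchor would fall before the contig start are skipped. Mismatches against
// reference N, or read base N, are skipped.
// [[Rcpp::export]]
List cpp_candidate_events(IntegerVector starts, CharacterVector cigars,
                          CharacterVector seqs, CharacterVector quals,
                          std::string ref, int min_base_qual) {
  int n = starts.size();
  int reflen = ref.size();
  IntegerVector depth(reflen);
  std::vector<int> ev_read, ev_pos, ev_kind;
  std::vector<std::string> ev_ref, ev_alt;

  for (int i = 0; i < n; ++i) {
    std::vector<CigOp> ops = parse_cigar(as<std::string>(cigars[i]));
    std::string seq = as<std::string>(seqs[i]);
    bool has_qual = !CharacterVector::is_na(quals[i]);
    std::string qual = has_qual ? as<std::string>(quals[i]) : std::string();
    int p = starts[i], q = 0;
    for (CigOp o : ops) {
      if (o.op == 'S') { q += o.len; continue; }
      if (o.op == 'M') {
        int lo = std::max(p, 0), hi = std::min(p + o.len, reflen);
        for (int rp = lo; rp < hi; ++rp) depth[rp]++;
        for (int t = 0; t < o.len; ++t) {
          int rp = p + t;
          if (rp < 0 || rp >= reflen) continue;
          char rb = ref[rp], qb = seq[q + t];
          if (rb == 'N' || qb == 'N' || rb == qb) continue;
          if (min_base_qual > 0 && has_qual &&
              (qual[q + t] - 33) < min_base_qual) continue;
          ev_read.push_back(i + 1);
          ev_pos.push_back(rp);
          ev_ref.push_back(std::string(1, rb));
          ev_alt.push_back(std::string(1, qb));
          ev_kind.push_back(0);
        }
        p += o.len; q += o.len;
      } else if (o.op == 'I') {
        std::string ins = seq.substr(q, o.len);
        if (p > 0 && p <= reflen && ins.find('N') == std::string::npos) {
          int ps = leftalign_ins(ref, p, ins);
          if (ps > 0) {
            int a = ps - 1;
            ev_read.push_back(i + 1);
            ev_pos.push_back(a);
            ev_ref.push_back(std::string(1, ref[a]));
            ev_alt.push_back(std::string(1, ref[a]) + ins);
            ev_kind.push_back(1);
          }
        }
        q += o.len;
      } else if (o.op == 'D') {
        if (p > 0 && p + o.len <= reflen) {
          int ps = leftalign_del(ref, p, o.len);
          if (ps > 0) {
            int a = ps - 1;
            std::string refall = ref.substr(a, o.len + 1);
            if (refall.find('N') == std::string::npos) {
              ev_read.push_back(i + 1);
              ev_pos.push_back(a);
              ev_ref.push_back(refall);
              ev_alt.push_back(std::string(1, ref[a]));
              ev_kind.push_back(2);
            }
          }
        }
        p += o.len;
      }
    }
  }

  return List::create(
    _["read"] = wrap(ev_read), _["pos"] = wrap(ev_pos),
    _["ref"] = wrap(ev_ref), _["alt"] = wrap(ev_alt),
    _["kind"] = wrap(ev_kind), _["depth"] = depth);
}

// Normalize a set of variant alleles against a reference contig string:
// trim shared suffix then shared prefix, then left-align pure indels.
// Positions are 0-based contig-local.
// [[Rcpp::export]]
List cpp_normalize_variants(IntegerVector pos, CharacterVector ref_allele,
                            CharacterVector alt_allele, std::string ref) {
  int n = pos.size();
  IntegerVector opos(n);
  CharacterVector oref(n), oalt(n);
  for (int i = 0; i < n; ++i) {
    int p = pos[i];
    std::string r = as<std::string>(ref_allele[i]);
    std::string a = as<std::string>(alt_allele[i]);
    while (r.size() > 1 && a.size() > 1 && r.back() == a.back()) {
      r.pop_back(); a.pop_back();
    }
    while (r.size() > 1 && a.size() > 1 && r[0] == a[0]) {
      r.erase(0, 1); a.erase(0, 1); ++p;
    }
    if (r.size() == 1 && a.size() > 1 && a[0] == r[0]) {
      // insertion: alt = anchor + ins at anchor p
      std::string ins = a.substr(1);
      int ps = leftalign_ins(ref, p + 1, ins);
      if (ps > 0) {
        p = ps - 1;
        r = std::string(1, ref[p]);
        a = r + ins;
      }
    } else if (a.size() == 1 && r.size() > 1 && r[0] == a[0]) {
      // deletion of [p+1, p+len)
      int L = r.size() - 1;
      int ps = leftalign_del(ref, p + 1, L);
      if (ps > 0) {
        p = ps - 1;
        r = ref.substr(p, L + 1);
        a = std::string(1, ref[p]);
      }
    }
    opos[i] = p; oref[i] = r; oalt[i] = a;
  }
  return List::create(_["pos"] = opos, _["ref"] = oref, _["alt"] = oalt);
}
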