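#include <Rcpp.h>
#include <cstring>
#include "pg_cigar.h"
using namespace Rcpp;

// Pileup tensor encoder. One example is a float32 buffer of shape
// (2*height) rows x width cols x 6 channels, stored row-major with the
// channel index fastest: buf[((row*width)+col)*6 + channel].
//
// Channels: 0 BASE, 1 BASE_QUAL, 2 MAP_QUAL, 3 STRAND, 4 SUPPORTS_ALT,
// 5 DIFFERS_FROM_REF. Encodings (bounded, monotone, distinct):
//   BASE:      A=0.25 C=0.50 G=0.75 T=1.00 N=0.05 deletion-gap=0.10 empty=0
//   BASE_QUAL: min(q,40)/40        MAP_QUAL: min(q,60)/60
//   STRAND:    forward=0.5 reverse=1.0 (0 when unspecified)
//   SUPPORTS_ALT: carries candidate alt=1.0, carries ref=0.5, other=0.25
//   DIFFERS_FROM_REF: differs=1.0, matches=0.3
// Haplotype rows leave BASE_QUAL, MAP_QUAL and STRAND at exactly 0.

static const int NCHAN = 6;

static inline float base_enc(char b) {
  switch (b) {
    case 'A': return 0.25f; case 'C': return 0.50f;
    case 'G': return 0.75f; case 'T': return 1.00f;
    default:  return 0.05f;  // N or other
  }
}

struct RowAssert {
  bool covers_span;        // all candidate ref-allele columns aligned with M
  char base_at_cand;       // aligned base at candidate column ('\0' if none)
  std::string ins_at_anchor;  // inserted sequence anchored at candidate pos
  int del_at_anchor;       // deletion length anchored at candidate pos
  bool indel_in_span;      // any indel touching the candidate span
};

// First walk: what does this row assert at the candidate site?
// Left-alignment of row indels is done in window coordinates; the
// candidate sits at the window center, so for any realistic homopolymer
// shift the window-local result equals the contig-local one.
static RowAssert row_assert(const std::vector<CigOp>& ops, int colp0,
                            const std::string& seq,
                            const std::string& ref_win,
                            int cand_col, int span_len) {
  RowAssert ra{true, '\0', "", 0, false};
  std::vector<bool> m_cover(span_len, false);
  int p = colp0, q = 0;
  int width = ref_win.size();
  for (const CigOp& o : ops) {
    if (o.op == 'S') { q += o.len; continue; }
    if (o.op == 'M') {
      int tlo = std::max(0, cand_col - p);
      int thi = std::min(o.len, cand_col + span_len - p);
      for (int t = tlo; t < thi; ++t) {
        int col = p + t;
        m_cover[col - cand_col] = true;
        if (col == cand_col) ra.base_at_cand = seq[q + t];
      }
      p += o.len; q += o.len;
    } else if (o.op == 'I') {
      std::string ins = seq.substr(q, o.len);
      int ps = (p > 0 && p <= width) ? leftalign_ins(ref_win, p, ins) : p;
      int anchor = ps - 1;
      if (anchor == cand_col) ra.ins_at_anchor = ins;
      if (anchor >= cand_col - 1 && anchor < cand_col + span_len)
        ra.indel_in_span = true;
      q += o.len;
    } else if (o.op == 'D') {
      int ps = (p > 0 && p + o.len <= width) ? leftalign_del(ref_win, p, o.len) : p;
      int anchor = ps - 1;
      if (anchor == cand_col) ra.del_at_anchor = o.len;
      if (anchor < cand_col + span_len && anchor + o.len >= cand_col)
        ra.indel_in_span = true;
      p += o.len;
    }
  }
  for (int t = 0; t < span_len; ++t) if (!m_cover[t]) ra.covers_span = false;
  return ra;
}

// SUPPORTS_ALT value for one row given the candidate alleles.
// kind: 0 SNP, 1 insertion, 2 deletion. Rows not covering the candidate
// column fall into the "other" bucket (0.25).
static float support_value(const RowAssert& ra, int kind,
                           const std::string& cand_ref,
                           const std::string& cand_alt) {
  if (kind == 0) {
    if (ra.base_at_cand == '\0') return 0.25f;
    if (ra.base_at_cand == cand_alt[0]) return 1.0f;
    if (ra.base_at_cand == cand_ref[0] && !ra.indel_in_span) return 0.5f;
    return 0.25f;
  }
  if (kind == 1) {
    if (!ra.ins_at_anchor.empty())
      return ra.ins_at_anchor == cand_alt.substr(1) ? 1.0f : 0.25f;
    if (ra.covers_span && !ra.indel_in_span && ra.base_at_cand == cand_ref[0])
      return 0.5f;
    return 0.25f;
  }
  // deletion
  if (ra.del_at_anchor > 0)
    return ra.del_at_anchor == (int)cand_ref.size() - 1 ? 1.0f : 0.25f;
  if (ra.covers_span && !ra.indel_in_span) return 0.5f;
  return 0.25f;
}

// Second walk: paint the row's columns.
static void paint_row(float* buf, int width, int row,
                      const std::vector<CigOp>& ops, int colp0,
                      const std::string& seq, const std::string& qual,
                      int mapq, int strand_code, bool is_hap,
                      const std::string& ref_win, float support) {
  float mq_enc = 0.0f, strand_enc = 0.0f;
  if (!is_hap) {
    if (mapq >= 0) mq_enc = std::min(mapq, 60) / 60.0f;
    if (strand_code == 1) strand_enc = 0.5f;
    else if (strand_code == 2) strand_enc = 1.0f;
  }
  bool has_qual = !is_hap && !qual.empty();
  int p = colp0, q = 0;
  for (const CigOp& o : ops) {
    if (o.op == 'S') { q += o.len; continue; }
    if (o.op == 'M') {
      int tlo = std::max(0, -p);
      int thi = std::min(o.len, width - p);
      for (int t = tlo; t < thi; ++t) {
        int col = p + t;
        if (ref_win[col] == '.') continue;  // outside the contig
        float* cell = buf + ((size_t)row * width + col) * NCHAN;
        char b = seq[q + t];
        cell[0] = base_enc(b);
        if (has_qual) cell[1] = std::min(qual[q + t] - 33, 40) / 40.0f;
        cell[2] = mq_enc;
        cell[3] = strand_enc;
        cell[4] = support;
        cell[5] = (b != ref_win[col] || b == 'N') ? 1.0f : 0.3f;
      }
      p += o.len; q += o.len;
    } else if (o.op == 'I') {
      std::string ins = seq.substr(q, o.len);
      int ps = (p > 0 && p <= width) ? leftalign_ins(ref_win, p, ins) : p;
      int anchor = ps - 1;
      if (anchor >= 0 && anchor < width && ref_win[anchor] != '.') {
        float* cell = buf + ((size_t)row * width + anchor) * NCHAN;
        cell[5] = 1.0f;  // insertion flagged at its anchor column
      }
      q += o.len;
    } else if (o.op == 'D') {
      int tlo = std::max(0, -p);
      int thi = std::min(o.len, width - p);
      for (int t = tlo; t < thi; ++t) {
        int col = p + t;
        if (ref_win[col] == '.') continue;
        float* cell = buf + ((size_t)row * width + col) * NCHAN;
        cell[0] = 0.10f;  // deletion gap
        cell[1] = 0.0f;
        cell[2] = mq_enc;
        cell[3] = strand_enc;
        cell[4] = support;
        cell[5] = 1.0f;
      }
      p += o.len;
    }
  }
}

static void encode_block(float* buf, int width, int row_offset,
                         const List& block, bool is_hap,
                         const std::string& ref_win, int cand_col,
                         const std::string& cand_ref,
                         const std::string& cand_alt, int kind,
                         int win_start) {
  IntegerVector starts = block["start"];
  CharacterVector cigars = block["cigar"];
  CharacterVector bases = block["bases"];
  CharacterVector quals = block["qual"];
  IntegerVector mapqs = block["mapq"];
  IntegerVector strands = block["strand"];
  int span_len = cand_ref.size();
  for (int i = 0; i < starts.size(); ++i) {
    std::vector<CigOp> ops = parse_cigar(as<std::string>(cigars[i]));
    std::string seq = as<std::string>(bases[i]);
    std::string qual = CharacterVector::is_na(quals[i])
                         ? std::string() : as<std::string>(quals[i]);
    int colp0 = starts[i] - win_start;
    RowAssert ra = row_assert(ops, colp0, seq, ref_win, cand_col, span_len);
    float sup = support_value(ra, kind, cand_ref, cand_alt);
    int mapq = IntegerVector::is_na(mapqs[i]) ? -1 : (int)mapqs[i];
    paint_row(buf, width, row_offset + i, ops, colp0, seq, qual, mapq,
              strands[i], is_hap, ref_win, sup);
  }
}

// [[Rcpp::export]]
RawVector cpp_encode_example(int width, int height, int win_start,
                             std::string ref_win, int cand_pos,
                             std::string cand_ref, std::string cand_alt,
                             int cand_kind, List hap_block, List read_block) {
  if ((int)ref_win.size() != width)
    stop("reference window length does not match pileup width");
  size_t nfloat = (size_t)2 * height * width * NCHAN;
  std::vector<float> buf(nfloat, 0.0f);
  int cand_col = cand_pos - win_start;
  encode_block(buf.data(), width, 0, hap_block, true, ref_win, cand_col,
               cand_ref, cand_alt, cand_kind, win_start);
  encode_block(buf.data(), width, height, read_block, false, ref_win,
               cand_col, cand_ref, cand_alt, cand_kind, win_start);
  RawVector out(nfloat * 4);
  std::memcpy(RAW(out), buf.data(), nfloat * 4);
  return out;
}

// Zero the haplotype block (rows [0, height)) of encoded examples in
// place; used for the reads-only ablation.
// [[Rcpp::export]]
List cpp_zero_hap_block(List examples, int height, int width) {
  size_t nbytes = (size_t)height * width * NCHAN * 4;
  for (R_xlen_t i = 0; i < examples.size(); ++i) {
    RawVector x = examples[i];
    RawVector y = clone(x);
    std::memset(RAW(y), 0, nbytes);
    examples[i] = y;
  }
  return examples;
}
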