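#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cstring>
#include <map>
#include <string>
#include <vector>
using namespace Rcpp;

// Scoring for the semi-global aligner. 'N' is neutral: it neither rewards
// nor penalizes, so ambiguous consensus positions never attract gaps.
static inline int score_pair(char a, char b, int match, int mismatch) {
  if (a == 'N' || b == 'N') return 0;
  return (a == b) ? match : mismatch;
}

struct Aln {
  std::string qa;  // gapped query
  std::string ra;  // gapped reference
  int score;
};

// Semi-global (free end-gap) alignment with affine gaps.
// A gap of length L costs gap_open + gap_ext * (L - 1).
// End gaps on either sequence are free; traceback ties prefer the
// diagonal, then a gap in the query (deletion), then a gap in the
// reference. Indel events are left-normalized downstream, so the
// tie-break only needs to be deterministic.
static Aln semiglobal_align(const std::string& q, const std::string& r,
                            int match, int mismatch, int gap_open,
                            int gap_ext) {
  const int n = (int)q.size(), m = (int)r.size();
  const int NEG = -100000000;
  std::vector<int> Hp(m + 1), H(m + 1), Ep(m + 1), E(m + 1), Fp(m + 1),
      F(m + 1);
  // full matrices for traceback (small sequences: <= ~110 bp)
  std::vector<std::vector<int>> HM(n + 1, std::vector<int>(m + 1)),
      EM(n + 1, std::vector<int>(m + 1, NEG)),
      FM(n + 1, std::vector<int>(m + 1, NEG));
  for (int j = 0; j <= m; ++j) HM[0][j] = 0;
  for (int i = 0; i <= n; ++i) HM[i][0] = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int e = std::max(HM[i][j - 1] - gap_open, EM[i][j - 1] - gap_ext);
      int f = std::max(HM[i - 1][j] - gap_open, FM[i - 1][j] - gap_ext);
      int d = HM[i - 1][j - 1] + score_pair(q[i - 1], r[j - 1], match, mismatch);
      EM[i][j] = e;
      FM[i][j] = f;
      HM[i][j] = std::max(d, std::max(e, f));
    }
  }
  // best end cell over last row / last column; prefer the corner, then
  // larger j, then larger i (deterministic)
  int bi = n, bj = m, best = HM[n][m];
  for (int j = m - 1; j >= 0; --j)
    if (HM[n][j] > best) { best = HM[n][j]; bi = n; bj = j; }
  for (int i = n - 1; i >= 0; --i)
    if (HM[i][m] > best) { best = HM[i][m]; bi = i; bj = m; }

  std::string qa, ra;
  // free trailing gaps
  for (int j = m; j > bj; --j) { qa.push_back('-'); ra.push_back(r[j - 1]); }
  for (int i = n; i > bi; --i) { qa.push_back(q[i - 1]); ra.push_back('-'); }
  int i = bi, j = bj;
  int state = 0;  // 0 = H, 1 = E (gap in query), 2 = F (gap in ref)
  while (i > 0 && j > 0) {
    if (state == 0) {
      int d = HM[i - 1][j - 1] + score_pair(q[i - 1], r[j - 1], match, mismatch);
      if (HM[i][j] == d) {
        qa.push_back(q[i - 1]); ra.push_back(r[j - 1]); --i; --j;
      } else if (HM[i][j] == EM[i][j]) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      qa.push_back('-'); ra.push_back(r[j - 1]);
      if (EM[i][j] == HM[i][j - 1] - gap_open) state = 0;
      --j;
    } else {
      qa.push_back(q[i - 1]); ra.push_back('-');
      if (FM[i][j] == HM[i - 1][j] - gap_open) state = 0;
      --i;
    }
  }
  while (j > 0) { qa.push_back('-'); ra.push_back(r[j - 1]); --j; }
  while (i > 0) { qa.push_back(q[i - 1]); ra.push_back('-'); --i; }
  std::reverse(qa.begin(), qa.end());
  std::reverse(ra.begin(), ra.end());
  Aln a; a.qa = qa; a.ra = ra; a.score = best;
  return a;
}

//' @noRd
// [[Rcpp::export]]
List cpp_align(std::string query, std::string ref, int match = 1,
               int mismatch = -1, int gap_open = 2, int gap_ext = 1) {
  Aln a = semiglobal_align(query, ref, match, -std::abs(mismatch),
                           gap_open, gap_ext);
  return List::create(_["query"] = a.qa, _["ref"] = a.ra,
                      _["score"] = a.score);
}

static inline int base_idx(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    case '-': return 4;
    default: return -1;  // N / other: no vote
  }
}

// Per-family consensus: reads are contiguous in `reads` per family
// (fam_start 1-based, fam_size). Families below min_reads yield NA.
// Reads whose length differs from the family's modal length are
// pairwise-aligned to the first modal-length read before column voting.
// A column emits the majority symbol when its unique argmax reaches
// min_agreement of the family size; a winning gap drops the column;
// everything else (including exact ties) emits N.
//' @noRd
// [[Rcpp::export]]
CharacterVector cpp_consensus(CharacterVector reads, IntegerVector fam_start,
                              IntegerVector fam_size, int min_reads = 3,
                              double min_agreement = 0.9, int match = 1,
                              int mismatch = -1, int gap_open = 2,
                              int gap_ext = 1) {
  const int nf = fam_start.size();
  CharacterVector out(nf);
  for (int f = 0; f < nf; ++f) {
    const int s = fam_start[f] - 1;
    const int n = fam_size[f];
    if (n < min_reads) { out[f] = NA_STRING; continue; }
    // modal length; ties -> shortest (std::map iterates ascending)
    std::map<int, int> lens;
    for (int i = 0; i < n; ++i)
      lens[(int)std::strlen(CHAR(STRING_ELT(reads, s + i)))]++;
    int L = 0, lc = -1;
    for (auto& kv : lens)
      if (kv.second > lc) { lc = kv.second; L = kv.first; }
    // anchor: lexicographically smallest modal-length read, so the
    // consensus is independent of read input order
    std::string anchor;
    for (int i = 0; i < n; ++i) {
      const char* rd = CHAR(STRING_ELT(reads, s + i));
      if ((int)std::strlen(rd) == L &&
          (anchor.empty() || std::string(rd) < anchor))
        anchor = rd;
    }
    std::vector<std::array<int, 5>> cnt(L, {0, 0, 0, 0, 0});
    for (int i = 0; i < n; ++i) {
      std::string rd = CHAR(STRING_ELT(reads, s + i));
      if ((int)rd.size() == L) {
        for (int j = 0; j < L; ++j) {
          int b = base_idx(rd[j]);
          if (b >= 0) cnt[j][b]++;
        }
      } else {
        Aln a = semiglobal_align(rd, anchor, match, mismatch, gap_open,
                                 gap_ext);
        int col = -1;
        for (size_t t = 0; t < a.ra.size(); ++t) {
          if (a.ra[t] == '-') continue;  // insertion rel. anchor: ignored
          ++col;
          int b = base_idx(a.qa[t]);
          if (b >= 0 && col < L) cnt[col][b]++;
        }
      }
    }
    std::string cons;
    cons.reserve(L);    static const char sym[5] = {'A', 'C', 'G', 'T', '-'};
    for (int j = 0; j < L; ++j) {
      int bi = 0, bc = -1, nb = 0;
      for (int b = 0; b < 5; ++b) {
        if (cnt[j][b] > bc) { bc = cnt[j][b]; bi = b; nb = 1; }
        else if (cnt[j][b] == bc) { nb++; }
      }
      const double frac = (double)bc / (double)n;
      if (nb == 1 && frac >= min_agreement - 1e-9) {
        if (sym[bi] != '-') cons.push_back(sym[bi]);
        // winning gap: column deleted
      } else {
        cons.push_back('N');
      }
    }
    out[f] = cons;
  }
  return out;
}

// Assign each sequence to the primer with minimal Hamming distance over
// the primer's length. Returns 1-based best index (0 = unassigned),
// mismatch count, and reason code (0 ok, 1 too_short, 2 ambiguous,
// 3 no_match).
//' @noRd
// [[Rcpp::export]]
List cpp_assign_primer(CharacterVector seqs, CharacterVector primers,
                       int max_mismatch = 2) {
  const int ns = seqs.size(), np = primers.size();
  std::vector<std::string> prim(np);
  int min_plen = 1 << 30;
  for (int p = 0; p < np; ++p) {
    prim[p] = CHAR(STRING_ELT(primers, p));
    min_plen = std::min(min_plen, (int)prim[p].size());
  }
  IntegerVector idx(ns), mm(ns), reason(ns);
  for (int i = 0; i < ns; ++i) {
    const char* sq = CHAR(STRING_ELT(seqs, i));
    const int slen = (int)std::strlen(sq);
    if (slen < min_plen) { idx[i] = 0; mm[i] = NA_INTEGER; reason[i] = 1; continue; }
    int best = 1 << 30, bestp = -1, nbest = 0;
    for (int p = 0; p < np; ++p) {
      const int pl = (int)prim[p].size();
      if (slen < pl) continue;
      int d = 0;
      for (int j = 0; j < pl && d <= max_mismatch; ++j)
        if (sq[j] != prim[p][j]) ++d;
      if (d < best) { best = d; bestp = p; nbest = 1; }
      else if (d == best) { nbest++; }
    }
    if (bestp < 0 || best > max_mismatch) {
      idx[i] = 0; mm[i] = NA_INTEGER; reason[i] = 3;
    } else if (nbest > 1) {
      idx[i] = 0; mm[i] = best; reason[i] = 2;
    } else {
      idx[i] = bestp + 1; mm[i] = best; reason[i] = 0;
    }
  }
  return List::create(_["index"] = idx, _["mismatches"] = mm,
                      _["reason"] = reason);
}
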