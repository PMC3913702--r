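// Fast inner loops for read cleaning and target-site scanning.

#include <Rcpp.h>
#include <string>
#include <cmath>

using namespace Rcpp;

namespace {

inline char norm(char c) {
  if (c == 't') return 'T';
  if (c == 'u' || c == 'U') return 'T';
  if (c >= 'a' && c <= 'z') return (char)(c - 32);
  return c;
}

// state of one duplex position: 2 = Watson-Crick match, 1 = G:U wobble,
// 0 = mismatch.  m is the miRNA base, t the transcript (site) base, both
// 5'->3' in DNA alphabet.
inline int duplexState(char m, char t) {
  switch (m) {
    case 'A': return (t == 'T') ? 2 : 0;
    case 'C': return (t == 'G') ? 2 : 0;
    case 'G': if (t == 'C') return 2; return (t == 'T') ? 1 : 0;
    case 'T': if (t == 'A') return 2; return (t == 'G') ? 1 : 0;
  }
  return 0;
}

}  // namespace

// Leftmost qualifying 3' adapter start (1-based) in each read, or 0 when no
// match.  The full overlap min(adapter length, bases remaining) is compared;
// overlaps >= mm_allow_len may carry max_mm mismatches, shorter overlaps
// must be exact; overlaps < min_overlap never qualify.
// [[Rcpp::export(name = ".find_adapter")]]
IntegerVector find_adapter(CharacterVector reads, std::string adapter,
                           int min_overlap = 5, int mm_allow_len = 8,
                           int max_mm = 1) {
  const int alen = (int)adapter.size();
  for (int t = 0; t < alen; ++t) adapter[t] = norm(adapter[t]);
  const int nr = reads.size();
  IntegerVector out(nr);
  for (int r = 0; r < nr; ++r) {
    const char* rd = CHAR(STRING_ELT(reads, r));
    int len = (int)LENGTH(STRING_ELT(reads, r));
    int hit = 0;
    for (int p = 0; p + min_overlap <= len; ++p) {
      const int ov = std::min(alen, len - p);
      const int allow = (ov >= mm_allow_len) ? max_mm : 0;
      int mm = 0;
      for (int t = 0; t < ov; ++t) {
        if (norm(rd[p + t]) != adapter[t] && ++mm > allow) break;
      }
      if (mm <= allow) { hit = p + 1; break; }
    }
    out[r] = hit;
  }
  return out;
}

// Scans every length-L window of a transcript against a miRNA (antisense
// pairing: miRNA position p pairs window position L - p + 1) and returns the
// 1-based starts and scores of windows with mismatch score <= max_score
// (G:U wobbles count 0.5, mismatches 1).
// [[Rcpp::export(name = ".scan_duplex")]]
DataFrame scan_duplex(std::string mirna, std::string transcript,
                      double max_score = 4.0) {
  const int L = (int)mirna.size();
  const int Tn = (int)transcript.size();
  for (auto& c : mirna) c = norm(c);
  for (auto& c : transcript) c = norm(c);
  std::vector<int> starts;
  std::vector<double> scores;
  for (int w = 0; w + L <= Tn; ++w) {
    double sc = 0.0;
    for (int p = 0; p < L; ++p) {
      const int st = duplexState(mirna[p], transcript[w + L - 1 - p]);
      if (st == 1) sc += 0.5; else if (st == 0) sc += 1.0;
      if (sc > max_score) break;
    }
    if (sc <= max_score) { starts.push_back(w + 1); scores.push_back(sc); }
  }
  return DataFrame::create(_["start"] = wrap(starts),
                           _["score"] = wrap(scores));
}
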