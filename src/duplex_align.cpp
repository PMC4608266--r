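// Semi-global alignment of a mature miRNA against a transcript.
//
// The miRNA is aligned antiparallel: walking the transcript 5'->3' walks the
// miRNA 3'->5'. The pattern is therefore the reversed miRNA; every pattern row
// must be consumed (the whole miRNA is covered) while the transcript start and
// end are free. Affine gaps; pairing is scored directly on (miRNA base,
// transcript base) so G:U wobbles can be rewarded.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -1e30;

static inline int pair_code(char m, char t) {
  // 2 = Watson-Crick, 1 = G:U wobble, 0 = mismatch
  if ((m == 'A' && t == 'U') || (m == 'U' && t == 'A') ||
      (m == 'G' && t == 'C') || (m == 'C' && t == 'G')) return 2;
  if ((m == 'G' && t == 'U') || (m == 'U' && t == 'G')) return 1;
  return 0;
}

// [[Rcpp::export(name = ".duplex_align_cpp")]]
List duplex_align_cpp(std::string mirna, std::string transcript,
                      double match, double gu, double mismatch,
                      double gap_open, double gap_ext,
                      double min_score) {
  const int m = (int) mirna.size();
  const int n = (int) transcript.size();
  if (m < 1 || n < m) stop("transcript shorter than miRNA");

  // pattern index i (1..m) corresponds to miRNA position m - i + 1
  std::vector<char> pat(m + 1);
  for (int i = 1; i <= m; ++i) pat[i] = mirna[m - i];

  const size_t sz = (size_t)(m + 1) * (n + 1);
  std::vector<double> M(sz, NEG_INF), X(sz, NEG_INF), Y(sz, NEG_INF);
  // traceback pointers: previous state (0=M,1=X,2=Y,3=start)
  std::vector<signed char> pM(sz, -1), pX(sz, -1), pY(sz, -1);
  auto at = [n](int i, int j) { return (size_t) i * (n + 1) + j; };

  for (int i = 1; i <= m; ++i) {
    for (int j = 0; j <= n; ++j) {
      const size_t ij = at(i, j);
      if (j >= 1) {
        // M: pattern i aligned to transcript j (pair or mismatch column)
        int pc = pair_code(pat[i], transcript[j - 1]);
        double s = (pc == 2) ? match : (pc == 1 ? gu : mismatch);
        double best = NEG_INF; signed char ptr = -1;
        if (i == 1) { best = 0.0; ptr = 3; }           // free start
        const size_t prev = at(i - 1, j - 1);
        if (i >= 2) {
          if (M[prev] > best) { best = M[prev]; ptr = 0; }
          if (X[prev] > best) { best = X[prev]; ptr = 1; }
          if (Y[prev] > best) { best = Y[prev]; ptr = 2; }
        }
        if (ptr >= 0) { M[ij] = best + s; pM[ij] = ptr; }
        // X: transcript base j unpaired (bulged target base), internal only
        const size_t left = at(i, j - 1);
        double bx = NEG_INF; signed char px = -1;
        if (M[left] + gap_open > bx) { bx = M[left] + gap_open; px = 0; }
        if (X[left] + gap_ext  > bx) { bx = X[left] + gap_ext;  px = 1; }
        if (Y[left] + gap_open > bx) { bx = Y[left] + gap_open; px = 2; }
        if (px >= 0 && bx > NEG_INF / 2) { X[ij] = bx; pX[ij] = px; }
      }
      // Y: pattern base i unpaired (bulged miRNA base)
      double by = NEG_INF; signed char py = -1;
      if (i == 1) { by = gap_open; py = 3; }
      else {
        const size_t up = at(i - 1, j);
        if (M[up] + gap_open > by) { by = M[up] + gap_open; py = 0; }
        if (Y[up] + gap_ext  > by) { by = Y[up] + gap_ext;  py = 2; }
        if (X[up] + gap_open > by) { by = X[up] + gap_open; py = 1; }
      }
      if (py >= 0 && by > NEG_INF / 2) { Y[at(i, j)] = by; pY[at(i, j)] = py; }
    }
  }

  // candidate ends: full pattern consumed; last column is a pairing column or
  // a bulged miRNA base (never a trailing bulged transcript base)
  List out;
  for (int j = 1; j <= n; ++j) {
    const size_t ej = at(m, j);
    double sc = std::max(M[ej], Y[ej]);
    if (sc < min_score) continue;
    int state = (M[ej] >= Y[ej]) ? 0 : 2;
    // traceback
    std::vector<int> mpos, tpos;   // 0 encodes a gap
    int i = m, jj = j, st = state;
    while (true) {
      signed char prev;
      if (st == 0) {              // M column: pattern i ~ transcript jj
        mpos.push_back(m - i + 1);
        tpos.push_back(jj);
        prev = pM[at(i, jj)];
        --i; --jj;
      } else if (st == 1) {       // X column: transcript jj unpaired
        mpos.push_back(0);
        tpos.push_back(jj);
        prev = pX[at(i, jj)];
        --jj;
      } else {                    // Y column: pattern i unpaired
        mpos.push_back(m - i + 1);
        tpos.push_back(0);
        prev = pY[at(i, jj)];
        --i;
      }
      if (prev == 3 || prev < 0) break;
      st = prev;
    }
    std::reverse(mpos.begin(), mpos.end());
    std::reverse(tpos.begin(), tpos.end());
    int site_start = 0, site_end = 0;
    for (size_t k = 0; k < tpos.size(); ++k)
      if (tpos[k] > 0) { if (!site_start) site_start = tpos[k]; site_end = tpos[k]; }
    out.push_back(List::create(
      _["score"] = sc,
      _["mirna_pos"] = IntegerVector(mpos.begin(), mpos.end()),
      _["t_pos"] = IntegerVector(tpos.begin(), tpos.end()),
      _["site_start"] = site_start,
      _["site_end"] = site_end));
  }
  return out;
}
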