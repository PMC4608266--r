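// Exhaustive enumeration of defect placements on an L-nt miRNA duplex for the
// target/decoy rule engine. Every placement assigns at most one defect
// (MISMATCH, bulged miRNA base, or bulged transcript base) per miRNA
// position; a bulged transcript base at position i is the insertion between
// miRNA positions i and i+1 (so i ranges over 1..L-1).
//
// Two independent code paths are computed per placement:
//   route A: build the explicit column-state sequence and count the region
//            diagnostics by scanning it (oracle for region_diagnostics);
//   route B: evaluate the published target/decoy clauses directly from the
//            placement (oracle for classify_interaction).
// Results are aggregated over distinct (diagnostics, route-B verdict) tuples.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

enum DefType { MM = 0, BM = 1, BT = 2 };

struct Key {
  int d912, p28, other_t, other_d, run, tgt, dcy;
};

static inline int pack(const Key& k) {
  return k.d912 | (k.p28 << 4) | (k.other_t << 5) | (k.other_d << 9) |
         (k.run << 13) | (k.tgt << 17) | (k.dcy << 18);
}

// [[Rcpp::export(name = ".enum_defect_rule_table_cpp")]]
DataFrame enum_defect_rule_table_cpp(int L, int max_defects) {
  if (L < 13) stop("L must be >= 13");
  std::unordered_map<int, double> acc;
  std::vector<int> pos(max_defects), typ(max_defects);

  std::vector<int> state(2 * L + 2);      // column scratch: 0=pair,1=MM,2=BM,3=BT
  std::vector<int> assign(2 * L + 2);     // miRNA position each column is assigned to

  for (int d = 0; d <= max_defects; ++d) {
    // first combination 1..d
    for (int c = 0; c < d; ++c) pos[c] = c + 1;
    bool more_comb = true;
    while (more_comb) {
      for (int c = 0; c < d; ++c) typ[c] = 0;
      bool more_typ = true;
      while (more_typ) {
        bool valid = true;
        for (int c = 0; c < d; ++c)
          if (typ[c] == BT && pos[c] == L) { valid = false; break; }
        if (valid) {
          // ---- route A: explicit columns ----
          int nc = 0;
          for (int i = 1; i <= L; ++i) {
            int t = -1;
            for (int c = 0; c < d; ++c) if (pos[c] == i) { t = typ[c]; break; }
            state[nc] = (t == MM) ? 1 : (t == BM ? 2 : 0);
            assign[nc] = i;
            ++nc;
            if (t == BT) { state[nc] = 3; assign[nc] = i; ++nc; }
          }
          Key k = {0, 1, 0, 0, 0, 0, 0};
          int run = 0;
          for (int c = 0; c < nc; ++c) {
            const int s = state[c], a = assign[c];
            const bool defect = (s != 0);
            if (defect) {
              if (a >= 9 && a <= 12) ++k.d912;
              else ++k.other_t;
              if (a == 1 || a >= 13) ++k.other_d;
            }
            if ((s == 1 || s == 2) && a >= 2 && a <= 8) k.p28 = 0;
            if (s == 3 && a >= 1 && a <= 8) k.p28 = 0;
            if (s == 1) { ++run; if (run > k.run) k.run = run; }
            else run = 0;
          }
          // ---- route B: clause checks straight from the placement ----
          int central = 0, othT = 0, othD = 0;
          bool perfect28 = true, doubleMM = false;
          for (int c = 0; c < d; ++c) {
            const int p = pos[c], t = typ[c];
            if (p >= 9 && p <= 12) ++central; else ++othT;
            if (p == 1 || p >= 13) ++othD;
            if (t == MM || t == BM) { if (p >= 2 && p <= 8) perfect28 = false; }
            if (t == BT && p <= 8) perfect28 = false;
            if (t == MM) {
              for (int c2 = 0; c2 < d; ++c2)
                if (typ[c2] == MM && pos[c2] == p + 1) doubleMM = true;
            }
          }
          bool tgt = (central <= 1) && (othT <= 4) && !doubleMM;
          bool dcy = (central >= 2) && (central <= 5) && perfect28 && (othD <= 4);
          k.tgt = tgt ? 1 : 0;
          k.dcy = dcy ? 1 : 0;
          acc[pack(k)] += 1.0;
        }
        // next type vector (base 3 odometer)
        more_typ = false;
        for (int c = 0; c < d; ++c) {
          if (++typ[c] < 3) { more_typ = true; break; }
          typ[c] = 0;
        }
      }
      // next combination
      more_comb = false;
      for (int c = d - 1; c >= 0; --c) {
        if (pos[c] < L - (d - 1 - c)) {
          ++pos[c];
          for (int c2 = c + 1; c2 < d; ++c2) pos[c2] = pos[c2 - 1] + 1;
          more_comb = true;
          break;
        }
      }
      if (d == 0) break;
    }
  }

  const int nrow = (int) acc.size();
  IntegerVector d912(nrow), other_t(nrow), other_d(nrow), run(nrow);
  LogicalVector p28(nrow), otgt(nrow), odcy(nrow);
  NumericVector count(nrow);
  int r = 0;
  for (auto& kv : acc) {
    const int key = kv.first;
    d912[r] = key & 15;
    p28[r] = (key >> 4) & 1;
    other_t[r] = (key >> 5) & 15;
    other_d[r] = (key >> 9) & 15;
    run[r] = (key >> 13) & 15;
    otgt[r] = (key >> 17) & 1;
    odcy[r] = (key >> 18) & 1;
    count[r] = kv.second;
    ++r;
  }
  return DataFrame::create(
    _["defects_9_12"] = d912, _["perfect_2_8"] = p28,
    _["defects_other_target"] = other_t, _["defects_other_decoy"] = other_d,
    _["max_mismatch_run"] = run,
    _["oracle_target"] = otgt, _["oracle_decoy"] = odcy,
    _["count"] = count);
}
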