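#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh). A gap of length
// k costs gap_open + k * gap_extend. N is treated as matching nothing
// (always a mismatch). Tie-breaking is deterministic: the best cell is the
// first maximal cell in row-major order (query index outer), and the
// traceback prefers diagonal over up (gap in target) over left (gap in
// query).
// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string query, std::string target,
                  int match, int mismatch, int gap_open, int gap_extend) {
  const int m = (int)query.size(), n = (int)target.size();
  const int oe = gap_open + gap_extend, ge = gap_extend;
  const int NEG = -1000000000;
  // (m+1) x (n+1) DP matrices, row-major
  std::vector<int> H((size_t)(m + 1) * (n + 1), 0);
  std::vector<int> E((size_t)(m + 1) * (n + 1), NEG);
  std::vector<int> F((size_t)(m + 1) * (n + 1), NEG);
  auto at = [n](int i, int j) { return (size_t)i * (n + 1) + j; };
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      char a = query[i - 1], b = target[j - 1];
      int s = (a == b && a != 'N') ? match : mismatch;
      int e = std::max(H[at(i, j - 1)] - oe, E[at(i, j - 1)] - ge);
      int f = std::max(H[at(i - 1, j)] - oe, F[at(i - 1, j)] - ge);
      int h = H[at(i - 1, j - 1)] + s;
      h = std::max(std::max(h, 0), std::max(e, f));
      E[at(i, j)] = e;
      F[at(i, j)] = f;
      H[at(i, j)] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0) {
    return List::create(_["score"] = 0, _["matches"] = 0, _["columns"] = 0,
                        _["query_start"] = NA_INTEGER,
                        _["query_end"] = NA_INTEGER,
                        _["target_start"] = NA_INTEGER,
                        _["target_end"] = NA_INTEGER);
  }
  // traceback
  int i = bi, j = bj, matches = 0, columns = 0;
  int state = 0;  // 0 = H, 1 = F (up), 2 = E (left)
  while (true) {
    if (state == 0) {
      if (H[at(i, j)] == 0) break;
      char a = query[i - 1], b = target[j - 1];
      int s = (a == b && a != 'N') ? match : mismatch;
      if (i > 0 && j > 0 && H[at(i, j)] == H[at(i - 1, j - 1)] + s) {
        if (a == b && a != 'N') ++matches;
        ++columns; --i; --j;
      } else if (H[at(i, j)] == F[at(i, j)]) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      // gap in target: consume query base
      ++columns;
      if (F[at(i, j)] == H[at(i - 1, j)] - oe) { --i; state = 0; }
      else { --i; }
    } else {
      // gap in query: consume target base
      ++columns;
      if (E[at(i, j)] == H[at(i, j - 1)] - oe) { --j; state = 0; }
      else { --j; }
    }
  }
  return List::create(_["score"] = best, _["matches"] = matches,
                      _["columns"] = columns,
                      _["query_start"] = i, _["query_end"] = bi,
                      _["target_start"] = j, _["target_end"] = bj);
}

// Exhaustive ungapped offset scan between r1 and the reverse complement of
// r2 (passed pre-complemented). Offset s places rc2[0] at r1 coordinate s;
// the implied insert size is s + len(r2). Positions where either base is
// 'N' count as mismatches. Among qualifying offsets (overlap >= min_overlap
// and mismatches <= max_error * overlap) the one with the most matches
// wins; ties go to the smallest insert size.
// [[Rcpp::export(name = ".overlap_scan_cpp")]]
IntegerVector overlap_scan_cpp(std::string r1, std::string rc2,
                               int min_overlap, double max_error) {
  const int n1 = (int)r1.size(), n2 = (int)rc2.size();
  int best_matches = -1, best_insert = NA_INTEGER, best_ov = 0, best_mm = 0;
  bool found = false;
  for (int s = min_overlap - n2; s <= n1 - min_overlap; ++s) {
    int a0 = std::max(0, s), a1 = std::min(n1, s + n2);
    int ov = a1 - a0;
    if (ov < min_overlap) continue;
    int mm = 0;
    int allowed = (int)(max_error * ov);
    for (int i = a0; i < a1; ++i) {
      char a = r1[i], b = rc2[i - s];
      if (a != b || a == 'N') {
        if (++mm > allowed) break;
      }
    }
    if (mm > allowed) continue;
    int matchcount = ov - mm;
    if (matchcount > best_matches) {  // strict: ties keep smaller insert
      best_matches = matchcount;
      best_insert = s + n2;
      best_ov = ov;
      best_mm = mm;
      found = true;
    }
  }
  return IntegerVector::create(found ? 1 : 0, best_insert, best_ov, best_mm,
                               best_matches < 0 ? 0 : best_matches);
}
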