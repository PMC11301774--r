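// Mass-based local alignment: Smith-Waterman extended with multi-residue
// rotation and isobaric steps (up to N residues on either side), affine
// gaps, and deterministic tie-breaking.
//
// Sequences arrive as 0-based integer codes into the scoring matrix; the
// code `wildcard_code` marks the template wildcard X. Step scores follow
// the printed constants: rotations score 3 per residue involved, isobaric
// matches 2 per the maximum number of residues involved, both strictly
// below any direct match on the BLOSUM62-style base matrix.

#include <Rcpp.h>
#include <algorithm>
#include <cstring>
using namespace Rcpp;

namespace {

// step kinds, in tie-break preference order (lower = preferred)
enum Kind { MATCH = 0, ROTATION = 1, ISOBARIC = 2, MISMATCH = 3,
            GAP_READ = 4, GAP_TEMPLATE = 5, NONE = 9 };

const int NEG_INF = -100000000;

struct Cell {
  int m, x, y;            // Gotoh layers: set-step / gap-in-read / gap-in-template
  int la, lb;             // chosen step lengths (template, read) for layer m
  signed char kind;       // step kind for layer m
  signed char prev;       // predecessor layer for m: 0=M,1=X,2=Y,3=fresh start
  int step_score;
  signed char x_from_m, y_from_m; // gap layer provenance
};

struct StepCandidate {
  int score;
  signed char kind;
  int la, lb;
};

inline bool better(const StepCandidate& a, const StepCandidate& b) {
  // strict improvement ordering: score, then kind preference, then
  // shorter total step length
  if (a.score != b.score) return a.score > b.score;
  if (a.kind != b.kind) return a.kind < b.kind;
  return (a.la + a.lb) < (b.la + b.lb);
}

} // namespace

// [[Rcpp::export]]
List mba_align_cpp(IntegerVector tmpl, IntegerVector read,
                   IntegerMatrix base, NumericVector masses,
                   int max_set_len, double iso_tol, int wildcard_score,
                   int gap_open, int gap_extend, int wildcard_code,
                   int rotation_per_res, int isobaric_per_res) {
  const int n = tmpl.size(), m = read.size();
  const int N = max_set_len;
  if (n == 0 || m == 0) stop("sequences must be non-empty");

  // prefix masses for O(1) substring masses; wildcard positions poison the
  // substring (NaN) so X never joins a rotation/isobaric set
  std::vector<double> ptm(n + 1, 0.0), prm(m + 1, 0.0);
  std::vector<bool> tX(n + 1, false), rX(m + 1, false);
  for (int i = 0; i < n; ++i) {
    ptm[i + 1] = ptm[i] + (tmpl[i] == wildcard_code ? 0.0 : masses[tmpl[i]]);
    tX[i + 1] = tX[i] || (tmpl[i] == wildcard_code);
  }
  for (int j = 0; j < m; ++j) {
    prm[j + 1] = prm[j] + (read[j] == wildcard_code ? 0.0 : masses[read[j]]);
    rX[j + 1] = rX[j] || (read[j] == wildcard_code);
  }

  std::vector<Cell> dp((n + 1) * (m + 1));
  auto at = [&](int i, int j) -> Cell& { return dp[i * (m + 1) + j]; };
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) {
      Cell& c = at(i, j);
      c.m = 0; c.x = NEG_INF; c.y = NEG_INF;
      c.kind = NONE; c.prev = 3; c.la = c.lb = 0; c.step_score = 0;
      c.x_from_m = 1; c.y_from_m = 1;
    }

  int best = 0, bi = 0, bj = 0;
  std::vector<signed char> sortbufA(N), sortbufB(N);

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      Cell& c = at(i, j);

      // gap layers (affine: opening a gap of length L costs open + L*ext)
      {
        const Cell& up = at(i - 1, j);
        int from_m = up.m + gap_open + gap_extend;
        int from_x = up.x + gap_extend;
        if (from_m >= from_x) { c.x = from_m; c.x_from_m = 1; }
        else { c.x = from_x; c.x_from_m = 0; }
        const Cell& left = at(i, j - 1);
        int fm = left.m + gap_open + gap_extend;
        int fy = left.y + gap_extend;
        if (fm >= fy) { c.y = fm; c.y_from_m = 1; }
        else { c.y = fy; c.y_from_m = 0; }
      }

      // set steps of (la residues on template) x (lb residues on read)
      StepCandidate chosen = {NEG_INF, NONE, 0, 0};
      signed char chosen_prev = 3;
      int chosen_pred = NEG_INF;

      for (int tot = 2; tot <= 2 * N; ++tot) {
        for (int la = std::max(1, tot - N); la <= std::min(N, tot - 1); ++la) {
          int lb = tot - la;
          if (la > i || lb > j) continue;

          // candidate step score(s) for this (la, lb)
          StepCandidate cand = {NEG_INF, NONE, la, lb};
          const int a0 = i - la, b0 = j - lb;

          if (la == 1 && lb == 1) {
            int a = tmpl[i - 1], b = read[j - 1];
            if (a == wildcard_code || b == wildcard_code) {
              cand.score = wildcard_score; cand.kind = MATCH;
            } else {
              cand.score = base(a, b);
              cand.kind = (a == b) ? MATCH : MISMATCH;
              if (a != b && std::abs(masses[a] - masses[b]) <= iso_tol) {
                StepCandidate iso = {isobaric_per_res, ISOBARIC, 1, 1};
                if (better(iso, cand)) cand = iso;
              }
            }
          } else {
            // multi-residue steps: no wildcards inside the window
            bool hasX = (tX[i] != tX[a0]) || (rX[j] != rX[b0]);
            if (hasX) continue;
            double dm = std::abs((ptm[i] - ptm[a0]) - (prm[j] - prm[b0]));
            if (dm > iso_tol) continue;
            bool same_multiset = false, identical = false;
            if (la == lb) {
              identical = true;
              for (int k = 0; k < la; ++k) {
                sortbufA[k] = (signed char)tmpl[a0 + k];
                sortbufB[k] = (signed char)read[b0 + k];
                if (sortbufA[k] != sortbufB[k]) identical = false;
              }
              std::sort(sortbufA.begin(), sortbufA.begin() + la);
              std::sort(sortbufB.begin(), sortbufB.begin() + la);
              same_multiset =
                std::equal(sortbufA.begin(), sortbufA.begin() + la,
                           sortbufB.begin());
            }
            if (identical) continue;       // plain matches cover this
            if (same_multiset) {
              cand.score = rotation_per_res * la; cand.kind = ROTATION;
            } else {
              cand.score = isobaric_per_res * std::max(la, lb);
              cand.kind = ISOBARIC;
            }
          }
          if (cand.kind == NONE) continue;

          // best predecessor at (a0, b0): continue from M/X/Y or start fresh
          const Cell& p = at(a0, b0);
          int pred = p.m; signed char pk = 0;
          if (p.x > pred) { pred = p.x; pk = 1; }
          if (p.y > pred) { pred = p.y; pk = 2; }
          if (pred < 0) { pred = 0; pk = 3; }
          StepCandidate total = cand;
          total.score = cand.score + pred;
          StepCandidate cur = chosen;
          cur.score = chosen_pred == NEG_INF ? NEG_INF
                                             : chosen.score + chosen_pred;
          if (chosen.kind == NONE || better(total, cur)) {
            chosen = cand; chosen_prev = pk; chosen_pred = pred;
          }
        }
      }

      int mval = (chosen.kind == NONE) ? 0 : chosen.score + chosen_pred;
      if (mval <= 0) {               // local alignment: floor at zero
        c.m = 0; c.kind = NONE; c.prev = 3; c.la = c.lb = 0; c.step_score = 0;
      } else {
        c.m = mval; c.kind = chosen.kind; c.prev = chosen_prev;
        c.la = chosen.la; c.lb = chosen.lb; c.step_score = chosen.score;
      }
      if (c.m > best) { best = c.m; bi = i; bj = j; }
    }
  }

  // traceback from the best-scoring cell (first maximum in row-major order)
  std::vector<int> k_kind, k_la, k_lb, k_sc;
  int i = bi, j = bj, layer = 0;
  while (i > 0 || j > 0) {
    Cell& c = at(i, j);
    if (layer == 0) {
      if (c.kind == NONE) break;
      k_kind.push_back(c.kind); k_la.push_back(c.la);
      k_lb.push_back(c.lb); k_sc.push_back(c.step_score);
      int pi = i - c.la, pj = j - c.lb;
      int pl = c.prev;
      i = pi; j = pj;
      if (pl == 3) break;
      layer = pl;
    } else if (layer == 1) {        // gap in read (template consumed)
      k_kind.push_back(GAP_READ); k_la.push_back(1); k_lb.push_back(0);
      int sc = c.x_from_m ? gap_open + gap_extend : gap_extend;
      k_sc.push_back(sc);
      layer = c.x_from_m ? 0 : 1;
      i -= 1;
    } else {                        // gap in template (read consumed)
      k_kind.push_back(GAP_TEMPLATE); k_la.push_back(0); k_lb.push_back(1);
      int sc = c.y_from_m ? gap_open + gap_extend : gap_extend;
      k_sc.push_back(sc);
      layer = c.y_from_m ? 0 : 2;
      j -= 1;
    }
  }
  std::reverse(k_kind.begin(), k_kind.end());
  std::reverse(k_la.begin(), k_la.end());
  std::reverse(k_lb.begin(), k_lb.end());
  std::reverse(k_sc.begin(), k_sc.end());

  return List::create(
    _["score"] = best,
    _["template_start"] = i, _["template_end"] = bi,
    _["read_start"] = j, _["read_end"] = bj,
    _["kind"] = IntegerVector(k_kind.begin(), k_kind.end()),
    _["len_template"] = IntegerVector(k_la.begin(), k_la.end()),
    _["len_read"] = IntegerVector(k_lb.begin(), k_lb.end()),
    _["step_score"] = IntegerVector(k_sc.begin(), k_sc.end()));
}
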