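// Affine-gap pairwise alignment (Gotoh) for protein sequences, plus
// exhaustive path-enumeration oracles used only by the test suite.
//
// Sequences arrive as 0-based integer index vectors into a square score
// matrix; residue-to-index mapping and input validation happen in R.
// A gap run of length k costs gap_open + k * gap_extend.
// Alignments are reported as op strings over {D, I, J}: D = aligned pair,
// I = gap in target (consumes query), J = gap in query (consumes target).

#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <climits>
using namespace Rcpp;

static const int NEG = INT_MIN / 4;
typedef std::vector<std::vector<int> > Mat;

struct Trace {
  int q_start, t_start, q_end, t_end, length, matches;
  std::string ops;
  Trace() : q_start(0), t_start(0), q_end(0), t_end(0), length(0), matches(0) {}
};

// Deterministic traceback of a local alignment ending at (ei, ej) in M.
// When predecessors tie, preference is M, then Ix, then Iy, then a fresh
// start; a fresh start is preferred over a zero-scoring continuation so the
// reported alignment is as short as possible.
static Trace traceback_local(const IntegerVector &q, const IntegerVector &t,
                             const IntegerMatrix &S, int open, int ext,
                             const Mat &M, const Mat &Ix, const Mat &Iy,
                             int ei, int ej) {
  int i = ei, j = ej, state = 0;
  std::string ops;
  int matches = 0;
  while (true) {
    if (state == 0) {
      ops.push_back('D');
      if (q[i - 1] == t[j - 1]) matches++;
      int prev = M[i][j] - S(q[i - 1], t[j - 1]);
      if (prev > 0 && M[i - 1][j - 1] == prev) { i--; j--; state = 0; continue; }
      if (prev > NEG / 2 && prev > 0 && Ix[i - 1][j - 1] == prev) { i--; j--; state = 1; continue; }
      if (prev > NEG / 2 && prev > 0 && Iy[i - 1][j - 1] == prev) { i--; j--; state = 2; continue; }
      i--; j--;
      break; // fresh start: prev == 0
    } else if (state == 1) { // gap in target, consumes q[i-1]
      ops.push_back('I');
      int cur = Ix[i][j];
      if (i <= 1) break; // defensive: should not occur on an optimal path
      if (M[i - 1][j] - (open + ext) == cur) { i--; state = 0; continue; }
      if (Ix[i - 1][j] - ext == cur) { i--; state = 1; continue; }
      i--; state = 2; continue;
    } else { // gap in query, consumes t[j-1]
      ops.push_back('J');
      int cur = Iy[i][j];
      if (j <= 1) break;
      if (M[i][j - 1] - (open + ext) == cur) { j--; state = 0; continue; }
      if (Iy[i][j - 1] - ext == cur) { j--; state = 2; continue; }
      j--; state = 1; continue;
    }
  }
  Trace tr;
  tr.q_start = i; tr.t_start = j; tr.q_end = ei; tr.t_end = ej;
  std::reverse(ops.begin(), ops.end());
  tr.ops = ops;
  tr.matches = matches;
  tr.length = (int)ops.size();
  return tr;
}

// [[Rcpp::export]]
List cpp_local_align(IntegerVector q, IntegerVector t, IntegerMatrix S,
                     int gap_open, int gap_extend) {
  int m = q.size(), n = t.size();
  Mat M(m + 1, std::vector<int>(n + 1, 0));
  Mat Ix(m + 1, std::vector<int>(n + 1, NEG));
  Mat Iy(m + 1, std::vector<int>(n + 1, NEG));
  int best = 0;
  for (int i = 1; i <= m; i++) {
    for (int j = 1; j <= n; j++) {
      int diag = std::max(0, std::max(M[i - 1][j - 1],
                 std::max(Ix[i - 1][j - 1], Iy[i - 1][j - 1])));
      M[i][j] = diag + S(q[i - 1], t[j - 1]);
      int a = std::max(M[i - 1][j] - (gap_open + gap_extend),
              std::max(Ix[i - 1][j] - gap_extend,
                       Iy[i - 1][j] - (gap_open + gap_extend)));
      Ix[i][j] = (a <= NEG / 2) ? NEG : a;
      int b = std::max(M[i][j - 1] - (gap_open + gap_extend),
              std::max(Iy[i][j - 1] - gap_extend,
                       Ix[i][j - 1] - (gap_open + gap_extend)));
      Iy[i][j] = (b <= NEG / 2) ? NEG : b;
      if (M[i][j] > best) best = M[i][j];
    }
  }
  if (best <= 0)
    return List::create(_["score"] = 0, _["q_start"] = 0, _["q_end"] = 0,
                        _["t_start"] = 0, _["t_end"] = 0, _["ops"] = "",
                        _["matches"] = 0, _["columns"] = 0);
  // ties among max-score endpoints: earliest target start, then earliest
  // query start, then shortest alignment
  bool have = false;
  Trace chosen;
  for (int i = 1; i <= m; i++)
    for (int j = 1; j <= n; j++)
      if (M[i][j] == best) {
        Trace tr = traceback_local(q, t, S, gap_open, gap_extend, M, Ix, Iy, i, j);
        if (!have ||
            tr.t_start < chosen.t_start ||
            (tr.t_start == chosen.t_start && tr.q_start < chosen.q_start) ||
            (tr.t_start == chosen.t_start && tr.q_start == chosen.q_start &&
             tr.length < chosen.length)) {
          chosen = tr;
          have = true;
        }
      }
  return List::create(_["score"] = best,
                      _["q_start"] = chosen.q_start, _["q_end"] = chosen.q_end,
                      _["t_start"] = chosen.t_start, _["t_end"] = chosen.t_end,
                      _["ops"] = chosen.ops,
                      _["matches"] = chosen.matches,
                      _["columns"] = chosen.length);
}

// [[Rcpp::export]]
List cpp_global_align(IntegerVector q, IntegerVector t, IntegerMatrix S,
                      int gap_open, int gap_extend) {
  int m = q.size(), n = t.size();
  Mat M(m + 1, std::vector<int>(n + 1, NEG));
  Mat Ix(m + 1, std::vector<int>(n + 1, NEG));
  Mat Iy(m + 1, std::vector<int>(n + 1, NEG));
  M[0][0] = 0;
  for (int i = 1; i <= m; i++) Ix[i][0] = -(gap_open + i * gap_extend);
  for (int j = 1; j <= n; j++) Iy[0][j] = -(gap_open + j * gap_extend);
  for (int i = 1; i <= m; i++) {
    for (int j = 1; j <= n; j++) {
      int diag = std::max(M[i - 1][j - 1],
                 std::max(Ix[i - 1][j - 1], Iy[i - 1][j - 1]));
      M[i][j] = (diag <= NEG / 2) ? NEG : diag + S(q[i - 1], t[j - 1]);
      int a = std::max(M[i - 1][j] - (gap_open + gap_extend),
              std::max(Ix[i - 1][j] - gap_extend,
                       Iy[i - 1][j] - (gap_open + gap_extend)));
      Ix[i][j] = (a <= NEG / 2) ? NEG : a;
      int b = std::max(M[i][j - 1] - (gap_open + gap_extend),
              std::max(Iy[i][j - 1] - gap_extend,
                       Ix[i][j - 1] - (gap_open + gap_extend)));
      Iy[i][j] = (b <= NEG / 2) ? NEG : b;
    }
  }
  int score = std::max(M[m][n], std::max(Ix[m][n], Iy[m][n]));
  int i = m, j = n, state;
  if (M[m][n] == score) state = 0;
  else if (Ix[m][n] == score) state = 1;
  else state = 2;
  std::string ops;
  int matches = 0;
  while (i > 0 || j > 0) {
    if (state == 0) {
      ops.push_back('D');
      if (q[i - 1] == t[j - 1]) matches++;
      int prev = M[i][j] - S(q[i - 1], t[j - 1]);
      i--; j--;
      if (i == 0 && j == 0) break;
      if (M[i][j] == prev) state = 0;
      else if (Ix[i][j] == prev) state = 1;
      else state = 2;
    } else if (state == 1) {
      ops.push_back('I');
      int cur = Ix[i][j];
      int pm = (i >= 1) ? M[i - 1][j] : NEG;
      int px = (i >= 1) ? Ix[i - 1][j] : NEG;
      int py = (i >= 1) ? Iy[i - 1][j] : NEG;
      i--;
      if (i == 0 && j == 0) break;
      if (pm - (gap_open + gap_extend) == cur && pm > NEG / 2) state = 0;
      else if (px - gap_extend == cur && px > NEG / 2) state = 1;
      else if (py - (gap_open + gap_extend) == cur && py > NEG / 2) state = 2;
      else state = 1;
    } else {
      ops.push_back('J');
      int cur = Iy[i][j];
      int pm = (j >= 1) ? M[i][j - 1] : NEG;
      int py = (j >= 1) ? Iy[i][j - 1] : NEG;
      int px = (j >= 1) ? Ix[i][j - 1] : NEG;
      j--;
      if (i == 0 && j == 0) break;
      if (pm - (gap_open + gap_extend) == cur && pm > NEG / 2) state = 0;
      else if (py - gap_extend == cur && py > NEG / 2) state = 2;
      else if (px - (gap_open + gap_extend) == cur && px > NEG / 2) state = 1;
      else state = 2;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = score, _["ops"] = ops,
                      _["matches"] = matches, _["columns"] = (int)ops.size());
}

// ---- exhaustive enumeration oracles (test-only; exponential, tiny inputs) ----

static long long g_best;

static void enum_local_rec(const IntegerVector &q, const IntegerVector &t,
                           const IntegerMatrix &S, int open, int ext,
                           int i, int j, int last, long long sc) {
  // i, j: number of residues consumed so far; last: 0 diag, 1 gap-in-t, 2 gap-in-q
  if (last == 0 && sc > g_best) g_best = sc;
  int m = q.size(), n = t.size();
  if (i < m && j < n)
    enum_local_rec(q, t, S, open, ext, i + 1, j + 1, 0, sc + S(q[i], t[j]));
  if (i < m)
    enum_local_rec(q, t, S, open, ext, i + 1, j, 1,
                   sc - (last == 1 ? ext : open + ext));
  if (j < n)
    enum_local_rec(q, t, S, open, ext, i, j + 1, 2,
                   sc - (last == 2 ? ext : open + ext));
}

// [[Rcpp::export]]
double cpp_enum_local_score(IntegerVector q, IntegerVector t, IntegerMatrix S,
                            int gap_open, int gap_extend) {
  g_best = 0; // empty alignment scores 0
  int m = q.size(), n = t.size();
  for (int i = 0; i < m; i++)
    for (int j = 0; j < n; j++)
      enum_local_rec(q, t, S, gap_open, gap_extend, i + 1, j + 1, 0,
                     S(q[i], t[j]));
  return (double)g_best;
}

static void enum_global_rec(const IntegerVector &q, const IntegerVector &t,
                            const IntegerMatrix &S, int open, int ext,
                            int i, int j, int last, long long sc) {
  int m = q.size(), n = t.size();
  if (i == m && j == n) {
    if (sc > g_best) g_best = sc;
    return;
  }
  if (i < m && j < n)
    enum_global_rec(q, t, S, open, ext, i + 1, j + 1, 0, sc + S(q[i], t[j]));
  if (i < m)
    enum_global_rec(q, t, S, open, ext, i + 1, j, 1,
                    sc - (last == 1 ? ext : open + ext));
  if (j < n)
    enum_global_rec(q, t, S, open, ext, i, j + 1, 2,
                    sc - (last == 2 ? ext : open + ext));
}

// [[Rcpp::export]]
double cpp_enum_global_score(IntegerVector q, IntegerVector t, IntegerMatrix S,
                             int gap_open, int gap_extend) {
  g_best = LLONG_MIN / 4;
  enum_global_rec(q, t, S, gap_open, gap_extend, 0, 0, -1, 0);
  return (double)g_best;
}
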