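#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>
using namespace Rcpp;

// Semi-global similarity scan of a satDNA monomer against a chromosome.
//
// Alignment model shared by the whole package: the query (monomer) is
// aligned end to end, the subject (chromosome) contributes a free-standing
// window. Scoring: match +1, mismatch -1, gap of length k costs
// gap_open + k * gap_ext (Biostrings gapOpening/gapExtension convention).
// Identity = 100 * matches / alignment columns; gap columns count against
// identity. N never matches; substitution columns that involve an N are
// kept out of the transition/transversion tallies (K2P is defined over
// unambiguous substitutions only).

static const long NEG = LONG_MIN / 4;

struct Cell {
  long score;
  int start;    // 0-based subject offset of the first consumed subject base
  int match;    // match columns
  int ts;       // transition columns
  int tv;       // transversion columns
  int ncol;     // substitution columns involving N (excluded from ts/tv)
  int cols;     // total alignment columns
};

static inline bool is_transition(char a, char b) {
  return (a == 'A' && b == 'G') || (a == 'G' && b == 'A') ||
         (a == 'C' && b == 'T') || (a == 'T' && b == 'C');
}

// Deterministic preference when scores tie: more matches, then fewer
// columns (shorter alignment), then larger start (leftmost end for equal
// spans, resolved later in R).
static inline bool better(const Cell &a, const Cell &b) {
  if (a.score != b.score) return a.score > b.score;
  if (a.match != b.match) return a.match > b.match;
  if (a.cols  != b.cols)  return a.cols  < b.cols;
  return a.start > b.start;
}

static inline Cell take_best(const Cell &a, const Cell &b) {
  return better(a, b) ? a : b;
}

static inline bool valid(const Cell &c) { return c.score > NEG / 2; }

static inline Cell extend_diag(const Cell &from, char q, char s, int start_if_origin) {
  Cell c = from;
  if (!valid(c)) return c;
  if (c.cols == 0) c.start = start_if_origin;
  bool m = (q == s) && q != 'N';
  c.score += m ? 1 : -1;
  if (m) c.match++;
  else if (q == 'N' || s == 'N') c.ncol++;
  else if (is_transition(q, s)) c.ts++;
  else c.tv++;
  c.cols++;
  return c;
}

static inline Cell extend_gap(const Cell &from, bool opening, int go, int ge,
                              int start_if_origin) {
  Cell c = from;
  if (!valid(c)) return c;
  if (c.cols == 0) c.start = start_if_origin;
  c.score -= opening ? (go + ge) : ge;
  c.cols++;
  return c;
}

static DataFrame make_result(std::vector<int> &start_v, std::vector<int> &end_v,
                             std::vector<double> &score_v, std::vector<int> &match_v,
                             std::vector<int> &ts_v, std::vector<int> &tv_v,
                             std::vector<int> &gap_v, std::vector<int> &cols_v,
                             std::vector<double> &ident_v) {
  return DataFrame::create(
      _["start"] = start_v, _["end"] = end_v, _["score"] = score_v,
      _["matches"] = match_v, _["transitions"] = ts_v,
      _["transversions"] = tv_v, _["indel_columns"] = gap_v,
      _["columns"] = cols_v, _["identity"] = ident_v);
}

// Fast scan: single pass over the subject, O(m * n) time and O(m) memory.
// For every subject end position the best full-query semi-global alignment
// ending there is tracked; ends whose identity reaches min_identity are
// emitted as candidate hits (overlap resolution happens in R).
// [[Rcpp::export]]
DataFrame scan_semiglobal_cpp(std::string query, std::string subject,
                              double min_identity,
                              int gap_open = 2, int gap_ext = 1) {
  const int m = (int)query.size(), n = (int)subject.size();
  if (m == 0) stop("empty query");
  std::vector<int> start_v, end_v, match_v, ts_v, tv_v, gap_v, cols_v;
  std::vector<double> score_v, ident_v;
  if (n == 0)
    return make_result(start_v, end_v, score_v, match_v, ts_v, tv_v, gap_v,
                       cols_v, ident_v);

  const Cell none = {NEG, 0, 0, 0, 0, 0, 0};
  // D: query i aligned to subject j; U: query char against a subject gap
  // (no subject consumed); L: subject char against a query gap. States are
  // indexed by query row i and rolled over subject position j.
  std::vector<Cell> D(m + 1, none), U(m + 1, none), L(m + 1, none);
  std::vector<Cell> Dp(m + 1, none), Up(m + 1, none), Lp(m + 1, none);

  // j = 0 boundary: pure leading-deletion prefixes (query chars against
  // gaps before any subject base is consumed; first consumed base will be
  // subject offset 0).
  for (int i = 1; i <= m; ++i) {
    Cell origin0 = {0, 0, 0, 0, 0, 0, 0};
    Up[i] = extend_gap(i == 1 ? origin0 : Up[i - 1], i == 1, gap_open, gap_ext, 0);
  }

  for (int j = 1; j <= n; ++j) {
    const char sj = subject[j - 1];
    Cell origin_d = {0, 0, 0, 0, 0, 0, 0};  // fresh start consuming s_j
    Cell origin_u = {0, 0, 0, 0, 0, 0, 0};  // fresh deletion prefix after s_j
    for (int i = 1; i <= m; ++i) {
      const char qi = query[i - 1];
      Cell h = (i == 1) ? origin_d
                        : take_best(Dp[i - 1], take_best(Up[i - 1], Lp[i - 1]));
      D[i] = extend_diag(h, qi, sj, j - 1);
      U[i] = take_best(
          extend_gap(i == 1 ? origin_u : D[i - 1], true, gap_open, gap_ext, j),
          take_best(
              extend_gap(i == 1 ? none : L[i - 1], true, gap_open, gap_ext, j),
              extend_gap(i == 1 ? none : U[i - 1], false, gap_open, gap_ext, j)));
      L[i] = take_best(
          extend_gap(Dp[i], true, gap_open, gap_ext, j - 1),
          take_best(extend_gap(Up[i], true, gap_open, gap_ext, j - 1),
                    extend_gap(Lp[i], false, gap_open, gap_ext, j - 1)));
    }
    // Trailing query-against-gap moves (U) do not consume s_j, but any
    // valid U chain at row m either descends from a D/L in this column
    // (subject consumed through j) or is a pure-deletion prefix with zero
    // matches, which the identity filter removes.
    Cell best = take_best(D[m], take_best(U[m], L[m]));
    if (valid(best) && best.match > 0) {
      double ident = 100.0 * best.match / best.cols;
      if (ident >= min_identity) {
        int nd = best.match + best.ts + best.tv + best.ncol;  // #diagonal cols
        start_v.push_back(best.start);
        end_v.push_back(best.start + nd + (best.cols - m));   // + #query-gap cols
        score_v.push_back((double)best.score);
        match_v.push_back(best.match);
        ts_v.push_back(best.ts);
        tv_v.push_back(best.tv);
        gap_v.push_back(best.cols - nd);
        cols_v.push_back(best.cols);
        ident_v.push_back(ident);
      }
    }
    std::swap(D, Dp); std::swap(U, Up); std::swap(L, Lp);
  }
  return make_result(start_v, end_v, score_v, match_v, ts_v, tv_v, gap_v,
                     cols_v, ident_v);
}

// Reference scan: brute force over every subject start offset. For each
// offset the query is aligned semi-globally (full query, subject window
// anchored at the offset, free right end) by a plain quadratic DP over a
// window of m + m/2 + 8 subject characters. Used as an independent oracle
// in tests; it shares the scoring definition but not the traversal.
// [[Rcpp::export]]
DataFrame scan_reference_cpp(std::string query, std::string subject,
                             double min_identity,
                             int gap_open = 2, int gap_ext = 1) {
  const int m = (int)query.size(), n = (int)subject.size();
  if (m == 0) stop("empty query");
  const int w_max = m + m / 2 + 8;
  std::vector<int> start_v, end_v, match_v, ts_v, tv_v, gap_v, cols_v;
  std::vector<double> score_v, ident_v;
  const Cell none = {NEG, 0, 0, 0, 0, 0, 0};

  std::vector<std::vector<Cell> > D(m + 1), U(m + 1), L(m + 1);
  for (int i = 0; i <= m; ++i) {
    D[i].assign(w_max + 1, none);
    U[i].assign(w_max + 1, none);
    L[i].assign(w_max + 1, none);
  }

  for (int s = 0; s < n; ++s) {
    const int w = std::min(w_max, n - s);
    Cell origin = {0, s, 0, 0, 0, 0, 0};
    for (int j = 0; j <= w; ++j) { D[0][j] = U[0][j] = L[0][j] = none; }
    for (int i = 1; i <= m; ++i) {
      D[i][0] = L[i][0] = none;
      U[i][0] = extend_gap(i == 1 ? origin : U[i - 1][0], i == 1,
                           gap_open, gap_ext, s);
    }
    for (int i = 1; i <= m; ++i) {
      const char qi = query[i - 1];
      for (int j = 1; j <= w; ++j) {
        const char sj = subject[s + j - 1];
        Cell h;
        if (i == 1 && j == 1) h = origin;
        else h = take_best(D[i - 1][j - 1],
                           take_best(U[i - 1][j - 1], L[i - 1][j - 1]));
        D[i][j] = extend_diag(h, qi, sj, s);
        U[i][j] = take_best(
            extend_gap(i == 1 ? none : D[i - 1][j], true, gap_open, gap_ext, s),
            take_best(
                extend_gap(i == 1 ? none : L[i - 1][j], true, gap_open, gap_ext, s),
                extend_gap(i == 1 ? none : U[i - 1][j], false, gap_open, gap_ext, s)));
        L[i][j] = take_best(
            extend_gap(D[i][j - 1], true, gap_open, gap_ext, s),
            take_best(extend_gap(U[i][j - 1], true, gap_open, gap_ext, s),
                      extend_gap(L[i][j - 1], false, gap_open, gap_ext, s)));
      }
    }
    // every end position whose best full-query alignment anchored at this
    // offset clears the identity threshold is a candidate
    for (int j = 1; j <= w; ++j) {
      Cell best = take_best(D[m][j], take_best(U[m][j], L[m][j]));
      if (!valid(best) || best.match == 0 || best.start != s) continue;
      double ident = 100.0 * best.match / best.cols;
      if (ident < min_identity) continue;
      // #diagonal cols = match+ts+tv+ncol; #query-gap cols = cols - m;
      // subject bp consumed = #diagonal + #query-gap.
      int nd = best.match + best.ts + best.tv + best.ncol;
      start_v.push_back(s);
      end_v.push_back(s + nd + (best.cols - m));
      score_v.push_back((double)best.score);
      match_v.push_back(best.match);
      ts_v.push_back(best.ts);
      tv_v.push_back(best.tv);
      gap_v.push_back(best.cols - nd);
      cols_v.push_back(best.cols);
      ident_v.push_back(ident);
    }
  }
  return make_result(start_v, end_v, score_v, match_v, ts_v, tv_v, gap_v,
                     cols_v, ident_v);
}
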