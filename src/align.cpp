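#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>
using namespace Rcpp;

// Affine-gap convention: a gap of length g costs gap_open + (g-1)*gap_extend
// (first gapped base pays the open cost). All costs passed as positive numbers.
// Non-ACGT characters mismatch everything, including themselves.

static const int NEG = INT_MIN / 4;

static inline int subscore(char a, char b, int match, int mismatch) {
  if (a != b) return mismatch;
  switch (a) {
  case 'A': case 'C': case 'G': case 'T': return match;
  default: return mismatch;
  }
}

enum State { ST_M = 0, ST_GS = 1, ST_GQ = 2, ST_START = 3 };

// Semi-global ("glocal") alignment: the entire query is aligned against a
// local region of the subject. Subject-terminal gaps are free; the query must
// be fully covered. Traceback ties prefer diagonal over gap-in-subject over
// gap-in-query, and among equal end scores the smallest subject end.
// [[Rcpp::export]]
List glocal_align_cpp(std::string q, std::string s,
                      int match, int mismatch, int gap_open, int gap_extend) {
  const int n = q.size(), m = s.size();
  if (n < 1) stop("empty query");
  const int W = m + 1;
  std::vector<int> M((n + 1) * W, NEG), GS((n + 1) * W, NEG), GQ((n + 1) * W, NEG);
  std::vector<signed char> pM((n + 1) * W, -1), pGS((n + 1) * W, -1), pGQ((n + 1) * W, -1);
#define IX(i, j) ((i) * W + (j))
  for (int j = 0; j <= m; ++j) M[IX(0, j)] = 0;   // free leading subject
  for (int i = 1; i <= n; ++i) {                   // leading gap-in-subject run
    GS[IX(i, 0)] = (i == 1) ? -gap_open : GS[IX(i - 1, 0)] - gap_extend;
    pGS[IX(i, 0)] = (i == 1) ? ST_M : ST_GS;       // ST_M at i==1 means "from start"
  }
  for (int i = 1; i <= n; ++i) {
    const char qc = q[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int d = IX(i - 1, j - 1);
      int best = M[d]; signed char ptr = ST_M;
      if (GS[d] > best) { best = GS[d]; ptr = ST_GS; }
      if (GQ[d] > best) { best = GQ[d]; ptr = ST_GQ; }
      M[IX(i, j)] = best + subscore(qc, s[j - 1], match, mismatch);
      pM[IX(i, j)] = ptr;

      const int u = IX(i - 1, j);
      int bgs = M[u] - gap_open; signed char pgs = ST_M;
      if (GS[u] - gap_extend > bgs) { bgs = GS[u] - gap_extend; pgs = ST_GS; }
      if (GQ[u] - gap_open > bgs) { bgs = GQ[u] - gap_open; pgs = ST_GQ; }
      GS[IX(i, j)] = bgs; pGS[IX(i, j)] = pgs;

      const int l = IX(i, j - 1);
      int bgq = M[l] - gap_open; signed char pgq = ST_M;
      if (GQ[l] - gap_extend > bgq) { bgq = GQ[l] - gap_extend; pgq = ST_GQ; }
      if (GS[l] - gap_open > bgq) { bgq = GS[l] - gap_open; pgq = ST_GS; }
      GQ[IX(i, j)] = bgq; pGQ[IX(i, j)] = pgq;
    }
  }
  // best end in the last query row (states M and GS; ending with a subject
  // base against a gap is always dominated by ending earlier)
  int bestScore = NEG, bestJ = -1; signed char bestState = ST_M;
  for (int j = 0; j <= m; ++j) {
    if (M[IX(n, j)] > bestScore) { bestScore = M[IX(n, j)]; bestJ = j; bestState = ST_M; }
    if (GS[IX(n, j)] > bestScore) { bestScore = GS[IX(n, j)]; bestJ = j; bestState = ST_GS; }
  }
  // traceback
  std::string aq, as;
  int i = n, j = bestJ; signed char st = bestState;
  while (i > 0) {
    if (st == ST_M) {
      signed char nxt = pM[IX(i, j)];
      aq.push_back(q[i - 1]); as.push_back(s[j - 1]);
      --i; --j; st = nxt;
    } else if (st == ST_GS) {
      signed char nxt = (j == 0 && i == 1) ? ST_M : pGS[IX(i, j)];
      aq.push_back(q[i - 1]); as.push_back('-');
      --i; st = nxt;
    } else { // ST_GQ
      signed char nxt = pGQ[IX(i, j)];
      aq.push_back('-'); as.push_back(s[j - 1]);
      --j; st = nxt;
    }
  }
  std::reverse(aq.begin(), aq.end());
  std::reverse(as.begin(), as.end());
#undef IX
  return List::create(_["score"] = bestScore,
                      _["sstart"] = j,          // 0-based start on subject
                      _["send"] = bestJ,        // 0-based half-open end
                      _["aligned_query"] = aq,
                      _["aligned_subject"] = as);
}

// Score-only glocal DP with rolling rows; used for E-value calibration where
// only the best score per (query, subject) pair is needed.
// [[Rcpp::export]]
int glocal_best_score_cpp(std::string q, std::string s,
                          int match, int mismatch, int gap_open, int gap_extend) {
  const int n = q.size(), m = s.size();
  std::vector<int> M0(m + 1), GS0(m + 1), GQ0(m + 1), M1(m + 1), GS1(m + 1), GQ1(m + 1);
  for (int j = 0; j <= m; ++j) { M0[j] = 0; GS0[j] = NEG; GQ0[j] = NEG; }
  for (int i = 1; i <= n; ++i) {
    M1[0] = NEG; GQ1[0] = NEG;
    GS1[0] = (i == 1) ? -gap_open : GS0[0] - gap_extend;
    const char qc = q[i - 1];
    for (int j = 1; j <= m; ++j) {
      int d = std::max(M0[j - 1], std::max(GS0[j - 1], GQ0[j - 1]));
      M1[j] = d + subscore(qc, s[j - 1], match, mismatch);
      GS1[j] = std::max(M0[j] - gap_open,
                        std::max(GS0[j] - gap_extend, GQ0[j] - gap_open));
      GQ1[j] = std::max(M1[j - 1] - gap_open,
                        std::max(GQ1[j - 1] - gap_extend, GS1[j - 1] - gap_open));
    }
    std::swap(M0, M1); std::swap(GS0, GS1); std::swap(GQ0, GQ1);
  }
  int best = NEG;
  for (int j = 0; j <= m; ++j) best = std::max(best, std::max(M0[j], GS0[j]));
  return best;
}

// Score-only Smith-Waterman with rolling rows (calibration fast path).
// [[Rcpp::export]]
int local_best_score_cpp(std::string q, std::string s,
                         int match, int mismatch, int gap_open, int gap_extend) {
  const int n = q.size(), m = s.size();
  std::vector<int> M0(m + 1, NEG), GS0(m + 1, NEG), GQ0(m + 1, NEG),
    M1(m + 1), GS1(m + 1), GQ1(m + 1);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    M1[0] = NEG; GS1[0] = NEG; GQ1[0] = NEG;
    const char qc = q[i - 1];
    for (int j = 1; j <= m; ++j) {
      int d = std::max(0, std::max(M0[j - 1], std::max(GS0[j - 1], GQ0[j - 1])));
      M1[j] = d + subscore(qc, s[j - 1], match, mismatch);
      GS1[j] = std::max(M0[j] - gap_open,
                        std::max(GS0[j] - gap_extend, GQ0[j] - gap_open));
      GQ1[j] = std::max(M1[j - 1] - gap_open,
                        std::max(GQ1[j - 1] - gap_extend, GS1[j - 1] - gap_open));
      if (M1[j] > best) best = M1[j];
    }
    std::swap(M0, M1); std::swap(GS0, GS1); std::swap(GQ0, GQ1);
  }
  return best;
}

// Batched calibration helper: best score of each query against the matching
// subject (both vectors the same length); glocal or local mode.
// [[Rcpp::export]]
IntegerVector score_batch_cpp(CharacterVector queries, CharacterVector subjects,
                              int match, int mismatch, int gap_open, int gap_extend,
                              bool local) {
  if (queries.size() != subjects.size()) stop("length mismatch");
  IntegerVector out(queries.size());
  for (R_xlen_t k = 0; k < queries.size(); ++k) {
    std::string q = as<std::string>(queries[k]), s = as<std::string>(subjects[k]);
    out[k] = local ? local_best_score_cpp(q, s, match, mismatch, gap_open, gap_extend)
                   : glocal_best_score_cpp(q, s, match, mismatch, gap_open, gap_extend);
  }
  return out;
}

// Standard Smith-Waterman local alignment (Gotoh affine gaps).
// [[Rcpp::export]]
List local_align_cpp(std::string q, std::string s,
                     int match, int mismatch, int gap_open, int gap_extend) {
  const int n = q.size(), m = s.size();
  const int W = m + 1;
  std::vector<int> M((n + 1) * W, NEG), GS((n + 1) * W, NEG), GQ((n + 1) * W, NEG);
  std::vector<signed char> pM((n + 1) * W, -1), pGS((n + 1) * W, -1), pGQ((n + 1) * W, -1);
#define IX(i, j) ((i) * W + (j))
  int bestScore = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const char qc = q[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int d = IX(i - 1, j - 1);
      int best = 0; signed char ptr = ST_START;                 // fresh start
      if (M[d] > best) { best = M[d]; ptr = ST_M; }
      if (GS[d] > best) { best = GS[d]; ptr = ST_GS; }
      if (GQ[d] > best) { best = GQ[d]; ptr = ST_GQ; }
      M[IX(i, j)] = best + subscore(qc, s[j - 1], match, mismatch);
      pM[IX(i, j)] = ptr;
      const int u = IX(i - 1, j);
      int bgs = M[u] - gap_open; signed char pgs = ST_M;
      if (GS[u] - gap_extend > bgs) { bgs = GS[u] - gap_extend; pgs = ST_GS; }
      if (GQ[u] - gap_open > bgs) { bgs = GQ[u] - gap_open; pgs = ST_GQ; }
      GS[IX(i, j)] = bgs; pGS[IX(i, j)] = pgs;
      const int l = IX(i, j - 1);
      int bgq = M[l] - gap_open; signed char pgq = ST_M;
      if (GQ[l] - gap_extend > bgq) { bgq = GQ[l] - gap_extend; pgq = ST_GQ; }
      if (GS[l] - gap_open > bgq) { bgq = GS[l] - gap_open; pgq = ST_GS; }
      GQ[IX(i, j)] = bgq; pGQ[IX(i, j)] = pgq;
      if (M[IX(i, j)] > bestScore) { bestScore = M[IX(i, j)]; bi = i; bj = j; }
    }
  }
  if (bestScore <= 0) {
    return List::create(_["score"] = 0, _["qstart"] = NA_INTEGER, _["qend"] = NA_INTEGER,
                        _["sstart"] = NA_INTEGER, _["send"] = NA_INTEGER,
                        _["aligned_query"] = "", _["aligned_subject"] = "");
  }
  std::string aq, as;
  int i = bi, j = bj; signed char st = ST_M;
  while (true) {
    if (st == ST_M) {
      signed char nxt = pM[IX(i, j)];
      aq.push_back(q[i - 1]); as.push_back(s[j - 1]);
      --i; --j;
      if (nxt == ST_START) break;
      st = nxt;
    } else if (st == ST_GS) {
      signed char nxt = pGS[IX(i, j)];
      aq.push_back(q[i - 1]); as.push_back('-'); --i; st = nxt;
    } else {
      signed char nxt = pGQ[IX(i, j)];
      aq.push_back('-'); as.push_back(s[j - 1]); --j; st = nxt;
    }
  }
  std::reverse(aq.begin(), aq.end());
  std::reverse(as.begin(), as.end());
#undef IX
  return List::create(_["score"] = bestScore, _["qstart"] = i, _["qend"] = bi,
                      _["sstart"] = j, _["send"] = bj,
                      _["aligned_query"] = aq, _["aligned_subject"] = as);
}

// Exhaustive enumeration of every glocal alignment (independent oracle for the
// DP). Exponential; only usable for tiny instances.
struct BruteCtx {
  const std::string *q, *s;
  int n, m, match, mismatch, gap_open, gap_extend, best;
};

static void brute_rec(BruteCtx &c, int i, int j, int state, int score) {
  if (i == c.n) { if (score > c.best) c.best = score; return; }
  if (score + (c.n - i) * c.match <= c.best) return;  // admissible bound: prune
  if (j < c.m)
    brute_rec(c, i + 1, j + 1, ST_M,
              score + subscore((*c.q)[i], (*c.s)[j], c.match, c.mismatch));
  brute_rec(c, i + 1, j, ST_GS, score - (state == ST_GS ? c.gap_extend : c.gap_open));
  if (i > 0 && j < c.m)   // no gap-in-query before the first or after the last query base
    brute_rec(c, i, j + 1, ST_GQ, score - (state == ST_GQ ? c.gap_extend : c.gap_open));
}

// [[Rcpp::export]]
int glocal_brute_cpp(std::string q, std::string s,
                     int match, int mismatch, int gap_open, int gap_extend) {
  if (q.size() > 12 || s.size() > 16) stop("brute-force oracle limited to tiny instances");
  BruteCtx c{&q, &s, (int)q.size(), (int)s.size(), match, mismatch, gap_open, gap_extend, NEG};
  for (int a = 0; a <= c.m; ++a) brute_rec(c, 0, a, ST_START, 0);
  return c.best;
}
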