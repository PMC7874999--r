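// Affine-gap pairwise alignment kernels (Gotoh). Scoring: +match, -mismatch,
// a gap of length L costs gapOpen + L * gapExtend; N scores nScore against
// everything including N (N never matches).
//
// cpp_align_local runs three passes: a forward score-only Smith-Waterman to
// find the best score and end point, a reverse score-only pass to find the
// start point, and a global alignment of the bounded subrectangle (whose
// score provably equals the local score) to extract match and column counts.
// The score passes keep only rolling rows, so memory stays O(target).
//
// cpp_align_global is Needleman-Wunsch with a full byte traceback returning
// the gapped aligned strings (callers bound the problem size).

#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

static const double NEG = -1e18;

struct ScoreHit {
  double score;
  int qEnd, tEnd;  // 1-based DP indices of the best cell
};

// Score-only local DP; sub[] is a 25-entry lookup over indexed bases.
static ScoreHit scoreLocal(const std::vector<int> &q, const std::vector<int> &t,
                           const double *sub, double open, double ext) {
  const int n = (int)q.size(), m = (int)t.size();
  std::vector<double> M0(m + 1, 0.0), M1(m + 1, 0.0), X0(m + 1, NEG),
      X1(m + 1, NEG), Y0(m + 1, NEG), Y1(m + 1, NEG);
  ScoreHit best = {0.0, 0, 0};
  for (int i = 1; i <= n; ++i) {
    M1[0] = 0.0; X1[0] = NEG; Y1[0] = NEG;
    const double *srow = sub + 5 * q[i - 1];
    for (int j = 1; j <= m; ++j) {
      double diag = std::max(M0[j - 1], std::max(X0[j - 1], Y0[j - 1]));
      if (diag < 0.0) diag = 0.0;
      double mv = diag + srow[t[j - 1]];
      if (mv < 0.0) mv = 0.0;
      M1[j] = mv;
      X1[j] = std::max(std::max(M1[j - 1], Y1[j - 1]) - open, X1[j - 1] - ext);
      Y1[j] = std::max(std::max(M0[j], X0[j]) - open, Y0[j] - ext);
      if (mv > best.score) { best = {mv, i, j}; }
    }
    std::swap(M0, M1); std::swap(X0, X1); std::swap(Y0, Y1);
  }
  return best;
}

static std::vector<int> indexBases(const std::string &s, int from, int to,
                                   bool reversed) {
  std::vector<int> v;
  v.reserve(to - from);
  for (int k = from; k < to; ++k) {
    char c = s[reversed ? (to - 1 - (k - from)) : k];
    int b;
    switch (c) {
      case 'A': b = 0; break;
      case 'C': b = 1; break;
      case 'G': b = 2; break;
      case 'T': b = 3; break;
      default: b = 4;  // N and anything unexpected never match
    }
    v.push_back(b);
  }
  return v;
}

static void fillSub(double *sub, double match, double mismatch, double nScore) {
  for (int a = 0; a < 5; ++a)
    for (int b = 0; b < 5; ++b)
      sub[5 * a + b] = (a == 4 || b == 4) ? nScore
                       : (a == b ? match : mismatch);
}

// Global alignment over indexed bases with byte traceback; returns score and
// writes the gapped strings.
static double globalCore(const std::vector<int> &q, const std::vector<int> &t,
                         const std::string &qs, const std::string &ts,
                         const double *sub, double open, double ext,
                         std::string &pa, std::string &sa) {
  const int n = (int)q.size(), m = (int)t.size();
  std::vector<double> Mp(m + 1), Mc(m + 1), Xp(m + 1), Xc(m + 1), Yp(m + 1),
      Yc(m + 1);
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1), 0);
  Mp[0] = 0.0; Xp[0] = Yp[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    Mp[j] = NEG; Yp[j] = NEG;
    Xp[j] = -(open + ext * (j - 1));
    tb[j] = (unsigned char)(1 << 2);
  }
  for (int i = 1; i <= n; ++i) {
    Mc[0] = NEG; Xc[0] = NEG;
    Yc[0] = -(open + ext * (i - 1));
    unsigned char *trow = &tb[(size_t)i * (m + 1)];
    trow[0] = (unsigned char)(1 << 4);
    const double *srow = sub + 5 * q[i - 1];
    for (int j = 1; j <= m; ++j) {
      unsigned char code = 0;
      double mBest = Mp[j - 1]; int mFrom = 0;
      if (Xp[j - 1] > mBest) { mBest = Xp[j - 1]; mFrom = 1; }
      if (Yp[j - 1] > mBest) { mBest = Yp[j - 1]; mFrom = 2; }
      Mc[j] = (mBest <= NEG / 2) ? NEG : mBest + srow[t[j - 1]];
      code |= (unsigned char)mFrom;
      double xBest = Mc[j - 1] - open; int xFrom = 0;
      if (Xc[j - 1] - ext > xBest) { xBest = Xc[j - 1] - ext; xFrom = 1; }
      if (Yc[j - 1] - open > xBest) { xBest = Yc[j - 1] - open; xFrom = 2; }
      Xc[j] = xBest;
      code |= (unsigned char)(xFrom << 2);
      double yBest = Mp[j] - open; int yFrom = 0;
      if (Yp[j] - ext > yBest) { yBest = Yp[j] - ext; yFrom = 1; }
      if (Xp[j] - open > yBest) { yBest = Xp[j] - open; yFrom = 2; }
      Yc[j] = yBest;
      code |= (unsigned char)(yFrom << 4);
      trow[j] = code;
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  double score = Mp[m]; int state = 0;
  if (Xp[m] > score) { score = Xp[m]; state = 1; }
  if (Yp[m] > score) { score = Yp[m]; state = 2; }
  pa.clear(); sa.clear();
  pa.reserve(n + m); sa.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char code = tb[(size_t)i * (m + 1) + j];
    if (j == 0) state = 2;
    else if (i == 0) state = 1;
    if (state == 0) {
      int from = code & 3;
      pa.push_back(qs[i - 1]); sa.push_back(ts[j - 1]);
      --i; --j; state = from;
    } else if (state == 1) {  // gap in query, consume target
      int from = (code >> 2) & 3;
      pa.push_back('-'); sa.push_back(ts[j - 1]);
      --j;
      state = (from == 0) ? 0 : (from == 1 ? 1 : 2);
    } else {  // gap in target, consume query
      int from = (code >> 4) & 3;
      pa.push_back(qs[i - 1]); sa.push_back('-');
      --i;
      state = (from == 0) ? 0 : (from == 1 ? 2 : 1);
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(sa.begin(), sa.end());
  return score;
}

// [[Rcpp::export]]
List cpp_align_local(std::string q, std::string t, double match,
                     double mismatch, double gapOpen, double gapExtend,
                     double nScore) {
  double sub[25];
  fillSub(sub, match, mismatch, nScore);
  const double open = gapOpen + gapExtend, ext = gapExtend;
  std::vector<int> qi = indexBases(q, 0, (int)q.size(), false);
  std::vector<int> ti = indexBases(t, 0, (int)t.size(), false);
  ScoreHit fwd = scoreLocal(qi, ti, sub, open, ext);
  if (fwd.score <= 0.0)
    return List::create(_["score"] = 0.0, _["nmatch"] = 0, _["columns"] = 0,
                        _["query_start"] = 0, _["query_end"] = 0,
                        _["target_start"] = 0, _["target_end"] = 0);
  // reverse pass over the prefixes ending at the optimum locates the start
  std::vector<int> qr = indexBases(q, 0, fwd.qEnd, true);
  std::vector<int> tr = indexBases(t, 0, fwd.tEnd, true);
  ScoreHit rev = scoreLocal(qr, tr, sub, open, ext);
  int q0 = fwd.qEnd - rev.qEnd, t0 = fwd.tEnd - rev.tEnd;
  std::string qsub = q.substr(q0, fwd.qEnd - q0);
  std::string tsub = t.substr(t0, fwd.tEnd - t0);
  std::vector<int> qsi = indexBases(qsub, 0, (int)qsub.size(), false);
  std::vector<int> tsi = indexBases(tsub, 0, (int)tsub.size(), false);
  std::string pa, sa;
  globalCore(qsi, tsi, qsub, tsub, sub, open, ext, pa, sa);
  int nmatch = 0;
  for (size_t k = 0; k < pa.size(); ++k)
    if (pa[k] == sa[k] && pa[k] != '-' && pa[k] != 'N') ++nmatch;
  return List::create(
      _["score"] = fwd.score, _["nmatch"] = nmatch,
      _["columns"] = (int)pa.size(),
      _["query_start"] = q0, _["query_end"] = fwd.qEnd,
      _["target_start"] = t0, _["target_end"] = fwd.tEnd);
}

// [[Rcpp::export]]
List cpp_align_global(std::string q, std::string t, double match,
                      double mismatch, double gapOpen, double gapExtend,
                      double nScore) {
  double sub[25];
  fillSub(sub, match, mismatch, nScore);
  const double open = gapOpen + gapExtend, ext = gapExtend;
  std::vector<int> qi = indexBases(q, 0, (int)q.size(), false);
  std::vector<int> ti = indexBases(t, 0, (int)t.size(), false);
  std::string pa, sa;
  double score = globalCore(qi, ti, q, t, sub, open, ext, pa, sa);
  return List::create(_["score"] = score, _["pattern"] = pa, _["subject"] = sa);
}
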