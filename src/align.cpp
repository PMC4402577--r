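#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap dynamic programming over an arbitrary column-pair score matrix.
//
// M[i][j] is the score for aligning element i of the first axis against
// element j of the second axis (a substitution score for residue pairs, or
// an expected profile-profile score).  A gap run of length k costs
// gap_open + (k - 1) * gap_extend.
//
// Traceback tie-break: diagonal first, then up (gap in the second axis,
// consuming an element of the first), then left.  Inside a gap state a tie
// between opening and extending is resolved by opening, i.e. the shorter
// gap wins.  This makes the traceback fully deterministic.
//
// Returns the optimal score and the alignment path as two integer vectors:
// path_a[k] / path_b[k] give the 1-based index consumed from each axis at
// output column k, 0 meaning a gap.  In local mode the path covers the best
// contiguous segment pair; an empty path with score 0 is the degenerate
// local optimum.

static const double NEG_INF = -1e300;

// state codes for traceback
enum { ST_DIAG = 0, ST_UP = 1, ST_LEFT = 2, ST_STOP = 3 };

// [[Rcpp::export(name = ".affine_dp")]]
List affine_dp(NumericMatrix M, double gap_open, double gap_extend,
               bool local) {
  const int n = M.nrow(), m = M.ncol();
  if (n < 1 || m < 1) stop("score matrix must be at least 1x1");

  // H: best ending at (i,j) in any state; U: ending with gap in axis b
  // (consuming a, vertical); L: ending with gap in axis a (horizontal).
  std::vector<double> Hprev(m + 1), Hcur(m + 1), Uprev(m + 1), Ucur(m + 1),
      Lprev(m + 1), Lcur(m + 1);
  // full traceback matrices, one byte per cell per state
  // tbH: which state achieved H; tbU/tbL: 1 = extend, 0 = open from H
  std::vector<signed char> tbH((n + 1) * (m + 1)), tbU((n + 1) * (m + 1)),
      tbL((n + 1) * (m + 1));
  const int W = m + 1;

  // boundary row i = 0
  Hprev[0] = 0.0;
  Uprev[0] = NEG_INF;
  Lprev[0] = NEG_INF;
  tbH[0] = ST_STOP;
  for (int j = 1; j <= m; ++j) {
    if (local) {
      Hprev[j] = 0.0;
      Lprev[j] = NEG_INF;
      tbH[j] = ST_STOP;
    } else {
      Lprev[j] = -(gap_open + (j - 1) * gap_extend);
      Hprev[j] = Lprev[j];
      tbH[j] = ST_LEFT;
      tbL[j] = (j == 1) ? 0 : 1;
    }
    Uprev[j] = NEG_INF;
  }

  double best = 0.0;
  int best_i = 0, best_j = 0;  // for local traceback start

  for (int i = 1; i <= n; ++i) {
    if (local) {
      Hcur[0] = 0.0;
      Ucur[0] = NEG_INF;
      tbH[i * W] = ST_STOP;
    } else {
      Ucur[0] = -(gap_open + (i - 1) * gap_extend);
      Hcur[0] = Ucur[0];
      tbH[i * W] = ST_UP;
      tbU[i * W] = (i == 1) ? 0 : 1;
    }
    Lcur[0] = NEG_INF;
    for (int j = 1; j <= m; ++j) {
      // vertical: consume a[i], gap in b
      double u_open = Hprev[j] - gap_open;
      double u_ext = Uprev[j] - gap_extend;
      if (u_open >= u_ext) {  // tie -> open (shorter gap)
        Ucur[j] = u_open;
        tbU[i * W + j] = 0;
      } else {
        Ucur[j] = u_ext;
        tbU[i * W + j] = 1;
      }
      // horizontal: consume b[j], gap in a
      double l_open = Hcur[j - 1] - gap_open;
      double l_ext = Lcur[j - 1] - gap_extend;
      if (l_open >= l_ext) {
        Lcur[j] = l_open;
        tbL[i * W + j] = 0;
      } else {
        Lcur[j] = l_ext;
        tbL[i * W + j] = 1;
      }
      double diag = Hprev[j - 1] + M(i - 1, j - 1);
      // tie-break: diagonal, then up, then left
      double h = diag;
      signed char st = ST_DIAG;
      if (Ucur[j] > h) {
        h = Ucur[j];
        st = ST_UP;
      }
      if (Lcur[j] > h) {
        h = Lcur[j];
        st = ST_LEFT;
      }
      if (local && h <= 0.0) {
        h = 0.0;
        st = ST_STOP;
      }
      Hcur[j] = h;
      tbH[i * W + j] = st;
      if (local && h > best) {  // first maximum in row-major scan wins
        best = h;
        best_i = i;
        best_j = j;
      }
    }
    std::swap(Hprev, Hcur);
    std::swap(Uprev, Ucur);
    std::swap(Lprev, Lcur);
  }

  int i, j;
  double score;
  if (local) {
    score = best;
    i = best_i;
    j = best_j;
    if (score <= 0.0) {
      return List::create(_["score"] = 0.0,
                          _["path_a"] = IntegerVector(0),
                          _["path_b"] = IntegerVector(0));
    }
  } else {
    score = Hprev[m];  // after final swap Hprev holds row n
    i = n;
    j = m;
  }

  // traceback
  std::vector<int> pa, pb;
  pa.reserve(n + m);
  pb.reserve(n + m);
  int state = ST_DIAG;  // meaning: currently in H
  // we walk states explicitly: cur = which matrix we are in
  int cur = 0;  // 0 = H, 1 = U, 2 = L
  while (i > 0 || j > 0) {
    if (cur == 0) {
      signed char st = tbH[i * W + j];
      if (st == ST_STOP) break;  // local start
      if (st == ST_DIAG) {
        pa.push_back(i);
        pb.push_back(j);
        --i;
        --j;
        cur = 0;
      } else if (st == ST_UP) {
        cur = 1;
      } else {
        cur = 2;
      }
    } else if (cur == 1) {
      signed char ext = tbU[i * W + j];
      pa.push_back(i);
      pb.push_back(0);
      --i;
      cur = ext ? 1 : 0;
    } else {
      signed char ext = tbL[i * W + j];
      pa.push_back(0);
      pb.push_back(j);
      --j;
      cur = ext ? 2 : 0;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["score"] = score,
                      _["path_a"] = IntegerVector(pa.begin(), pa.end()),
                      _["path_b"] = IntegerVector(pb.begin(), pb.end()));
}
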