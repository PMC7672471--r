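#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap overlap alignment on a precomputed column-similarity matrix.
//
// S is n x m: S(i-1, j-1) = s(x_i, y_j).  Three-state Gotoh recursion:
//   M(i,j)  = max(M, Ix, Iy)(i-1, j-1) + s(x_i, y_j)
//   Ix(i,j) = max(M(i-1,j) - d, Ix(i-1,j) - e)      [x_i against a gap]
//   Iy(i,j) = max(M(i,j-1) - d, Iy(i,j-1) - e)      [y_j inserted]
// Overlap initialization: the first row and first column of ALL three
// matrices are 0 (free end gaps).  A consequence of zero-initializing Ix and
// Iy on the edges is that a gap run opened at the very start of a path is
// charged e per column (it "extends" the free edge state) rather than
// d + (g-1)e; the enumeration oracle below models the same alignment space.
// Traceback starts at the best cell on the lower-right quadrant border:
// (n, j) for j >= ceil(m/2) or (i, m) for i >= ceil(n/2), over all three
// matrices, and runs until the top or left edge.
//
// Ties: M preferred over Ix over Iy; among equal border cells the one with
// the larger i + j (larger overlap) wins.
//
// Returns score, the traceback path as a 2-column matrix of (i, j) with 0
// marking a gap in that profile, and the start/end cells.

static const double NEG_INF = -1e300;

// [[Rcpp::export]]
List overlap_align_cpp(NumericMatrix S, double d, double e) {
  const int n = S.nrow(), m = S.ncol();
  const size_t W = (size_t) m + 1;
  std::vector<double> M((n + 1) * W, 0.0), Ix((n + 1) * W, 0.0),
                      Iy((n + 1) * W, 0.0);
  // predecessor state at each cell: 0 = M, 1 = Ix, 2 = Iy
  std::vector<unsigned char> ptrM((n + 1) * W, 0), ptrIx((n + 1) * W, 0),
                             ptrIy((n + 1) * W, 0);
  const double *Sp = REAL(S);
#define IDX(i, j) ((size_t)(i) * W + (size_t)(j))

  for (int i = 1; i <= n; ++i) {
    const size_t row = IDX(i, 0), prow = IDX(i - 1, 0);
    for (int j = 1; j <= m; ++j) {
      const double s = Sp[(i - 1) + (size_t) n * (j - 1)];
      // M: best predecessor among the three, tie-break M > Ix > Iy
      double best = M[prow + j - 1]; int bp = 0;
      if (Ix[prow + j - 1] > best) { best = Ix[prow + j - 1]; bp = 1; }
      if (Iy[prow + j - 1] > best) { best = Iy[prow + j - 1]; bp = 2; }
      M[row + j] = best + s; ptrM[row + j] = (unsigned char) bp;

      double a = M[prow + j] - d, b = Ix[prow + j] - e;
      if (a >= b) { Ix[row + j] = a; ptrIx[row + j] = 0; }
      else        { Ix[row + j] = b; ptrIx[row + j] = 1; }

      a = M[row + j - 1] - d; b = Iy[row + j - 1] - e;
      if (a >= b) { Iy[row + j] = a; ptrIy[row + j] = 0; }
      else        { Iy[row + j] = b; ptrIy[row + j] = 2; }
    }
  }

  // traceback start: lower-right quadrant border
  const int jmin = (m + 1) / 2, imin = (n + 1) / 2;
  double best = NEG_INF; int bi = n, bj = m, bstate = 0;
  for (int j = jmin; j <= m; ++j) {
    double v[3] = { M[IDX(n, j)], Ix[IDX(n, j)], Iy[IDX(n, j)] };
    for (int st = 0; st < 3; ++st) {
      if (v[st] > best ||
          (v[st] == best && (n + j > bi + bj ||
                             (n + j == bi + bj && st < bstate)))) {
        best = v[st]; bi = n; bj = j; bstate = st;
      }
    }
  }
  for (int i = imin; i <= n; ++i) {
    double v[3] = { M[IDX(i, m)], Ix[IDX(i, m)], Iy[IDX(i, m)] };
    for (int st = 0; st < 3; ++st) {
      if (v[st] > best ||
          (v[st] == best && (i + m > bi + bj ||
                             (i + m == bi + bj && st < bstate)))) {
        best = v[st]; bi = i; bj = m; bstate = st;
      }
    }
  }

  // traceback
  std::vector<int> pi, pj;
  int i = bi, j = bj, st = bstate;
  while (i > 0 && j > 0) {
    if (st == 0) {            // match x_i : y_j
      pi.push_back(i); pj.push_back(j);
      st = ptrM[IDX(i, j)]; --i; --j;
    } else if (st == 1) {     // x_i : gap
      pi.push_back(i); pj.push_back(0);
      st = ptrIx[IDX(i, j)]; --i;
    } else {                  // gap : y_j
      pi.push_back(0); pj.push_back(j);
      st = ptrIy[IDX(i, j)]; --j;
    }
  }
#undef IDX
  const int plen = (int) pi.size();
  IntegerMatrix path(plen, 2);
  for (int k = 0; k < plen; ++k) {
    path(k, 0) = pi[plen - 1 - k];
    path(k, 1) = pj[plen - 1 - k];
  }

  return List::create(_["score"] = best,
                      _["path"] = path,
                      _["start"] = IntegerVector::create(i, j),
                      _["end"] = IntegerVector::create(bi, bj));
}

// ---------------------------------------------------------------------------
// Independent brute-force oracle: exhaustively enumerates every monotone
// overlap alignment (start on the top/left edge, end on the lower-right
// quadrant border) with affine gap runs scored -d-(g-1)e, and returns the
// maximum score.  Two deliberate matches with the recursion's alignment
// space: (a) an x-gap run never directly abuts a y-gap run (there is no
// Ix<->Iy transition); (b) a gap run at the very start of the path is
// charged e per column (zero-initialized edge states).  Plain depth-first
// recursion; no code shared with the DP above.

struct OracleCtx {
  const double *S;
  int n, m;
  double d, e;
  int jmin, imin;
  double best;
};

// last: 0 = match/none, 1 = in x-gap run, 2 = in y-gap run
// first_run: no match consumed yet (initial gap run extends the free edge)
static void oracle_dfs(OracleCtx &C, int i, int j, int last, bool first_run,
                       double score) {
  if ((i == C.n && j >= C.jmin) || (j == C.m && i >= C.imin)) {
    if (score > C.best) C.best = score;
  }
  if (i < C.n && j < C.m)
    oracle_dfs(C, i + 1, j + 1, 0, false,
               score + C.S[i + (size_t) C.n * j]);
  if (i < C.n && last != 2) {
    double cost = (last == 1 || first_run) ? C.e : C.d;
    oracle_dfs(C, i + 1, j, 1, first_run, score - cost);
  }
  if (j < C.m && last != 1) {
    double cost = (last == 2 || first_run) ? C.e : C.d;
    oracle_dfs(C, i, j + 1, 2, first_run, score - cost);
  }
}

// [[Rcpp::export]]
double overlap_align_bruteforce_cpp(NumericMatrix S, double d, double e) {
  OracleCtx C;
  C.S = REAL(S); C.n = S.nrow(); C.m = S.ncol();
  C.d = d; C.e = e;
  C.jmin = (C.m + 1) / 2; C.imin = (C.n + 1) / 2;
  C.best = NEG_INF;
  for (int i0 = 0; i0 <= C.n; ++i0) oracle_dfs(C, i0, 0, 0, true, 0.0);
  for (int j0 = 1; j0 <= C.m; ++j0) oracle_dfs(C, 0, j0, 0, true, 0.0);
  return C.best;
}
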