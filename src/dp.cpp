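// Dynamic-programming kernels: profile-HMM forward/Viterbi scoring,
// pairwise p-distances on alignment matrices, and affine-gap
// profile-profile alignment used by the progressive aligner.
#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// log(exp(a) + exp(b)), safe at -Inf
static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = a > b ? a : b;
  return m + log1p(exp(-std::fabs(a - b)));
}

// Sequence residues are 0-based indices into the 20-letter alphabet;
// -1 marks a wildcard (X) whose emission odds ratio is 1 (log 0).
// All probabilities arrive in natural-log space; transitions out of
// match state k have already been rescaled for the local exit
// probability on the R side.  Flank (N/C) emissions and transitions
// score zero by construction, so entry is possible before any residue
// and exit after any match emission.
//
// lmat: M x 20 log emission-odds (log match - log background).
// ltXY: length-M vectors, entry k (0-based) = transition out of
//       position k+1 into position k+2 states; unusable entries -Inf.
// lentry: log P(B -> M_k); lexit: log P(M_k -> E).

struct HmmPar {
  int M;
  NumericMatrix lmat;
  NumericVector lMM, lMI, lMD, lIM, lII, lDM, lDD, lentry, lexit;
};

static HmmPar unpack(List hmm) {
  HmmPar p;
  p.lmat = as<NumericMatrix>(hmm["lmat"]);
  p.M = p.lmat.nrow();
  p.lMM = hmm["lMM"]; p.lMI = hmm["lMI"]; p.lMD = hmm["lMD"];
  p.lIM = hmm["lIM"]; p.lII = hmm["lII"];
  p.lDM = hmm["lDM"]; p.lDD = hmm["lDD"];
  p.lentry = hmm["lentry"]; p.lexit = hmm["lexit"];
  return p;
}

static inline double emit(const HmmPar& p, int k, int x) {
  return x < 0 ? 0.0 : p.lmat(k, x);
}

// [[Rcpp::export(name = "C_forward_bits")]]
double C_forward_bits(List hmm, IntegerVector seq) {
  HmmPar p = unpack(hmm);
  const int M = p.M, L = seq.size();
  std::vector<double> FMp(M, NEG_INF), FIp(M, NEG_INF), FDp(M, NEG_INF);
  std::vector<double> FM(M), FI(M), FD(M);
  double total = NEG_INF;
  for (int i = 0; i < L; ++i) {
    int x = seq[i];
    for (int k = 0; k < M; ++k) {
      double acc = p.lentry[k];
      if (k > 0) {
        acc = lse2(acc, FMp[k - 1] + p.lMM[k - 1]);
        acc = lse2(acc, FIp[k - 1] + p.lIM[k - 1]);
        acc = lse2(acc, FDp[k - 1] + p.lDM[k - 1]);
      }
      FM[k] = emit(p, k, x) + acc;
      // insert emission odds are background/background = 0
      FI[k] = lse2(FMp[k] + p.lMI[k], FIp[k] + p.lII[k]);
    }
    // deletes are non-emitting: fill left-to-right within this i
    FD[0] = NEG_INF;
    for (int k = 1; k < M; ++k)
      FD[k] = lse2(FM[k - 1] + p.lMD[k - 1], FD[k - 1] + p.lDD[k - 1]);
    for (int k = 0; k < M; ++k)
      total = lse2(total, FM[k] + p.lexit[k]);
    FMp = FM; FIp = FI; FDp = FD;
  }
  // the alignment start offset is uniform over the L residues, so the
  // placement sum is normalised by L; without this the free flanks
  // would inflate null scores by ~log2(L)
  return (total - log((double)L)) / M_LN2;
}

// Viterbi with traceback.  Tie-breaking: candidate predecessors are
// examined in the order entry < match < delete < insert and replaced
// only on strict improvement, so match beats delete beats insert; the
// terminal cell scan runs over increasing (i, k) with strict
// improvement, so among equal-scoring placements the leftmost
// (earliest-ending) one wins.
// [[Rcpp::export(name = "C_viterbi")]]
List C_viterbi(List hmm, IntegerVector seq) {
  HmmPar p = unpack(hmm);
  const int M = p.M, L = seq.size();
  if (L == 0) stop("empty sequence");
  // state codes for traceback: 0 none/entry, 1 M, 2 D, 3 I
  NumericMatrix VM(L, M), VI(L, M), VD(L, M);
  IntegerMatrix PM(L, M), PI(L, M), PD(L, M);
  for (int i = 0; i < L; ++i) {
    int x = seq[i];
    for (int k = 0; k < M; ++k) {
      double best = p.lentry[k]; int ptr = 0;
      if (k > 0 && i > 0) {
        double c = VM(i - 1, k - 1) + p.lMM[k - 1];
        if (c > best) { best = c; ptr = 1; }
        c = VD(i - 1, k - 1) + p.lDM[k - 1];
        if (c > best) { best = c; ptr = 2; }
        c = VI(i - 1, k - 1) + p.lIM[k - 1];
        if (c > best) { best = c; ptr = 3; }
      }
      VM(i, k) = emit(p, k, x) + best; PM(i, k) = ptr;
      double bi = NEG_INF; int pi = 0;
      if (i > 0) {
        double c = VM(i - 1, k) + p.lMI[k];
        if (c > bi) { bi = c; pi = 1; }
        c = VI(i - 1, k) + p.lII[k];
        if (c > bi) { bi = c; pi = 3; }
      }
      VI(i, k) = bi; PI(i, k) = pi;
    }
    VD(i, 0) = NEG_INF; PD(i, 0) = 0;
    for (int k = 1; k < M; ++k) {
      double c1 = VM(i, k - 1) + p.lMD[k - 1];
      double c2 = VD(i, k - 1) + p.lDD[k - 1];
      if (c1 >= c2) { VD(i, k) = c1; PD(i, k) = 1; }
      else          { VD(i, k) = c2; PD(i, k) = 2; }
    }
  }
  double best = NEG_INF; int bi = -1, bk = -1;
  for (int i = 0; i < L; ++i)
    for (int k = 0; k < M; ++k) {
      double c = VM(i, k) + p.lexit[k];
      if (c > best) { best = c; bi = i; bk = k; }
    }
  if (bi < 0) return List::create(_["bits"] = R_NegInf);
  // traceback from (bi, bk) in state M
  int i = bi, k = bk, st = 1;
  int envStart = bi, mStart = bk;
  while (true) {
    if (st == 1) {
      envStart = i; mStart = k;
      int ptr = PM(i, k);
      if (ptr == 0) break;
      st = ptr; --i; --k;      // M/I/D predecessors all sit at (i-1, k-1)
    } else if (st == 2) {
      int ptr = PD(i, k);
      st = ptr; --k;
      if (st == 2) { }        // stay on same i
    } else {                   // insert
      envStart = i;
      int ptr = PI(i, k);
      st = ptr; --i;
    }
  }
  return List::create(
    _["bits"] = (best - log((double)L)) / M_LN2,
    _["env_start"] = envStart,       // 0-based inclusive
    _["env_end"] = bi + 1,           // 0-based exclusive
    _["m_start"] = mStart + 1,       // 1-based model positions
    _["m_end"] = bk + 1);
}

// Pairwise proportion-different over mutually ungapped columns.
// seqs: integer matrix rows = sequences, gap/unknown coded < 0.
// Returns list(p = matrix, n = comparable-column counts).
// [[Rcpp::export(name = "C_pdist")]]
List C_pdist(IntegerMatrix seqs) {
  const int n = seqs.nrow(), L = seqs.ncol();
  NumericMatrix P(n, n);
  IntegerMatrix N(n, n);
  for (int a = 0; a < n; ++a)
    for (int b = a + 1; b < n; ++b) {
      int comp = 0, diff = 0;
      for (int j = 0; j < L; ++j) {
        int xa = seqs(a, j), xb = seqs(b, j);
        if (xa >= 0 && xb >= 0) { ++comp; if (xa != xb) ++diff; }
      }
      N(a, b) = N(b, a) = comp;
      P(a, b) = P(b, a) = comp > 0 ? (double)diff / comp : NA_REAL;
    }
  return List::create(_["p"] = P, _["n"] = N);
}

// Global affine-gap profile-profile alignment (Needleman-Wunsch,
// Gotoh).  A and B are 20 x L column-frequency profiles (gaps simply
// missing mass).  Column score = fA' S fB.  Tie-break on traceback:
// diagonal > up (consume A) > left (consume B).
// [[Rcpp::export(name = "C_nw_profile")]]
List C_nw_profile(NumericMatrix A, NumericMatrix B, NumericMatrix S,
                  double gapOpen, double gapExt) {
  const int La = A.ncol(), Lb = B.ncol();
  // precompute SB = S %*% B (20 x Lb), then score(i,j) = A[,i] . SB[,j]
  NumericMatrix SB(20, Lb);
  for (int j = 0; j < Lb; ++j)
    for (int a = 0; a < 20; ++a) {
      double s = 0;
      for (int b = 0; b < 20; ++b) s += S(a, b) * B(b, j);
      SB(a, j) = s;
    }
  std::vector<double> sc((size_t)La * Lb);
  for (int i = 0; i < La; ++i)
    for (int j = 0; j < Lb; ++j) {
      double s = 0;
      for (int a = 0; a < 20; ++a) s += A(a, i) * SB(a, j);
      sc[(size_t)i * Lb + j] = s;
    }
  const int R = La + 1, C = Lb + 1;
  std::vector<double> Mm((size_t)R * C, NEG_INF), X((size_t)R * C, NEG_INF),
      Y((size_t)R * C, NEG_INF);
  // X = gap in B (consume A, "up"); Y = gap in A (consume B, "left")
  auto idx = [C](int i, int j) { return (size_t)i * C + j; };
  Mm[idx(0, 0)] = 0;
  for (int i = 1; i < R; ++i)
    X[idx(i, 0)] = gapOpen + gapExt * (i - 1);
  for (int j = 1; j < C; ++j)
    Y[idx(0, j)] = gapOpen + gapExt * (j - 1);
  for (int i = 1; i < R; ++i)
    for (int j = 1; j < C; ++j) {
      double d = sc[(size_t)(i - 1) * Lb + (j - 1)];
      double pm = Mm[idx(i - 1, j - 1)], px = X[idx(i - 1, j - 1)],
             py = Y[idx(i - 1, j - 1)];
      double best = pm;
      if (px > best) best = px;
      if (py > best) best = py;
      Mm[idx(i, j)] = best + d;
      double xo = Mm[idx(i - 1, j)] + gapOpen,
             xe = X[idx(i - 1, j)] + gapExt,
             xy = Y[idx(i - 1, j)] + gapOpen;
      double bx = xo; if (xe > bx) bx = xe; if (xy > bx) bx = xy;
      X[idx(i, j)] = bx;
      double yo = Mm[idx(i, j - 1)] + gapOpen,
             ye = Y[idx(i, j - 1)] + gapExt,
             yx = X[idx(i, j - 1)] + gapOpen;
      double by = yo; if (ye > by) by = ye; if (yx > by) by = yx;
      Y[idx(i, j)] = by;
    }
  // traceback
  int i = La, j = Lb;
  double fm = Mm[idx(i, j)], fx = X[idx(i, j)], fy = Y[idx(i, j)];
  int state;  // 0 M, 1 X, 2 Y; prefer M > X > Y
  double score;
  if (fm >= fx && fm >= fy) { state = 0; score = fm; }
  else if (fx >= fy)        { state = 1; score = fx; }
  else                      { state = 2; score = fy; }
  std::vector<int> pa, pb;
  while (i > 0 || j > 0) {
    if (state == 0) {
      pa.push_back(i); pb.push_back(j);
      double d = sc[(size_t)(i - 1) * Lb + (j - 1)];
      double target = Mm[idx(i, j)] - d;
      --i; --j;
      if (std::fabs(Mm[idx(i, j)] - target) < 1e-9) state = 0;
      else if (std::fabs(X[idx(i, j)] - target) < 1e-9) state = 1;
      else state = 2;
    } else if (state == 1) {
      pa.push_back(i); pb.push_back(0);
      double target = X[idx(i, j)];
      --i;
      if (std::fabs(Mm[idx(i, j)] + gapOpen - target) < 1e-9) state = 0;
      else if (std::fabs(X[idx(i, j)] + gapExt - target) < 1e-9) state = 1;
      else state = 2;
      if (i == 0 && j > 0) state = 2;
      if (i == 0 && j == 0) break;
    } else {
      pa.push_back(0); pb.push_back(j);
      double target = Y[idx(i, j)];
      --j;
      if (std::fabs(Mm[idx(i, j)] + gapOpen - target) < 1e-9) state = 0;
      else if (std::fabs(Y[idx(i, j)] + gapExt - target) < 1e-9) state = 2;
      else state = 1;
      if (j == 0 && i > 0) state = 1;
      if (i == 0 && j == 0) break;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["score"] = score,
                      _["pathA"] = IntegerVector(pa.begin(), pa.end()),
                      _["pathB"] = IntegerVector(pb.begin(), pb.end()));
}
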