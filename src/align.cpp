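#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Affine-gap pairwise alignment by dynamic programming over three states:
//   M  - a aligned to b (substitution)
//   Ix - gap in b (consumes a; traceback direction "up")
//   Iy - gap in a (consumes b; traceback direction "left")
// A gap of length k costs gap_open + k * gap_extend (BLAST convention).
// Tie-break everywhere: diagonal (M) > up (Ix) > left (Iy), which makes the
// single reported traceback deterministic.
//
// Sequences arrive as 0-based integer codes into the rows/cols of the
// substitution matrix handed over from R.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

struct DPResult {
  double score;
  std::string aligned_a, aligned_b;
  int a_start, a_end, b_start, b_end; // 0-based half-open on the inputs
};

// pick the best of (m, x, y) with preference m > x > y; returns 0/1/2
static inline int argmax3(double m, double x, double y) {
  if (m >= x && m >= y) return 0;
  if (x >= y) return 1;
  return 2;
}

static DPResult align_core(const IntegerVector& a, const IntegerVector& b,
                           const NumericMatrix& S, double gap_open,
                           double gap_extend, bool local,
                           const CharacterVector& letters) {
  const int n = a.size(), m = b.size();
  const double open_cost = gap_open + gap_extend; // first gap residue
  // DP matrices, (n+1) x (m+1), row-major
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Ix((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Iy((n + 1) * (m + 1), NEG_INF);
  // traceback: for each state, which state it came from (0=M,1=Ix,2=Iy,3=start)
  std::vector<unsigned char> tbM((n + 1) * (m + 1), 3);
  std::vector<unsigned char> tbX((n + 1) * (m + 1), 3);
  std::vector<unsigned char> tbY((n + 1) * (m + 1), 3);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  if (!local) {
    for (int i = 1; i <= n; ++i) {
      Ix[at(i, 0)] = -(open_cost + (i - 1) * gap_extend);
      tbX[at(i, 0)] = (i == 1) ? 0 : 1;
    }
    for (int j = 1; j <= m; ++j) {
      Iy[at(0, j)] = -(open_cost + (j - 1) * gap_extend);
      tbY[at(0, j)] = (j == 1) ? 0 : 2;
    }
  } else {
    for (int i = 0; i <= n; ++i) M[at(i, 0)] = 0.0;
    for (int j = 0; j <= m; ++j) M[at(0, j)] = 0.0;
  }

  double best = 0.0;
  int best_i = 0, best_j = 0;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = S(a[i - 1], b[j - 1]);
      // M state
      double dm = M[at(i - 1, j - 1)], dx = Ix[at(i - 1, j - 1)],
             dy = Iy[at(i - 1, j - 1)];
      int from = argmax3(dm, dx, dy);
      double base = (from == 0 ? dm : (from == 1 ? dx : dy));
      double mv = base + s;
      if (local && mv < 0.0) { mv = 0.0; from = 3; }
      if (local && base == NEG_INF) { mv = s > 0.0 ? s : 0.0; from = 3; }
      M[at(i, j)] = mv;
      tbM[at(i, j)] = (unsigned char)from;
      // Ix: gap in b, consume a[i-1]
      double xo = M[at(i - 1, j)] - open_cost;
      double xe = Ix[at(i - 1, j)] - gap_extend;
      double xy = Iy[at(i - 1, j)] - open_cost; // switch gap type: reopen
      if (xo >= xe && xo >= xy) { Ix[at(i, j)] = xo; tbX[at(i, j)] = 0; }
      else if (xe >= xy)        { Ix[at(i, j)] = xe; tbX[at(i, j)] = 1; }
      else                      { Ix[at(i, j)] = xy; tbX[at(i, j)] = 2; }
      // Iy: gap in a, consume b[j-1]
      double yo = M[at(i, j - 1)] - open_cost;
      double yx = Ix[at(i, j - 1)] - open_cost; // switch gap type: reopen
      double ye = Iy[at(i, j - 1)] - gap_extend;
      if (yo >= yx && yo >= ye) { Iy[at(i, j)] = yo; tbY[at(i, j)] = 0; }
      else if (yx >= ye)        { Iy[at(i, j)] = yx; tbY[at(i, j)] = 1; }
      else                      { Iy[at(i, j)] = ye; tbY[at(i, j)] = 2; }
      if (local && M[at(i, j)] > best) {
        best = M[at(i, j)];
        best_i = i; best_j = j;
      }
    }
  }

  DPResult res;
  int i, j, state;
  if (local) {
    res.score = best;
    i = best_i; j = best_j; state = 0;
    if (best <= 0.0) { // no positive-scoring local alignment
      res.score = 0.0;
      res.aligned_a = ""; res.aligned_b = "";
      res.a_start = res.a_end = 0; res.b_start = res.b_end = 0;
      return res;
    }
  } else {
    double fm = M[at(n, m)], fx = Ix[at(n, m)], fy = Iy[at(n, m)];
    state = argmax3(fm, fx, fy);
    res.score = (state == 0 ? fm : (state == 1 ? fx : fy));
    i = n; j = m;
  }

  std::string ra, rb;
  while (true) {
    if (local && state == 0 && tbM[at(i, j)] == 3 && M[at(i, j)] == 0.0) break;
    if (!local && i == 0 && j == 0) break;
    if (state == 0) {
      int from = tbM[at(i, j)];
      if (local && from == 3) {
        // alignment starts with this substitution
        ra += as<std::string>(letters[a[i - 1]]);
        rb += as<std::string>(letters[b[j - 1]]);
        --i; --j;
        break;
      }
      ra += as<std::string>(letters[a[i - 1]]);
      rb += as<std::string>(letters[b[j - 1]]);
      --i; --j;
      state = from;
    } else if (state == 1) {
      int from = tbX[at(i, j)];
      ra += as<std::string>(letters[a[i - 1]]);
      rb += "-";
      --i;
      state = from;
    } else {
      int from = tbY[at(i, j)];
      ra += "-";
      rb += as<std::string>(letters[b[j - 1]]);
      --j;
      state = from;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  res.aligned_a = ra; res.aligned_b = rb;
  if (local) {
    res.a_start = i; res.b_start = j;
    res.a_end = best_i; res.b_end = best_j;
  } else {
    res.a_start = 0; res.b_start = 0;
    res.a_end = n; res.b_end = m;
  }
  return res;
}

// [[Rcpp::export(name = ".cpp_align_pair")]]
List cpp_align_pair(IntegerVector a, IntegerVector b, NumericMatrix S,
                    double gap_open, double gap_extend, bool local,
                    CharacterVector letters) {
  DPResult r = align_core(a, b, S, gap_open, gap_extend, local, letters);
  return List::create(
      _["score"] = r.score, _["aligned_a"] = r.aligned_a,
      _["aligned_b"] = r.aligned_b,
      _["a_start"] = r.a_start, _["a_end"] = r.a_end,
      _["b_start"] = r.b_start, _["b_end"] = r.b_end);
}

// Score-only batch: one query against many subjects (local). Used by the
// homology search where tracebacks are only needed for reported hits.
// [[Rcpp::export(name = ".cpp_local_scores")]]
NumericVector cpp_local_scores(IntegerVector a, List subjects, NumericMatrix S,
                               double gap_open, double gap_extend) {
  const int n = a.size();
  const double open_cost = gap_open + gap_extend;
  NumericVector out(subjects.size());
  for (int k = 0; k < subjects.size(); ++k) {
    IntegerVector b = subjects[k];
    const int m = b.size();
    std::vector<double> Mp(m + 1, 0.0), Xp(m + 1, NEG_INF), Yp(m + 1, NEG_INF);
    std::vector<double> Mc(m + 1), Xc(m + 1), Yc(m + 1);
    double best = 0.0;
    for (int i = 1; i <= n; ++i) {
      Mc[0] = 0.0; Xc[0] = NEG_INF; Yc[0] = NEG_INF;
      for (int j = 1; j <= m; ++j) {
        const double s = S(a[i - 1], b[j - 1]);
        double diag = Mp[j - 1];
        if (Xp[j - 1] > diag) diag = Xp[j - 1];
        if (Yp[j - 1] > diag) diag = Yp[j - 1];
        double mv = diag + s;
        if (mv < 0.0) mv = 0.0;
        Mc[j] = mv;
        double xo = Mp[j] - open_cost, xe = Xp[j] - gap_extend,
               xy = Yp[j] - open_cost;
        double xv = xo > xe ? xo : xe;
        if (xy > xv) xv = xy;
        Xc[j] = xv;
        double yo = Mc[j - 1] - open_cost, yx = Xc[j - 1] - open_cost,
               ye = Yc[j - 1] - gap_extend;
        double yv = yo > yx ? yo : yx;
        if (ye > yv) yv = ye;
        Yc[j] = yv;
        if (Mc[j] > best) best = Mc[j];
      }
      std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
    }
    out[k] = best;
  }
  return out;
}
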