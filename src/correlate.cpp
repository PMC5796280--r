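#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Valid-mode cross-correlation: C(i,j) = sum_{x,y} t(x,y) * p(x+i, y+j).
// Offsets are 0-based; out(i+1, j+1) in R holds C(i,j).
// [[Rcpp::export]]
NumericMatrix cpp_cross_correlate(NumericMatrix p, NumericMatrix t) {
  const int W = p.nrow(), Z = p.ncol(), U = t.nrow(), V = t.ncol();
  if (U > W || V > Z) stop("template larger than image");
  NumericMatrix out(W - U + 1, Z - V + 1);
  for (int j = 0; j <= Z - V; ++j) {
    for (int i = 0; i <= W - U; ++i) {
      double s = 0.0;
      for (int y = 0; y < V; ++y) {
        const double *pc = &p(i, j + y);
        const double *tc = &t(0, y);
        for (int x = 0; x < U; ++x) s += tc[x] * pc[x];
      }
      out(i, j) = s;
    }
  }
  return out;
}

// Normalized cross-correlation (valid mode).  The window mean / sum of
// squares come from summed-area tables; for integer-valued inputs (8-bit
// frames, binary masks) those sums are exact in double precision.  Windows
// with zero intensity variance score 0 by convention.  The cross term is
// accumulated over the template's nonzero pixels only, which is exact and
// fast for sparse binary templates.
// [[Rcpp::export]]
NumericMatrix cpp_ncc(NumericMatrix p, NumericMatrix t) {
  const int W = p.nrow(), Z = p.ncol(), U = t.nrow(), V = t.ncol();
  if (U > W || V > Z) stop("template larger than image");
  const double n = (double)U * (double)V;

  double tsum = 0.0, tss = 0.0;
  std::vector<int> tx, ty;
  std::vector<double> tv;
  tx.reserve(U * V); ty.reserve(U * V); tv.reserve(U * V);
  for (int y = 0; y < V; ++y)
    for (int x = 0; x < U; ++x) {
      const double v = t(x, y);
      tsum += v;
      if (v != 0.0) { tx.push_back(x); ty.push_back(y); tv.push_back(v); }
    }
  const double tbar = tsum / n;
  for (int y = 0; y < V; ++y)
    for (int x = 0; x < U; ++x) {
      const double d = t(x, y) - tbar;
      tss += d * d;
    }
  if (tss <= 0.0) stop("constant template: normalized correlation undefined");

  // summed-area tables, (W+1) x (Z+1), first row/col zero
  std::vector<double> S1((W + 1) * (Z + 1), 0.0), S2((W + 1) * (Z + 1), 0.0);
  const int LD = W + 1;
  for (int j = 1; j <= Z; ++j)
    for (int i = 1; i <= W; ++i) {
      const double v = p(i - 1, j - 1);
      S1[i + j * LD] = v +     S1[(i - 1) + j * LD] + S1[i + (j - 1) * LD] - S1[(i - 1) + (j - 1) * LD];
      S2[i + j * LD] = v * v + S2[(i - 1) + j * LD] + S2[i + (j - 1) * LD] - S2[(i - 1) + (j - 1) * LD];
    }

  const size_t nt = tv.size();
  NumericMatrix out(W - U + 1, Z - V + 1);
  for (int j = 0; j <= Z - V; ++j) {
    for (int i = 0; i <= W - U; ++i) {
      const double s1 = S1[(i + U) + (j + V) * LD] - S1[i + (j + V) * LD]
                      - S1[(i + U) + j * LD] + S1[i + j * LD];
      const double s2 = S2[(i + U) + (j + V) * LD] - S2[i + (j + V) * LD]
                      - S2[(i + U) + j * LD] + S2[i + j * LD];
      const double varw = s2 - s1 * s1 / n;
      if (!(varw > 1e-12)) { out(i, j) = 0.0; continue; }
      double cross = 0.0;
      for (size_t k = 0; k < nt; ++k)
        cross += tv[k] * p(i + tx[k], j + ty[k]);
      double r = (cross - tbar * s1) / std::sqrt(tss * varw);
      if (r > 1.0) r = 1.0; else if (r < -1.0) r = -1.0;
      out(i, j) = r;
    }
  }
  return out;
}
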