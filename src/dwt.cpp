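#include <Rcpp.h>
using namespace Rcpp;

// Periodized orthogonal DWT analysis step on the rows of a channels x
// samples matrix: a[k] = sum_m lo[m] x[(2k+m) mod n], d likewise with hi.

// [[Rcpp::export]]
List dwt_step_cpp(NumericMatrix x, NumericVector lo, NumericVector hi) {
  const int nr = x.nrow(), n = x.ncol(), half = n / 2, L = lo.size();
  NumericMatrix a(nr, half), d(nr, half);
  const double *xp = REAL(x), *lp = REAL(lo), *hp = REAL(hi);
  double *ap = REAL(a), *dp = REAL(d);
  for (int k = 0; k < half; ++k) {
    double *acol = ap + (size_t)k * nr, *dcol = dp + (size_t)k * nr;
    for (int m = 0; m < L; ++m) {
      const int idx = (2 * k + m) % n;
      const double cl = lp[m], ch = hp[m];
      const double *xcol = xp + (size_t)idx * nr;
      for (int r = 0; r < nr; ++r) {
        acol[r] += cl * xcol[r];
        dcol[r] += ch * xcol[r];
      }
    }
  }
  return List::create(_["a"] = a, _["d"] = d);
}

// Transpose (= inverse, filters being orthonormal) of dwt_step_cpp.

// [[Rcpp::export]]
NumericMatrix idwt_step_cpp(NumericMatrix a, NumericMatrix d,
                            NumericVector lo, NumericVector hi) {
  const int nr = a.nrow(), half = a.ncol(), n = 2 * half, L = lo.size();
  NumericMatrix x(nr, n);
  const double *ap = REAL(a), *dp = REAL(d), *lp = REAL(lo), *hp = REAL(hi);
  double *xp = REAL(x);
  for (int k = 0; k < half; ++k) {
    const double *acol = ap + (size_t)k * nr, *dcol = dp + (size_t)k * nr;
    for (int m = 0; m < L; ++m) {
      const int idx = (2 * k + m) % n;
      const double cl = lp[m], ch = hp[m];
      double *xcol = xp + (size_t)idx * nr;
      for (int r = 0; r < nr; ++r)
        xcol[r] += acol[r] * cl + dcol[r] * ch;
    }
  }
  return x;
}
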