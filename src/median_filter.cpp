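#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Exact 2-D median filter with symmetric (edge-replicating mirror) padding,
// matching the boundary convention of the package's small-kernel
// convolutions.  Mirror indices are precomputed per axis and the window is
// gathered through raw column pointers.
// [[Rcpp::export]]
NumericMatrix median_filter_sym(NumericMatrix x, int radius) {
  const int nr = x.nrow(), nc = x.ncol();
  const int w = 2 * radius + 1, n = w * w;
  NumericMatrix out(nr, nc);
  const double *xp = x.begin();
  double *op = out.begin();

  std::vector<int> mi(nr + 2 * radius), mj(nc + 2 * radius);
  for (int i = 0; i < nr + 2 * radius; ++i) {
    int ii = i - radius;
    if (ii < 0) ii = -ii - 1;
    if (ii >= nr) ii = 2 * nr - ii - 1;
    mi[i] = ii;
  }
  for (int j = 0; j < nc + 2 * radius; ++j) {
    int jj = j - radius;
    if (jj < 0) jj = -jj - 1;
    if (jj >= nc) jj = 2 * nc - jj - 1;
    mj[j] = jj;
  }

  std::vector<double> buf(n);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int k = 0;
      for (int dj = 0; dj < w; ++dj) {
        const double *col = xp + (R_xlen_t)mj[j + dj] * nr;
        for (int di = 0; di < w; ++di) buf[k++] = col[mi[i + di]];
      }
      std::nth_element(buf.begin(), buf.begin() + n / 2, buf.end());
      op[(R_xlen_t)j * nr + i] = buf[n / 2];
    }
  }
  return out;
}
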