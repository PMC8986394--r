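#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// symmetric (mirror) boundary index: ... 2 1 0 | 0 1 2 ... n-1 | n-1 n-2 ...
static inline int reflect(int x, int n) {
  while (x < 0 || x >= n) {
    if (x < 0) x = -x - 1;
    if (x >= n) x = 2 * n - x - 1;
  }
  return x;
}

// Non-local means with exhaustive search. For each pixel, candidates are the
// in-image pixels of the (2*sr+1)^2 search window; patch distances use the
// mirror-padded image. Weights exp(-d2/h^2) with d2 the mean squared patch
// difference; the self weight is exp(0) = 1.
// [[Rcpp::export(name = ".nlm_cpp")]]
NumericMatrix nlm_cpp(NumericMatrix img, int pr, int sr, double h) {
  const int A = img.nrow(), B = img.ncol();
  NumericMatrix out(A, B);
  const int np = (2 * pr + 1) * (2 * pr + 1);
  const double h2 = h * h;
  for (int i = 0; i < A; ++i) {
    for (int j = 0; j < B; ++j) {
      double wsum = 0.0, vsum = 0.0;
      const int k0 = std::max(0, i - sr), k1 = std::min(A - 1, i + sr);
      const int l0 = std::max(0, j - sr), l1 = std::min(B - 1, j + sr);
      for (int k = k0; k <= k1; ++k) {
        for (int l = l0; l <= l1; ++l) {
          double d2 = 0.0;
          for (int p = -pr; p <= pr; ++p) {
            const int ip = reflect(i + p, A), kp = reflect(k + p, A);
            for (int q = -pr; q <= pr; ++q) {
              const double diff = img(ip, reflect(j + q, B)) -
                                  img(kp, reflect(l + q, B));
              d2 += diff * diff;
            }
          }
          const double w = std::exp(-(d2 / np) / h2);
          wsum += w;
          vsum += w * img(k, l);
        }
      }
      out(i, j) = vsum / wsum;
    }
  }
  return out;
}
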