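#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Square-window median filter with edge replication: out-of-image window
// samples take the nearest edge pixel. Window must be odd.
// [[Rcpp::export]]
NumericMatrix median_filter_replicate(NumericMatrix x, int window) {
  const int nr = x.nrow(), nc = x.ncol(), h = window / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf(window * window);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int k = 0;
      for (int dj = -h; dj <= h; ++dj) {
        int cj = std::min(std::max(j + dj, 0), nc - 1);
        for (int di = -h; di <= h; ++di) {
          int ci = std::min(std::max(i + di, 0), nr - 1);
          buf[k++] = x(ci, cj);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + k / 2, buf.begin() + k);
      double med = buf[k / 2];
      if (k % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + k / 2);
        med = 0.5 * (lo + med);
      }
      out(i, j) = med;
    }
  }
  return out;
}
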