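#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Sliding-window 2-D median filter (Huang's histogram algorithm with a
// 256-bin coarse level over a 65536-bin fine histogram).
//
// The window is a (2r+1) x (2r+1) square clamped to the image at the
// borders, so border estimates use the available (possibly even-sized)
// neighbourhood; the median of an even count is the mean of the two middle
// order statistics, matching stats::median().
//
// Intensities are quantized onto 65536 levels spanning the image range, so
// the result can deviate from the exact floating-point median by at most
// range/131070 (half a quantization step) -- well below one camera gray
// level for 16-bit data.
// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix img, int window) {
  if (window < 1 || window % 2 == 0)
    stop("window must be a positive odd integer");
  const int nr = img.nrow(), nc = img.ncol();
  if (window >= nr || window >= nc)
    stop("window must be smaller than both image dimensions");
  const int r = window / 2;
  NumericMatrix out(nr, nc);

  double mn = img(0, 0), mx = img(0, 0);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      const double v = img(i, j);
      if (!R_finite(v)) stop("image must be finite");
      if (v < mn) mn = v;
      if (v > mx) mx = v;
    }
  if (mx == mn) {
    std::fill(out.begin(), out.end(), mn);
    return out;
  }
  const double scale = 65535.0 / (mx - mn);
  std::vector<uint16_t> q((size_t)nr * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      long v = std::lround((img(i, j) - mn) * scale);
      if (v < 0) v = 0;
      if (v > 65535) v = 65535;
      q[(size_t)j * nr + i] = (uint16_t)v;
    }

  std::vector<int> fine(65536), coarse(256);

  for (int i = 0; i < nr; ++i) {
    const int i0 = std::max(0, i - r), i1 = std::min(nr - 1, i + r);
    std::memset(fine.data(), 0, fine.size() * sizeof(int));
    std::memset(coarse.data(), 0, coarse.size() * sizeof(int));
    int jlo = 0, jhi = std::min(nc - 1, r);
    int n = 0;
    for (int jj = jlo; jj <= jhi; ++jj)
      for (int ii = i0; ii <= i1; ++ii) {
        const uint16_t v = q[(size_t)jj * nr + ii];
        ++fine[v]; ++coarse[v >> 8]; ++n;
      }
    for (int j = 0; j < nc; ++j) {
      if (j > 0) {
        const int njlo = std::max(0, j - r), njhi = std::min(nc - 1, j + r);
        if (njlo > jlo) { // drop leftmost column strip
          for (int ii = i0; ii <= i1; ++ii) {
            const uint16_t v = q[(size_t)jlo * nr + ii];
            --fine[v]; --coarse[v >> 8]; --n;
          }
        }
        if (njhi > jhi) { // add rightmost column strip
          for (int ii = i0; ii <= i1; ++ii) {
            const uint16_t v = q[(size_t)njhi * nr + ii];
            ++fine[v]; ++coarse[v >> 8]; ++n;
          }
        }
        jlo = njlo; jhi = njhi;
      }
      // k-th (0-based) order statistics k1 = (n-1)/2 and k2 = n/2
      const int k1 = (n - 1) / 2, k2 = n / 2;
      int acc = 0, cb = 0;
      while (acc + coarse[cb] <= k1) acc += coarse[cb++];
      int v1 = cb << 8;
      while (acc + fine[v1] <= k1) acc += fine[v1++];
      int v2 = v1;
      if (k2 > k1) { // even count: also need the next order statistic
        int acc2 = acc + fine[v1];
        if (acc2 > k2) v2 = v1;
        else {
          v2 = v1 + 1;
          int cb2 = cb;
          // continue scan from v1
          while (true) {
            if ((v2 >> 8) != cb2 && fine[v2] == 0) {
              // skip empty fine bins quickly via coarse level
              cb2 = v2 >> 8;
              while (coarse[cb2] == 0) { ++cb2; }
              if (cb2 > (v2 >> 8)) v2 = cb2 << 8;
            }
            if (fine[v2] > 0) break;
            ++v2;
          }
        }
      }
      out(i, j) = mn + 0.5 * ((double)v1 + (double)v2) / scale;
    }
  }
  return out;
}
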