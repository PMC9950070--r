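#include <Rcpp.h>
using namespace Rcpp;

// Exact rectangular-window local median via a sliding 256-bin histogram
// (Huang's algorithm). The input is a matrix of integer levels in 0..255,
// already padded by (ry, rx) on each side with replicated edge values
// (quantisation happens on the R side so thresholding can compare on the
// same grid). Returns the lower-median level of each (2*ry+1) x (2*rx+1)
// window on the original (unpadded) grid.
// [[Rcpp::export]]
IntegerMatrix local_median_cpp(IntegerMatrix padded, int ry, int rx) {
  const int hp = padded.nrow(), wp = padded.ncol();
  const int h = hp - 2 * ry, w = wp - 2 * rx;
  if (h < 1 || w < 1) stop("padded image smaller than window");
  const int wy = 2 * ry + 1, wx = 2 * rx + 1;
  const int n = wy * wx;
  const int half = n / 2 + 1;  // rank of the lower median

  std::vector<unsigned char> q((size_t)hp * wp);
  for (int j = 0; j < wp; ++j)
    for (int i = 0; i < hp; ++i) {
      int v = padded(i, j);
      if (v < 0) v = 0; else if (v > 255) v = 255;
      q[(size_t)j * hp + i] = (unsigned char)v;
    }

  IntegerMatrix out(h, w);
  std::vector<int> hist(256);

  for (int cx = 0; cx < w; ++cx) {
    std::fill(hist.begin(), hist.end(), 0);
    for (int j = cx; j < cx + wx; ++j)
      for (int i = 0; i < wy; ++i)
        ++hist[q[(size_t)j * hp + i]];
    for (int cy = 0; cy < h; ++cy) {
      if (cy > 0) {
        const int rem = cy - 1, add = cy - 1 + wy;
        for (int j = cx; j < cx + wx; ++j) {
          --hist[q[(size_t)j * hp + rem]];
          ++hist[q[(size_t)j * hp + add]];
        }
      }
      int cum = 0, lev = 0;
      for (; lev < 256; ++lev) {
        cum += hist[lev];
        if (cum >= half) break;
      }
      out(cy, cx) = lev;
    }
  }
  return out;
}
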