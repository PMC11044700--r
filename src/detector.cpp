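// Pooled patch features for the single-stage grid detector: for each
// candidate cell centre, block means of a square patch plus signed
// horizontal and vertical extent profiles (band means to the right, left,
// below and above the centre). For disc/ellipse-like objects the profiles
// carry the size almost linearly and their left/right (up/down) asymmetry
// encodes the centre offset.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// image: H x W matrix (rows = y, cols = x), pixel coords 0-based.
// cx, cy: centre coordinates (x = column, y = row).
// patch: side of the square patch (multiple of block); block: pooling side.
// profBins bands of width profStep along each axis, band half-height profBand.
// Out-of-image pixels contribute 0 with a fixed denominator so features are
// comparable across positions.
// [[Rcpp::export(name = ".grid_features")]]
arma::mat grid_features_cpp(const arma::mat& image,
                            const arma::vec& cx, const arma::vec& cy,
                            int patch, int block,
                            int profBins, double profStep, int profBand) {
  const int H = image.n_rows, W = image.n_cols;
  const int nb = patch / block;
  const int nfeat = nb * nb + 4 * profBins;
  const int n = cx.n_elem;
  mat out(n, nfeat, fill::zeros);

  for (int i = 0; i < n; ++i) {
    const double x0 = cx(i), y0 = cy(i);
    const int px0 = (int)std::lround(x0) - patch / 2;
    const int py0 = (int)std::lround(y0) - patch / 2;
    // block means
    for (int by = 0; by < nb; ++by) {
      for (int bx = 0; bx < nb; ++bx) {
        double s = 0.0;
        for (int dy = 0; dy < block; ++dy) {
          const int r = py0 + by * block + dy;
          if (r < 0 || r >= H) continue;
          for (int dx = 0; dx < block; ++dx) {
            const int c = px0 + bx * block + dx;
            if (c < 0 || c >= W) continue;
            s += image(r, c);
          }
        }
        out(i, by * nb + bx) = s / (block * block);
      }
    }
    // signed profiles: band means over dx (dy) in [k*step, (k+1)*step)
    // right/left of (below/above) the centre, |dy| (|dx|) <= band
    const int icx = (int)std::lround(x0), icy = (int)std::lround(y0);
    for (int k = 0; k < profBins; ++k) {
      const int lo = (int)std::floor(k * profStep);
      const int hi = (int)std::floor((k + 1) * profStep);
      double sxp = 0.0, sxm = 0.0, syp = 0.0, sym = 0.0;
      int denom = 0;
      for (int d = lo; d < hi; ++d) {
        for (int b = -profBand; b <= profBand; ++b) {
          denom += 1;
          int r = icy + b;
          if (r >= 0 && r < H) {
            int c1 = icx + d, c2 = icx - d - 1;
            if (c1 >= 0 && c1 < W) sxp += image(r, c1);
            if (c2 >= 0 && c2 < W) sxm += image(r, c2);
          }
          int c = icx + b;
          if (c >= 0 && c < W) {
            int r1 = icy + d, r2 = icy - d - 1;
            if (r1 >= 0 && r1 < H) syp += image(r1, c);
            if (r2 >= 0 && r2 < H) sym += image(r2, c);
          }
        }
      }
      out(i, nb * nb + k) = sxp / denom;
      out(i, nb * nb + profBins + k) = sxm / denom;
      out(i, nb * nb + 2 * profBins + k) = syp / denom;
      out(i, nb * nb + 3 * profBins + k) = sym / denom;
    }
  }
  return out;
}
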