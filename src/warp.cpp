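#include <Rcpp.h>
using namespace Rcpp;

// Bilinear resampling of `img` onto an outH x outW grid.
// `minv` is a 2x3 matrix mapping output-frame continuous coordinates
// (x = col, y = row, 0-based, pixel centres at integers) to input-frame
// coordinates: (xs, ys) = A (x, y)' + t. Samples falling outside the
// input grid are set to `fill` (may be NA).
// [[Rcpp::export]]
NumericMatrix warp_image_bilinear(NumericMatrix img, NumericMatrix minv,
                                  int outH, int outW, double fill) {
  const int H = img.nrow(), W = img.ncol();
  const double a11 = minv(0, 0), a12 = minv(0, 1), tx = minv(0, 2);
  const double a21 = minv(1, 0), a22 = minv(1, 1), ty = minv(1, 2);
  NumericMatrix out(outH, outW);
  for (int c = 0; c < outW; ++c) {
    const double x = (double)c;
    for (int r = 0; r < outH; ++r) {
      const double y = (double)r;
      const double xs = a11 * x + a12 * y + tx;
      const double ys = a21 * x + a22 * y + ty;
      if (xs < 0.0 || ys < 0.0 || xs > (double)(W - 1) || ys > (double)(H - 1)) {
        out(r, c) = fill;
        continue;
      }
      int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys);
      if (x0 == W - 1) --x0;  // clamp so x0+1 stays in range (xs == W-1)
      if (y0 == H - 1) --y0;
      if (W == 1) x0 = 0;
      if (H == 1) y0 = 0;
      const double fx = xs - x0, fy = ys - y0;
      const int x1 = (W == 1) ? x0 : x0 + 1;
      const int y1 = (H == 1) ? y0 : y0 + 1;
      const double v00 = img(y0, x0), v01 = img(y0, x1);
      const double v10 = img(y1, x0), v11 = img(y1, x1);
      out(r, c) = (1 - fy) * ((1 - fx) * v00 + fx * v01) +
                  fy * ((1 - fx) * v10 + fx * v11);
    }
  }
  return out;
}

// Normalised cross-correlation between two equally sized matrices,
// ignoring positions where either value is NA. Returns the correlation
// and the fraction of positions used, as a length-2 vector.
// [[Rcpp::export]]
NumericVector ncc_masked(NumericMatrix a, NumericMatrix b) {
  const int n = a.size();
  double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
  int m = 0;
  for (int i = 0; i < n; ++i) {
    const double x = a[i], y = b[i];
    if (NumericVector::is_na(x) || NumericVector::is_na(y)) continue;
    sa += x; sb += y; saa += x * x; sbb += y * y; sab += x * y;
    ++m;
  }
  NumericVector out(2);
  if (m < 2) { out[0] = NA_REAL; out[1] = 0.0; return out; }
  const double va = saa - sa * sa / m, vb = sbb - sb * sb / m;
  if (va <= 0 || vb <= 0) { out[0] = NA_REAL; out[1] = (double)m / n; return out; }
  out[0] = (sab - sa * sb / m) / std::sqrt(va * vb);
  out[1] = (double)m / n;
  return out;
}
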