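#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bilinear affine resampling with zero padding.
//
// Forward map (applied to points in pixel coordinates, x = column,
// y = row, origin at the image centre):
//   p' = scale * R(rot_deg) * p + (dx, dy)
// The warped image W satisfies W(q) = img(T^{-1}(q)), so warping an image
// by T moves its features the way T moves points.

// [[Rcpp::export(name = ".warp_affine")]]
NumericMatrix warp_affine(NumericMatrix img, double rot_deg, double dx,
                          double dy, double scale) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  const double *src = REAL(img);
  double *dst = REAL(out);
  const double cx = (W + 1) / 2.0, cy = (H + 1) / 2.0;
  const double th = rot_deg * M_PI / 180.0;
  const double c = std::cos(th) / scale, s = std::sin(th) / scale;
  // inverse map: p = R(-th) * (q - t) / scale
  for (int col = 0; col < W; ++col) {
    const double qx = (col + 1) - cx - dx;
    for (int r = 0; r < H; ++r) {
      const double qy = (r + 1) - cy - dy;
      const double px = c * qx + s * qy + cx;
      const double py = -s * qx + c * qy + cy;
      const int x0 = (int)std::floor(px), y0 = (int)std::floor(py);
      double v = 0.0;
      if (x0 >= 1 && x0 < W && y0 >= 1 && y0 < H) {  // fully interior
        const double fx = px - x0, fy = py - y0;
        const double *col0 = src + (size_t)(x0 - 1) * H + (y0 - 1);
        const double *col1 = col0 + H;
        v = (1 - fx) * ((1 - fy) * col0[0] + fy * col0[1]) +
            fx * ((1 - fy) * col1[0] + fy * col1[1]);
      } else if (x0 >= 0 && x0 <= W && y0 >= 0 && y0 <= H) {  // border
        const double fx = px - x0, fy = py - y0;
        for (int j = 0; j <= 1; ++j) {
          for (int i2 = 0; i2 <= 1; ++i2) {
            const int xx = x0 + i2, yy = y0 + j;
            if (xx >= 1 && xx <= W && yy >= 1 && yy <= H) {
              const double wgt = (i2 ? fx : 1 - fx) * (j ? fy : 1 - fy);
              v += wgt * src[(size_t)(xx - 1) * H + (yy - 1)];
            }
          }
        }
      }
      dst[(size_t)col * H + r] = v;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".frob_dist")]]
double frob_dist(NumericMatrix a, NumericMatrix b) {
  if (a.nrow() != b.nrow() || a.ncol() != b.ncol())
    stop("image shape mismatch");
  const double *pa = REAL(a), *pb = REAL(b);
  double acc = 0.0;
  const R_xlen_t n = (R_xlen_t)a.nrow() * a.ncol();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double d = pa[i] - pb[i];
    acc += d * d;
  }
  return std::sqrt(acc);
}
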