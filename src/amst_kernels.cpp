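#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Pixel coordinate convention used throughout: x = column index, y = row
// index, both 0-based, origin at the centre of the top-left pixel.
// R matrices are (row, col) = (y, x).

static inline bool sample_bilinear(const NumericMatrix &img, double u, double v,
                                   double &out) {
  // u: x (column), v: y (row); valid domain [0, W-1] x [0, H-1]
  const int H = img.nrow(), W = img.ncol();
  if (u < 0.0 || v < 0.0 || u > W - 1.0 || v > H - 1.0) return false;
  int x0 = (int)std::floor(u);
  int y0 = (int)std::floor(v);
  if (x0 >= W - 1) x0 = W - 2;
  if (y0 >= H - 1) y0 = H - 2;
  if (W == 1) x0 = 0;
  if (H == 1) y0 = 0;
  const int x1 = std::min(x0 + 1, W - 1);
  const int y1 = std::min(y0 + 1, H - 1);
  const double fx = u - x0, fy = v - y0;
  const double i00 = img(y0, x0), i01 = img(y0, x1);
  const double i10 = img(y1, x0), i11 = img(y1, x1);
  out = (1.0 - fy) * ((1.0 - fx) * i00 + fx * i01) +
        fy * ((1.0 - fx) * i10 + fx * i11);
  return true;
}

// Backward affine warp per T(x) = A (x - c) + t + c:
// output(x) = bilinear sample of img at T(x); out-of-domain -> fill.
// [[Rcpp::export]]
NumericMatrix warp_affine_cpp(const NumericMatrix &img, const NumericVector &mu,
                              double cx, double cy, double fill) {
  const int H = img.nrow(), W = img.ncol();
  const double a11 = mu[0], a12 = mu[1], a21 = mu[2], a22 = mu[3];
  const double tx = mu[4], ty = mu[5];
  NumericMatrix out(H, W);
  for (int x = 0; x < W; ++x) {
    const double dx = x - cx;
    for (int y = 0; y < H; ++y) {
      const double dy = y - cy;
      const double u = a11 * dx + a12 * dy + tx + cx;
      const double v = a21 * dx + a22 * dy + ty + cy;
      double s;
      out(y, x) = sample_bilinear(img, u, v, s) ? s : fill;
    }
  }
  return out;
}

// Mutual information (bits) between `fixed` and `moving` warped through
// T(x) = A (x - c) + t + c, from a joint histogram with linear
// (partial-volume) bin contributions. Only pixels whose warped sample
// falls inside the moving image domain contribute. Intensities are
// min-max scaled with the supplied ranges before binning.
// [[Rcpp::export]]
double mi_affine_cpp(const NumericMatrix &fixed, const NumericMatrix &moving,
                     const NumericVector &mu, double cx, double cy, int bins,
                     double fmin, double fmax, double mmin, double mmax) {
  const int H = fixed.nrow(), W = fixed.ncol();
  const double a11 = mu[0], a12 = mu[1], a21 = mu[2], a22 = mu[3];
  const double tx = mu[4], ty = mu[5];
  const double fscale = (fmax > fmin) ? (bins - 1) / (fmax - fmin) : 0.0;
  const double mscale = (mmax > mmin) ? (bins - 1) / (mmax - mmin) : 0.0;
  std::vector<double> joint((size_t)bins * bins, 0.0);
  double total = 0.0;
  for (int x = 0; x < W; ++x) {
    const double dx = x - cx;
    for (int y = 0; y < H; ++y) {
      const double dy = y - cy;
      const double u = a11 * dx + a12 * dy + tx + cx;
      const double v = a21 * dx + a22 * dy + ty + cy;
      double mval;
      if (!sample_bilinear(moving, u, v, mval)) continue;
      double zf = (fixed(y, x) - fmin) * fscale;
      double zm = (mval - mmin) * mscale;
      if (zf < 0.0) zf = 0.0;
      if (zm < 0.0) zm = 0.0;
      if (zf > bins - 1.0) zf = bins - 1.0;
      if (zm > bins - 1.0) zm = bins - 1.0;
      int bf = (int)zf, bm = (int)zm;
      if (bf >= bins - 1) bf = bins - 2;
      if (bm >= bins - 1) bm = bins - 2;
      if (bins == 1) bf = bm = 0;
      double wf = zf - bf, wm = zm - bm;
      if (bins == 1) { wf = 0.0; wm = 0.0; }
      const int bf1 = std::min(bf + 1, bins - 1);
      const int bm1 = std::min(bm + 1, bins - 1);
      joint[(size_t)bf + (size_t)bins * bm] += (1.0 - wf) * (1.0 - wm);
      joint[(size_t)bf1 + (size_t)bins * bm] += wf * (1.0 - wm);
      joint[(size_t)bf + (size_t)bins * bm1] += (1.0 - wf) * wm;
      joint[(size_t)bf1 + (size_t)bins * bm1] += wf * wm;
      total += 1.0;
    }
  }
  if (total <= 0.0) return 0.0;
  std::vector<double> pf(bins, 0.0), pm(bins, 0.0);
  for (int j = 0; j < bins; ++j)
    for (int i = 0; i < bins; ++i) {
      const double p = joint[(size_t)i + (size_t)bins * j] / total;
      pf[i] += p;
      pm[j] += p;
    }
  double mi = 0.0;
  const double log2_ = std::log(2.0);
  for (int j = 0; j < bins; ++j)
    for (int i = 0; i < bins; ++i) {
      const double p = joint[(size_t)i + (size_t)bins * j] / total;
      if (p > 0.0 && pf[i] > 0.0 && pm[j] > 0.0)
        mi += p * std::log(p / (pf[i] * pm[j])) / log2_;
    }
  return mi;
}

// z-axis median filter with a clipped (shrinking) window at the stack
// ends; lower median for even window counts. vol has dim (H, W, Z).
// [[Rcpp::export]]
NumericVector zmedian_cpp(const NumericVector &vol, int H, int W, int Z,
                          int window) {
  NumericVector out((R_xlen_t)H * W * Z);
  const int hw = window / 2;
  std::vector<double> buf(window);
  const R_xlen_t plane = (R_xlen_t)H * W;
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      const R_xlen_t base = (R_xlen_t)h + (R_xlen_t)H * w;
      for (int z = 0; z < Z; ++z) {
        const int z0 = std::max(0, z - hw);
        const int z1 = std::min(Z - 1, z + hw);
        const int n = z1 - z0 + 1;
        for (int k = 0; k < n; ++k) buf[k] = vol[base + plane * (z0 + k)];
        const int mid = (n - 1) / 2;  // lower median for even n
        std::nth_element(buf.begin(), buf.begin() + mid, buf.begin() + n);
        out[base + plane * z] = buf[mid];
      }
    }
  }
  return out;
}

// Normalized cross-correlation of a template against an image over a
// rectangle of integer top-left placements [x0, x1] x [y0, y1] (0-based).
// Returns a matrix with rows indexing y placements, cols indexing x.
// A zero-variance window yields NA at that placement.
// [[Rcpp::export]]
NumericMatrix ncc_search_cpp(const NumericMatrix &img, const NumericMatrix &tpl,
                             int x0, int x1, int y0, int y1) {
  const int th = tpl.nrow(), tw = tpl.ncol();
  const int ny = y1 - y0 + 1, nx = x1 - x0 + 1;
  const double n = (double)th * tw;
  double tmean = 0.0;
  for (int j = 0; j < tw; ++j)
    for (int i = 0; i < th; ++i) tmean += tpl(i, j);
  tmean /= n;
  double tss = 0.0;
  NumericMatrix tc(th, tw);
  for (int j = 0; j < tw; ++j)
    for (int i = 0; i < th; ++i) {
      tc(i, j) = tpl(i, j) - tmean;
      tss += tc(i, j) * tc(i, j);
    }
  NumericMatrix out(ny, nx);
  for (int px = 0; px < nx; ++px) {
    const int xo = x0 + px;
    for (int py = 0; py < ny; ++py) {
      const int yo = y0 + py;
      double ws = 0.0, wss = 0.0, cross = 0.0;
      for (int j = 0; j < tw; ++j)
        for (int i = 0; i < th; ++i) {
          const double v = img(yo + i, xo + j);
          ws += v;
          wss += v * v;
          cross += v * tc(i, j);
        }
      const double wvar = wss - ws * ws / n;
      if (wvar <= 0.0 || tss <= 0.0) {
        out(py, px) = NA_REAL;
      } else {
        // cross already uses centred template, so window mean cancels
        out(py, px) = cross / std::sqrt(wvar * tss);
      }
    }
  }
  return out;
}

// Separable Gaussian blur, kernel radius ceil(3 sigma), mirrored edges.
// [[Rcpp::export]]
NumericMatrix gauss_blur_cpp(const NumericMatrix &img, double sigma) {
  const int H = img.nrow(), W = img.ncol();
  if (sigma <= 0.0) return clone(img);
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double ks = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    ks += k[i + r];
  }
  for (int i = 0; i <= 2 * r; ++i) k[i] /= ks;
  NumericMatrix tmp(H, W), out(H, W);
  // rows direction (along y)
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      double s = 0.0;
      for (int i = -r; i <= r; ++i) {
        int yy = y + i;
        if (yy < 0) yy = -yy;
        if (yy > H - 1) yy = 2 * (H - 1) - yy;
        if (yy < 0) yy = 0;  // degenerate H==1
        s += k[i + r] * img(yy, x);
      }
      tmp(y, x) = s;
    }
  // cols direction (along x)
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      double s = 0.0;
      for (int i = -r; i <= r; ++i) {
        int xx = x + i;
        if (xx < 0) xx = -xx;
        if (xx > W - 1) xx = 2 * (W - 1) - xx;
        if (xx < 0) xx = 0;
        s += k[i + r] * tmp(y, xx);
      }
      out(y, x) = s;
    }
  return out;
}
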