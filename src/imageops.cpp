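// Raster helpers for the synthetic-carapace renderer and the augmentation
// module. Images are R arrays dim (H, W, C) in [0, 255]; pixel (r, c)
// (0-based) has continuous coordinates (x = c, y = r) at its centre.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Even-odd polygon rasterisation at pixel centres.
// [[Rcpp::export]]
LogicalMatrix rasterize_polygon_cpp(int h, int w, NumericVector xs,
                                    NumericVector ys) {
  const int nv = xs.size();
  LogicalMatrix mask(h, w);
  std::vector<double> cross;
  for (int r = 0; r < h; ++r) {
    const double y = r;
    cross.clear();
    for (int i = 0; i < nv; ++i) {
      const int j = (i + 1) % nv;
      const double y1 = ys[i], y2 = ys[j];
      if ((y1 <= y && y2 > y) || (y2 <= y && y1 > y)) {
        const double t = (y - y1) / (y2 - y1);
        cross.push_back(xs[i] + t * (xs[j] - xs[i]));
      }
    }
    std::sort(cross.begin(), cross.end());
    for (size_t k = 0; k + 1 < cross.size(); k += 2) {
      int c0 = (int)std::ceil(cross[k]);
      int c1 = (int)std::floor(cross[k + 1]);
      if (c0 < 0) c0 = 0;
      if (c1 > w - 1) c1 = w - 1;
      for (int c = c0; c <= c1; ++c) mask(r, c) = true;
    }
  }
  return mask;
}

static void blur_1d(const double* src, double* dst, int n, int stride,
                    const std::vector<double>& k) {
  const int r = (int)k.size() / 2;
  for (int i = 0; i < n; ++i) {
    double acc = 0;
    for (int t = -r; t <= r; ++t) {
      int j = i + t;
      if (j < 0) j = -j;                 // reflect
      if (j > n - 1) j = 2 * (n - 1) - j;
      acc += k[t + r] * src[(size_t)j * stride];
    }
    dst[(size_t)i * stride] = acc;
  }
}

// Separable Gaussian blur with reflective boundaries; sigma in pixels.
// [[Rcpp::export]]
NumericVector gaussian_blur_cpp(NumericVector img, double sigma) {
  IntegerVector dim = img.attr("dim");
  const int h = dim[0], w = dim[1], nc = dim.size() > 2 ? dim[2] : 1;
  if (sigma <= 0) return clone(img);
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int t = -r; t <= r; ++t) {
    k[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += k[t + r];
  }
  for (auto& v : k) v /= s;
  NumericVector out = clone(img);
  std::vector<double> tmp((size_t)h * w);
  for (int c = 0; c < nc; ++c) {
    double* plane = REAL(out) + (size_t)c * h * w;
    // columns (along rows, stride 1)
    for (int j = 0; j < w; ++j)
      blur_1d(plane + (size_t)j * h, tmp.data() + (size_t)j * h, h, 1, k);
    // rows (stride h)
    for (int i = 0; i < h; ++i)
      blur_1d(tmp.data() + i, plane + i, w, h, k);
  }
  return out;
}

// Rotate image about its centre ((w-1)/2, (h-1)/2) by angle radians
// (positive = counter-clockwise in the x-right / y-down pixel frame, i.e.
// visually clockwise). Bilinear resampling; exposed canvas takes `fill`.
// [[Rcpp::export]]
NumericVector rotate_image_cpp(NumericVector img, double angle,
                               NumericVector fill) {
  IntegerVector dim = img.attr("dim");
  const int h = dim[0], w = dim[1], nc = dim.size() > 2 ? dim[2] : 1;
  NumericVector out(img.size());
  out.attr("dim") = dim;
  const double cx = (w - 1) / 2.0, cy = (h - 1) / 2.0;
  const double ca = std::cos(angle), sa = std::sin(angle);
  const double* src = REAL(img);
  double* dst = REAL(out);
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      // inverse map: source coords of output pixel (x=j, y=i)
      const double dx = j - cx, dy = i - cy;
      const double sx = cx + ca * dx + sa * dy;
      const double sy = cy - sa * dx + ca * dy;
      if (sx < 0 || sx > w - 1 || sy < 0 || sy > h - 1) {
        for (int c = 0; c < nc; ++c)
          dst[i + (size_t)j * h + (size_t)c * h * w] =
              fill[c < fill.size() ? c : 0];
        continue;
      }
      const int x0 = std::min((int)std::floor(sx), w - 2 < 0 ? 0 : w - 2);
      const int y0 = std::min((int)std::floor(sy), h - 2 < 0 ? 0 : h - 2);
      const double fx = sx - x0, fy = sy - y0;
      for (int c = 0; c < nc; ++c) {
        const double* p = src + (size_t)c * h * w;
        const double v =
            (1 - fy) * ((1 - fx) * p[y0 + (size_t)x0 * h] +
                        fx * p[y0 + (size_t)(x0 + 1) * h]) +
            fy * ((1 - fx) * p[y0 + 1 + (size_t)x0 * h] +
                  fx * p[y0 + 1 + (size_t)(x0 + 1) * h]);
        dst[i + (size_t)j * h + (size_t)c * h * w] = v;
      }
    }
  }
  return out;
}

// Unnormalised Gaussian heatmaps, one channel per landmark, peak value 1 at
// the landmark; out-of-frame landmarks give all-zero channels.
// coords: n x 2 matrix of pixel coordinates (x = column, y = row, 0-based).
// [[Rcpp::export]]
NumericVector render_heatmaps_cpp(NumericMatrix coords, int h, int w,
                                  double sigma) {
  const int n = coords.nrow();
  NumericVector out((size_t)h * w * n);
  out.attr("dim") = IntegerVector::create(h, w, n);
  double* o = REAL(out);
  const double s2 = 2.0 * sigma * sigma;
  for (int p = 0; p < n; ++p) {
    const double cx = coords(p, 0), cy = coords(p, 1);
    if (!std::isfinite(cx) || !std::isfinite(cy)) continue;
    if (cx < 0 || cx > w - 1 || cy < 0 || cy > h - 1) continue;
    double* plane = o + (size_t)p * h * w;
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i) {
        const double dx = j - cx, dy = i - cy;
        plane[i + (size_t)j * h] = std::exp(-(dx * dx + dy * dy) / s2);
      }
  }
  return out;
}

// Distance from every pixel centre in a window to a polyline; used to draw
// the neck groove as a soft dark stroke.
// [[Rcpp::export]]
NumericMatrix polyline_distance_cpp(int h, int w, NumericVector xs,
                                    NumericVector ys, double max_dist) {
  NumericMatrix d(h, w);
  std::fill(d.begin(), d.end(), max_dist);
  const int ns = xs.size() - 1;
  for (int s = 0; s < ns; ++s) {
    const double x1 = xs[s], y1 = ys[s], x2 = xs[s + 1], y2 = ys[s + 1];
    const double vx = x2 - x1, vy = y2 - y1;
    const double len2 = vx * vx + vy * vy;
    const int j0 = std::max(0, (int)std::floor(std::min(x1, x2) - max_dist));
    const int j1 = std::min(w - 1, (int)std::ceil(std::max(x1, x2) + max_dist));
    const int i0 = std::max(0, (int)std::floor(std::min(y1, y2) - max_dist));
    const int i1 = std::min(h - 1, (int)std::ceil(std::max(y1, y2) + max_dist));
    for (int j = j0; j <= j1; ++j)
      for (int i = i0; i <= i1; ++i) {
        double t = len2 > 0 ? ((j - x1) * vx + (i - y1) * vy) / len2 : 0.0;
        t = std::min(1.0, std::max(0.0, t));
        const double px = x1 + t * vx, py = y1 + t * vy;
        const double dist = std::hypot(j - px, i - py);
        if (dist < d(i, j)) d(i, j) = dist;
      }
  }
  return d;
}
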