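#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Bilinear sample with border clamping. y = row, x = col (0-based).
static inline double sample_bilinear(const NumericMatrix& img, double y, double x) {
  int h = img.nrow(), w = img.ncol();
  if (y < 0) y = 0; if (y > h - 1) y = h - 1;
  if (x < 0) x = 0; if (x > w - 1) x = w - 1;
  int y0 = (int)std::floor(y), x0 = (int)std::floor(x);
  int y1 = y0 + 1 < h ? y0 + 1 : y0;
  int x1 = x0 + 1 < w ? x0 + 1 : x0;
  double fy = y - y0, fx = x - x0;
  return (1 - fy) * ((1 - fx) * img(y0, x0) + fx * img(y0, x1)) +
         fy       * ((1 - fx) * img(y1, x0) + fx * img(y1, x1));
}

// [[Rcpp::export(name = ".cpp_warp")]]
NumericMatrix cpp_warp(NumericMatrix img, NumericMatrix dx, NumericMatrix dy) {
  int h = img.nrow(), w = img.ncol();
  NumericMatrix out(h, w);
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i)
      out(i, j) = sample_bilinear(img, i + dy(i, j), j + dx(i, j));
  return out;
}

static NumericMatrix downsample2(const NumericMatrix& img) {
  int h = img.nrow() / 2, w = img.ncol() / 2;
  NumericMatrix out(h, w);
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i)
      out(i, j) = 0.25 * (img(2 * i, 2 * j) + img(2 * i + 1, 2 * j) +
                          img(2 * i, 2 * j + 1) + img(2 * i + 1, 2 * j + 1));
  return out;
}

static NumericMatrix resize_bilinear(const NumericMatrix& img, int h, int w) {
  NumericMatrix out(h, w);
  double sy = (double)img.nrow() / h, sx = (double)img.ncol() / w;
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i)
      out(i, j) = sample_bilinear(img, (i + 0.5) * sy - 0.5, (j + 0.5) * sx - 0.5);
  return out;
}

// Separable box sum over a (2r+1)^2 window, zero-padded outside.
static NumericMatrix box_sum(const NumericMatrix& img, int r) {
  int h = img.nrow(), w = img.ncol();
  NumericMatrix tmp(h, w), out(h, w);
  for (int i = 0; i < h; ++i) {           // horizontal pass
    double acc = 0;
    for (int j = 0; j <= r && j < w; ++j) acc += img(i, j);
    tmp(i, 0) = acc;
    for (int j = 1; j < w; ++j) {
      if (j + r < w) acc += img(i, j + r);
      if (j - r - 1 >= 0) acc -= img(i, j - r - 1);
      tmp(i, j) = acc;
    }
  }
  for (int j = 0; j < w; ++j) {           // vertical pass
    double acc = 0;
    for (int i = 0; i <= r && i < h; ++i) acc += tmp(i, j);
    out(0, j) = acc;
    for (int i = 1; i < h; ++i) {
      if (i + r < h) acc += tmp(i + r, j);
      if (i - r - 1 >= 0) acc -= tmp(i - r - 1, j);
      out(i, j) = acc;
    }
  }
  return out;
}

// One pyramid level of iterative windowed least-squares flow refinement.
static void lk_refine(const NumericMatrix& I1, const NumericMatrix& I2,
                      NumericMatrix& u, NumericMatrix& v,
                      int iters, int r, double eps) {
  int h = I1.nrow(), w = I1.ncol();
  NumericMatrix Ix(h, w), Iy(h, w), It(h, w);
  for (int it = 0; it < iters; ++it) {
    NumericMatrix I2w = cpp_warp(const_cast<NumericMatrix&>(I2), u, v);
    for (int j = 0; j < w; ++j) {
      for (int i = 0; i < h; ++i) {
        int jm = j > 0 ? j - 1 : j, jp = j < w - 1 ? j + 1 : j;
        int im = i > 0 ? i - 1 : i, ip = i < h - 1 ? i + 1 : i;
        // gradients on the average image stabilize large-displacement updates
        Ix(i, j) = 0.5 * ((I1(i, jp) - I1(i, jm)) + (I2w(i, jp) - I2w(i, jm))) / (jp - jm > 0 ? jp - jm : 1);
        Iy(i, j) = 0.5 * ((I1(ip, j) - I1(im, j)) + (I2w(ip, j) - I2w(im, j))) / (ip - im > 0 ? ip - im : 1);
        It(i, j) = I2w(i, j) - I1(i, j);
      }
    }
    NumericMatrix gxx(h, w), gxy(h, w), gyy(h, w), gxt(h, w), gyt(h, w);
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i) {
        gxx(i, j) = Ix(i, j) * Ix(i, j);
        gxy(i, j) = Ix(i, j) * Iy(i, j);
        gyy(i, j) = Iy(i, j) * Iy(i, j);
        gxt(i, j) = Ix(i, j) * It(i, j);
        gyt(i, j) = Iy(i, j) * It(i, j);
      }
    NumericMatrix A11 = box_sum(gxx, r), A12 = box_sum(gxy, r), A22 = box_sum(gyy, r);
    NumericMatrix b1 = box_sum(gxt, r), b2 = box_sum(gyt, r);
    double lim = 2.0; // per-iteration update clamp (px)
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i) {
        double a11 = A11(i, j) + eps, a22 = A22(i, j) + eps, a12 = A12(i, j);
        double det = a11 * a22 - a12 * a12;
        if (det <= 0) continue;
        double du = -( a22 * b1(i, j) - a12 * b2(i, j)) / det;
        double dv = -(-a12 * b1(i, j) + a11 * b2(i, j)) / det;
        if (du > lim) du = lim; if (du < -lim) du = -lim;
        if (dv > lim) dv = lim; if (dv < -lim) dv = -lim;
        u(i, j) += du;
        v(i, j) += dv;
      }
  }
}

// [[Rcpp::export(name = ".cpp_dense_flow")]]
List cpp_dense_flow(NumericMatrix I1, NumericMatrix I2,
                    int levels = 3, int iters = 5, int win_radius = 7,
                    double eps = 1e-4) {
  std::vector<NumericMatrix> p1, p2;
  p1.push_back(I1); p2.push_back(I2);
  for (int l = 1; l < levels; ++l) {
    if (p1.back().nrow() < 2 * (2 * win_radius + 1) ||
        p1.back().ncol() < 2 * (2 * win_radius + 1)) break;
    p1.push_back(downsample2(p1.back()));
    p2.push_back(downsample2(p2.back()));
  }
  int top = (int)p1.size() - 1;
  NumericMatrix u(p1[top].nrow(), p1[top].ncol());
  NumericMatrix v(p1[top].nrow(), p1[top].ncol());
  for (int l = top; l >= 0; --l) {
    lk_refine(p1[l], p2[l], u, v, iters, win_radius, eps);
    if (l > 0) {
      int h = p1[l - 1].nrow(), w = p1[l - 1].ncol();
      NumericMatrix u2 = resize_bilinear(u, h, w), v2 = resize_bilinear(v, h, w);
      double fy = (double)h / p1[l].nrow(), fx = (double)w / p1[l].ncol();
      for (int j = 0; j < w; ++j)
        for (int i = 0; i < h; ++i) { u2(i, j) *= fx; v2(i, j) *= fy; }
      u = u2; v = v2;
    }
  }
  return List::create(_["u"] = u, _["v"] = v);
}

// 8-connected component labeling (iterative stack flood fill).
// [[Rcpp::export(name = ".cpp_label8")]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  int next = 0;
  std::vector<int> stack;
  for (int j0 = 0; j0 < w; ++j0) {
    for (int i0 = 0; i0 < h; ++i0) {
      if (!mask(i0, j0) || lab(i0, j0) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(i0 + j0 * h);
      lab(i0, j0) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int i = p % h, j = p / h;
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            int ii = i + di, jj = j + dj;
            if (ii < 0 || jj < 0 || ii >= h || jj >= w) continue;
            if (mask(ii, jj) && lab(ii, jj) == 0) {
              lab(ii, jj) = next;
              stack.push_back(ii + jj * h);
            }
          }
      }
    }
  }
  return lab;
}
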