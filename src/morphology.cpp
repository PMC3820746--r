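#include <Rcpp.h>
using namespace Rcpp;

// Guo-Hall two-subiteration thinning. Input/output: 0/1 integer matrix,
// images indexed [x, y]. Topology-preserving; terminates when stable.
// [[Rcpp::export(name = ".cpp_thin")]]
IntegerMatrix cpp_thin(IntegerMatrix mask) {
  int nx = mask.nrow(), ny = mask.ncol();
  IntegerMatrix m(clone(mask));
  std::vector<int> del;
  del.reserve(1024);
  bool changed = true;
  auto at = [&](int x, int y) -> int {
    if (x < 0 || x >= nx || y < 0 || y >= ny) return 0;
    return m(x, y);
  };
  while (changed) {
    changed = false;
    for (int iter = 0; iter < 2; ++iter) {
      del.clear();
      for (int y = 0; y < ny; ++y) {
        for (int x = 0; x < nx; ++x) {
          if (!m(x, y)) continue;
          // neighbours: p2=N(y+1) p3=NE p4=E(x+1) p5=SE p6=S(y-1) p7=SW p8=W p9=NW
          int p2 = at(x, y + 1), p3 = at(x + 1, y + 1), p4 = at(x + 1, y);
          int p5 = at(x + 1, y - 1), p6 = at(x, y - 1), p7 = at(x - 1, y - 1);
          int p8 = at(x - 1, y), p9 = at(x - 1, y + 1);
          int C = ((!p2) && (p3 || p4)) + ((!p4) && (p5 || p6)) +
                  ((!p6) && (p7 || p8)) + ((!p8) && (p9 || p2));
          int N1 = (p9 || p2) + (p3 || p4) + (p5 || p6) + (p7 || p8);
          int N2 = (p2 || p3) + (p4 || p5) + (p6 || p7) + (p8 || p9);
          int N = N1 < N2 ? N1 : N2;
          int c3;
          if (iter == 0)
            c3 = (p6 || p7 || (!p9)) && p8;
          else
            c3 = (p2 || p3 || (!p5)) && p4;
          if (C == 1 && N >= 2 && N <= 3 && c3 == 0)
            del.push_back(x + nx * y);
        }
      }
      if (!del.empty()) {
        changed = true;
        for (size_t k = 0; k < del.size(); ++k) m[del[k]] = 0;
      }
    }
  }
  return m;
}

// Separable convolution with replicate (edge-clamp) boundary handling.
// kx runs along x (rows of the [x, y] matrix), ky along y.
// [[Rcpp::export(name = ".cpp_conv_sep")]]
NumericMatrix cpp_conv_sep(NumericMatrix img, NumericVector kx, NumericVector ky) {
  int nx = img.nrow(), ny = img.ncol();
  int rx = (kx.size() - 1) / 2, ry = (ky.size() - 1) / 2;
  NumericMatrix tmp(nx, ny), out(nx, ny);
  for (int y = 0; y < ny; ++y) {
    for (int x = 0; x < nx; ++x) {
      double s = 0;
      for (int k = -rx; k <= rx; ++k) {
        int xx = x + k;
        if (xx < 0) xx = 0; else if (xx >= nx) xx = nx - 1;
        s += kx[k + rx] * img(xx, y);
      }
      tmp(x, y) = s;
    }
  }
  for (int y = 0; y < ny; ++y) {
    for (int x = 0; x < nx; ++x) {
      double s = 0;
      for (int k = -ry; k <= ry; ++k) {
        int yy = y + k;
        if (yy < 0) yy = 0; else if (yy >= ny) yy = ny - 1;
        s += ky[k + ry] * tmp(x, yy);
      }
      out(x, y) = s;
    }
  }
  return out;
}

// Local maxima (8-neighbourhood) above a threshold. Plateaus are broken
// lexicographically: a pixel loses to an equal-valued neighbour with a
// smaller linear index, so a flat plateau yields exactly one maximum.
// Returns 1-based linear indices into the matrix.
// [[Rcpp::export(name = ".cpp_local_maxima")]]
IntegerVector cpp_local_maxima(NumericMatrix img, double threshold) {
  int nx = img.nrow(), ny = img.ncol();
  std::vector<int> idx;
  for (int y = 0; y < ny; ++y) {
    for (int x = 0; x < nx; ++x) {
      double v = img(x, y);
      if (v < threshold) continue;
      int lin = x + nx * y;
      bool ismax = true;
      for (int dy = -1; dy <= 1 && ismax; ++dy) {
        for (int dx = -1; dx <= 1; ++dx) {
          if (dx == 0 && dy == 0) continue;
          int xx = x + dx, yy = y + dy;
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny) continue;
          double w = img(xx, yy);
          if (w > v || (w == v && xx + nx * yy < lin)) { ismax = false; break; }
        }
      }
      if (ismax) idx.push_back(lin + 1);
    }
  }
  return wrap(idx);
}

// 8-connected component labelling (used for skeleton networks; compartments
// use EBImage's 4-connected bwlabel). Returns integer labels 1..L.
// [[Rcpp::export(name = ".cpp_label8")]]
IntegerMatrix cpp_label8(IntegerMatrix mask) {
  int nx = mask.nrow(), ny = mask.ncol();
  IntegerMatrix lab(nx, ny);
  std::vector<int> stack;
  int next = 0;
  for (int y0 = 0; y0 < ny; ++y0) {
    for (int x0 = 0; x0 < nx; ++x0) {
      if (!mask(x0, y0) || lab(x0, y0)) continue;
      ++next;
      stack.clear();
      stack.push_back(x0 + nx * y0);
      lab(x0, y0) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int x = p % nx, y = p / nx;
        for (int dy = -1; dy <= 1; ++dy) {
          for (int dx = -1; dx <= 1; ++dx) {
            int xx = x + dx, yy = y + dy;
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny) continue;
            if (mask(xx, yy) && !lab(xx, yy)) {
              lab(xx, yy) = next;
              stack.push_back(xx + nx * yy);
            }
          }
        }
      }
    }
  }
  return lab;
}
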