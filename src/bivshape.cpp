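// Numerical kernels: bicubic/affine resampling, 3x3 convolution stack for the
// small stage networks, exact point-triangle distances, Hausdorff distance,
// and a connected-component flood fill used by heatmap decoding.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double cubic_keys(double x) {
  // Keys cubic kernel, a = -0.5 (the classic bicubic interpolation kernel)
  const double a = -0.5;
  x = std::fabs(x);
  if (x < 1.0) return (a + 2.0) * x * x * x - (a + 3.0) * x * x + 1.0;
  if (x < 2.0) return a * x * x * x - 5.0 * a * x * x + 8.0 * a * x - 4.0 * a;
  return 0.0;
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// [[Rcpp::export]]
arma::mat cpp_resize_bicubic(const arma::mat& img, int out_h, int out_w) {
  const int h = img.n_rows, w = img.n_cols;
  arma::mat out(out_h, out_w);
  const double sr = (double)h / out_h, sc = (double)w / out_w;
  for (int i = 0; i < out_h; ++i) {
    double y = (i + 0.5) * sr - 0.5;
    int y0 = (int)std::floor(y);
    double wy[4];
    for (int k = 0; k < 4; ++k) wy[k] = cubic_keys(y - (y0 - 1 + k));
    for (int j = 0; j < out_w; ++j) {
      double x = (j + 0.5) * sc - 0.5;
      int x0 = (int)std::floor(x);
      double wx[4];
      for (int k = 0; k < 4; ++k) wx[k] = cubic_keys(x - (x0 - 1 + k));
      double acc = 0.0, wsum = 0.0;
      for (int ky = 0; ky < 4; ++ky) {
        int yi = clampi(y0 - 1 + ky, 0, h - 1);
        for (int kx = 0; kx < 4; ++kx) {
          int xi = clampi(x0 - 1 + kx, 0, w - 1);
          double wgt = wy[ky] * wx[kx];
          acc += wgt * img(yi, xi);
          wsum += wgt;
        }
      }
      out(i, j) = acc / wsum;
    }
  }
  return out;
}

// Inverse-mapped affine warp about the image center: for each output pixel p,
// sample input at A %*% (p - c) + c + t.  interp: 0 nearest, 1 bilinear.
// [[Rcpp::export]]
arma::mat cpp_affine_warp(const arma::mat& img, const arma::mat& A,
                          const arma::vec& t, int interp, double fill) {
  const int h = img.n_rows, w = img.n_cols;
  arma::mat out(h, w);
  const double cr = (h - 1) / 2.0, cc = (w - 1) / 2.0;
  for (int i = 0; i < h; ++i) {
    for (int j = 0; j < w; ++j) {
      double sr = A(0, 0) * (i - cr) + A(0, 1) * (j - cc) + cr + t(0);
      double sc = A(1, 0) * (i - cr) + A(1, 1) * (j - cc) + cc + t(1);
      if (interp == 0) {
        int ri = (int)std::lround(sr), ci = (int)std::lround(sc);
        out(i, j) = (ri < 0 || ri >= h || ci < 0 || ci >= w) ? fill : img(ri, ci);
      } else {
        int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
        double fr = sr - r0, fc = sc - c0;
        if (r0 < -1 || r0 >= h || c0 < -1 || c0 >= w) { out(i, j) = fill; continue; }
        double v00 = (r0 < 0 || c0 < 0) ? fill : img(r0, c0);
        double v01 = (r0 < 0 || c0 + 1 >= w) ? fill : img(r0, clampi(c0 + 1, 0, w - 1));
        double v10 = (r0 + 1 >= h || c0 < 0) ? fill : img(clampi(r0 + 1, 0, h - 1), c0);
        double v11 = (r0 + 1 >= h || c0 + 1 >= w) ? fill
                     : img(clampi(r0 + 1, 0, h - 1), clampi(c0 + 1, 0, w - 1));
        out(i, j) = (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11);
      }
    }
  }
  return out;
}

// ---- 3x3 same-padding convolution via im2col + GEMM ------------------------

static arma::mat im2col3(const arma::cube& x) {
  const int h = x.n_rows, w = x.n_cols, cin = x.n_slices;
  arma::mat col(h * w, 9 * cin, arma::fill::zeros);
  for (int ch = 0; ch < cin; ++ch) {
    const arma::mat& xs = x.slice(ch);
    int kidx = 0;
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        int colj = ch * 9 + kidx;
        for (int j = 0; j < w; ++j) {
          int js = j + dc;
          if (js < 0 || js >= w) continue;
          int r0 = std::max(0, -dr), r1 = std::min(h, h - dr);
          double* dst = col.colptr(colj) + (size_t)j * h;
          const double* src = xs.colptr(js);
          for (int i = r0; i < r1; ++i) dst[i] = src[i + dr];
        }
        ++kidx;
      }
    }
  }
  return col;
}

// w: (9*cin) x cout, b: cout
// [[Rcpp::export]]
arma::cube cpp_conv3_fw(const arma::cube& x, const arma::mat& w, const arma::vec& b) {
  const int h = x.n_rows, wd = x.n_cols;
  arma::mat col = im2col3(x);
  arma::mat outm = col * w;
  outm.each_row() += b.t();
  arma::cube out(h, wd, w.n_cols);
  std::memcpy(out.memptr(), outm.memptr(), sizeof(double) * outm.n_elem);
  return out;
}

// [[Rcpp::export]]
List cpp_conv3_bw(const arma::cube& x, const arma::mat& w, const arma::cube& gout) {
  const int h = x.n_rows, wd = x.n_cols, cin = x.n_slices, cout = w.n_cols;
  arma::mat goutm(const_cast<double*>(gout.memptr()), h * wd, cout, false, true);
  arma::mat col = im2col3(x);
  arma::mat gw = col.t() * goutm;
  arma::vec gb = arma::sum(goutm, 0).t();
  arma::mat gcol = goutm * w.t();  // (h*w) x (9*cin)
  arma::cube gx(h, wd, cin, arma::fill::zeros);
  for (int ch = 0; ch < cin; ++ch) {
    arma::mat& gxs = gx.slice(ch);
    int kidx = 0;
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        int colj = ch * 9 + kidx;
        for (int j = 0; j < wd; ++j) {
          int js = j + dc;
          if (js < 0 || js >= wd) continue;
          int r0 = std::max(0, -dr), r1 = std::min(h, h - dr);
          const double* src = gcol.colptr(colj) + (size_t)j * h;
          double* dst = gxs.colptr(js);
          for (int i = r0; i < r1; ++i) dst[i + dr] += src[i];
        }
        ++kidx;
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2 (even input dims assumed; trailing row/col dropped)
// [[Rcpp::export]]
List cpp_maxpool2_fw(const arma::cube& x) {
  const int h = x.n_rows / 2, w = x.n_cols / 2, c = x.n_slices;
  arma::cube out(h, w, c);
  arma::ucube idx(h, w, c);
  for (int ch = 0; ch < c; ++ch) {
    for (int j = 0; j < w; ++j) {
      for (int i = 0; i < h; ++i) {
        double best = -1e300;
        unsigned bi = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            int ri = 2 * i + di, cj = 2 * j + dj;
            double v = x(ri, cj, ch);
            if (v > best) { best = v; bi = ri + cj * x.n_rows; }
          }
        }
        out(i, j, ch) = best;
        idx(i, j, ch) = bi;
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bw(const arma::ucube& idx, const arma::cube& gout,
                           int in_h, int in_w) {
  const int c = gout.n_slices;
  arma::cube gx(in_h, in_w, c, arma::fill::zeros);
  for (int ch = 0; ch < c; ++ch) {
    double* gxp = gx.slice_memptr(ch);
    for (size_t k = 0; k < gout.n_rows * gout.n_cols; ++k) {
      gxp[idx.slice(ch).at(k)] += gout.slice(ch).at(k);
    }
  }
  return gx;
}

// nearest-neighbour 2x upsampling
// [[Rcpp::export]]
arma::cube cpp_upsample2_fw(const arma::cube& x) {
  const int h = x.n_rows, w = x.n_cols, c = x.n_slices;
  arma::cube out(2 * h, 2 * w, c);
  for (int ch = 0; ch < c; ++ch)
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i) {
        double v = x(i, j, ch);
        out(2 * i, 2 * j, ch) = v; out(2 * i + 1, 2 * j, ch) = v;
        out(2 * i, 2 * j + 1, ch) = v; out(2 * i + 1, 2 * j + 1, ch) = v;
      }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_bw(const arma::cube& gout) {
  const int h = gout.n_rows / 2, w = gout.n_cols / 2, c = gout.n_slices;
  arma::cube gx(h, w, c);
  for (int ch = 0; ch < c; ++ch)
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i)
        gx(i, j, ch) = gout(2 * i, 2 * j, ch) + gout(2 * i + 1, 2 * j, ch) +
                       gout(2 * i, 2 * j + 1, ch) + gout(2 * i + 1, 2 * j + 1, ch);
  return gx;
}

// ---- exact point-triangle distance (Ericson, Real-Time Collision Detection)

static arma::vec3 closest_on_tri(const arma::vec3& p, const arma::vec3& a,
                                 const arma::vec3& b, const arma::vec3& c) {
  arma::vec3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = arma::dot(ab, ap), d2 = arma::dot(ac, ap);
  if (d1 <= 0 && d2 <= 0) return a;
  arma::vec3 bp = p - b;
  double d3 = arma::dot(ab, bp), d4 = arma::dot(ac, bp);
  if (d3 >= 0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) return a + (d1 / (d1 - d3)) * ab;
  arma::vec3 cp = p - c;
  double d5 = arma::dot(ab, cp), d6 = arma::dot(ac, cp);
  if (d6 >= 0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) return a + (d2 / (d2 - d6)) * ac;
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0)
    return b + ((d4 - d3) / ((d4 - d3) + (d5 - d6))) * (c - b);
  double denom = 1.0 / (va + vb + vc);
  return a + ab * (vb * denom) + ac * (vc * denom);
}

// points: n x 3; v: m x 3; f: k x 3 (1-based vertex indices).
// seed_faces (optional, 1-based, 0 = none): warm-start face per point from a
// previous query against (nearly) the same mesh; tightens pruning.
// [[Rcpp::export]]
List cpp_point_tri_dist(const arma::mat& points, const arma::mat& v,
                        const arma::imat& f,
                        Rcpp::Nullable<Rcpp::IntegerVector> seed_faces = R_NilValue) {
  const int n = points.n_rows, k = f.n_rows;
  arma::vec dist(n);
  arma::mat closest(n, 3);
  arma::ivec face(n);
  // coarse per-face bounding spheres for pruning
  arma::mat ctr(k, 3);
  arma::vec rad(k);
  for (int t = 0; t < k; ++t) {
    arma::rowvec a = v.row(f(t, 0) - 1), b = v.row(f(t, 1) - 1), c = v.row(f(t, 2) - 1);
    arma::rowvec m = (a + b + c) / 3.0;
    ctr.row(t) = m;
    rad(t) = std::sqrt(std::max(std::max(arma::dot(a - m, a - m),
                                         arma::dot(b - m, b - m)),
                                arma::dot(c - m, c - m)));
  }
  Rcpp::IntegerVector seeds;
  bool have_seeds = seed_faces.isNotNull();
  if (have_seeds) seeds = seed_faces.get();
  const double* cx = ctr.colptr(0);
  const double* cy = ctr.colptr(1);
  const double* cz = ctr.colptr(2);
  for (int i = 0; i < n; ++i) {
    arma::vec3 p = points.row(i).t();
    double best = 1e300;
    arma::vec3 bq;
    int bf = 0;
    int seed_t = (have_seeds && seeds[i] >= 1 && seeds[i] <= k) ? seeds[i] - 1 : -1;
    if (seed_t >= 0) {
      bq = closest_on_tri(p, v.row(f(seed_t, 0) - 1).t(),
                          v.row(f(seed_t, 1) - 1).t(),
                          v.row(f(seed_t, 2) - 1).t());
      best = arma::dot(p - bq, p - bq);
      bf = seed_t + 1;
    }
    double bound = (best < 1e300) ? std::sqrt(best) : 1e150;
    for (int t = 0; t < k; ++t) {
      if (t == seed_t) continue;
      double dx = p(0) - cx[t], dy = p(1) - cy[t], dz = p(2) - cz[t];
      double dc2 = dx * dx + dy * dy + dz * dz;
      double thr = bound + rad(t);
      if (dc2 >= thr * thr) continue;
      arma::vec3 q = closest_on_tri(p, v.row(f(t, 0) - 1).t(), v.row(f(t, 1) - 1).t(),
                                    v.row(f(t, 2) - 1).t());
      double d2 = arma::dot(p - q, p - q);
      if (d2 < best) { best = d2; bq = q; bf = t + 1; bound = std::sqrt(best); }
    }
    dist(i) = std::sqrt(best);
    closest.row(i) = bq.t();
    face(i) = bf;
  }
  return List::create(_["dist"] = dist, _["closest"] = closest, _["face"] = face);
}

// symmetric Hausdorff distance between two point sets (rows)
// [[Rcpp::export]]
double cpp_hausdorff(const arma::mat& a, const arma::mat& b) {
  double hab = 0.0, hba = 0.0;
  arma::vec minb(b.n_rows, arma::fill::value(1e300));
  for (size_t i = 0; i < a.n_rows; ++i) {
    double mn = 1e300;
    for (size_t j = 0; j < b.n_rows; ++j) {
      double d2 = arma::dot(a.row(i) - b.row(j), a.row(i) - b.row(j));
      if (d2 < mn) mn = d2;
      if (d2 < minb(j)) minb(j) = d2;
    }
    if (mn > hab) hab = mn;
  }
  hba = minb.max();
  return std::sqrt(std::max(hab, hba));
}

// 8-connected component of `mask` containing (seed_r, seed_c); 1-based seed.
// [[Rcpp::export]]
LogicalMatrix cpp_flood_component(const LogicalMatrix& mask, int seed_r, int seed_c) {
  const int h = mask.nrow(), w = mask.ncol();
  LogicalMatrix out(h, w);
  if (seed_r < 1 || seed_r > h || seed_c < 1 || seed_c > w || !mask(seed_r - 1, seed_c - 1))
    return out;
  std::vector<std::pair<int, int>> stack;
  stack.push_back({seed_r - 1, seed_c - 1});
  out(seed_r - 1, seed_c - 1) = true;
  while (!stack.empty()) {
    auto [r, c] = stack.back();
    stack.pop_back();
    for (int dr = -1; dr <= 1; ++dr)
      for (int dc = -1; dc <= 1; ++dc) {
        int rr = r + dr, cc = c + dc;
        if (rr < 0 || rr >= h || cc < 0 || cc >= w) continue;
        if (mask(rr, cc) && !out(rr, cc)) {
          out(rr, cc) = true;
          stack.push_back({rr, cc});
        }
      }
  }
  return out;
}
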