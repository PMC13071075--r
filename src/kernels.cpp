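// Numerical core: grouped 3D convolution (vol2col + GEMM), max pooling,
// trilinear/nearest resizing, and their gradients.
//
// Array layout (matches the R side): feature maps are dense numeric arrays
// with dim c(d1, d2, d3, C, N) — first spatial index fastest (R column-major),
// then channels, then batch. Weights for a grouped conv are stored with
// dim c(k, k, k, c_in/groups, c_out): flattening the first four dims gives
// the vol2col row index, so each weight column is one output-channel filter.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad, int dil) {
  return (in + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

// Fill `col` (K x P, K = cg*k^3, P = o1*o2*o3) from one sample's group slab.
// xg points at the first element of channel `c0` of sample n.
static void vol2col(const double* xg, int d1, int d2, int d3, int cg,
                    int k, int stride, int pad, int dil,
                    int o1, int o2, int o3, arma::mat& col) {
  const long vol = (long)d1 * d2 * d3;
  for (int c = 0; c < cg; ++c) {
    const double* xc = xg + (long)c * vol;
    for (int k3 = 0; k3 < k; ++k3)
      for (int k2 = 0; k2 < k; ++k2)
        for (int k1 = 0; k1 < k; ++k1) {
          const int row = k1 + k * (k2 + k * (k3 + k * c));
          long p = 0;
          for (int j3 = 0; j3 < o3; ++j3) {
            const int i3 = j3 * stride - pad + k3 * dil;
            const bool ok3 = (i3 >= 0 && i3 < d3);
            for (int j2 = 0; j2 < o2; ++j2) {
              const int i2 = j2 * stride - pad + k2 * dil;
              const bool ok2 = ok3 && (i2 >= 0 && i2 < d2);
              for (int j1 = 0; j1 < o1; ++j1, ++p) {
                const int i1 = j1 * stride - pad + k1 * dil;
                col.at(row, p) = (ok2 && i1 >= 0 && i1 < d1)
                  ? xc[i1 + (long)d1 * (i2 + (long)d2 * i3)] : 0.0;
              }
            }
          }
        }
  }
}

// Scatter-accumulate `col` back into the gradient slab (inverse of vol2col).
static void col2vol(const arma::mat& col, double* xg, int d1, int d2, int d3,
                    int cg, int k, int stride, int pad, int dil,
                    int o1, int o2, int o3) {
  const long vol = (long)d1 * d2 * d3;
  for (int c = 0; c < cg; ++c) {
    double* xc = xg + (long)c * vol;
    for (int k3 = 0; k3 < k; ++k3)
      for (int k2 = 0; k2 < k; ++k2)
        for (int k1 = 0; k1 < k; ++k1) {
          const int row = k1 + k * (k2 + k * (k3 + k * c));
          long p = 0;
          for (int j3 = 0; j3 < o3; ++j3) {
            const int i3 = j3 * stride - pad + k3 * dil;
            const bool ok3 = (i3 >= 0 && i3 < d3);
            for (int j2 = 0; j2 < o2; ++j2) {
              const int i2 = j2 * stride - pad + k2 * dil;
              const bool ok2 = ok3 && (i2 >= 0 && i2 < d2);
              for (int j1 = 0; j1 < o1; ++j1, ++p) {
                const int i1 = j1 * stride - pad + k1 * dil;
                if (ok2 && i1 >= 0 && i1 < d1)
                  xc[i1 + (long)d1 * (i2 + (long)d2 * i3)] += col.at(row, p);
              }
            }
          }
        }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_forward(NumericVector x, IntegerVector xdim,
                                 NumericVector w, NumericVector bias,
                                 int k, int stride, int pad, int dil,
                                 int groups, int c_out) {
  const int d1 = xdim[0], d2 = xdim[1], d3 = xdim[2], C = xdim[3], N = xdim[4];
  const int cg = C / groups, og = c_out / groups;
  const int o1 = out_size(d1, k, stride, pad, dil);
  const int o2 = out_size(d2, k, stride, pad, dil);
  const int o3 = out_size(d3, k, stride, pad, dil);
  const long P = (long)o1 * o2 * o3;
  const int K = cg * k * k * k;

  NumericVector y((long)P * c_out * N);
  arma::mat W(const_cast<double*>(w.begin()), K, c_out, false, true);
  arma::mat col(K, P);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (long)n * d1 * d2 * d3 * C;
    double* yn = y.begin() + (long)n * P * c_out;
    for (int g = 0; g < groups; ++g) {
      vol2col(xn + (long)g * cg * d1 * d2 * d3, d1, d2, d3, cg,
              k, stride, pad, dil, o1, o2, o3, col);
      arma::mat Yg(yn + (long)g * og * P, P, og, false, true);
      Yg = col.t() * W.cols(g * og, (g + 1) * og - 1);
      for (int c = 0; c < og; ++c) Yg.col(c) += bias[g * og + c];
    }
  }
  y.attr("dim") = IntegerVector::create(o1, o2, o3, c_out, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_backward(NumericVector x, IntegerVector xdim,
                         NumericVector w, NumericVector dy,
                         int k, int stride, int pad, int dil,
                         int groups, int c_out) {
  const int d1 = xdim[0], d2 = xdim[1], d3 = xdim[2], C = xdim[3], N = xdim[4];
  const int cg = C / groups, og = c_out / groups;
  const int o1 = out_size(d1, k, stride, pad, dil);
  const int o2 = out_size(d2, k, stride, pad, dil);
  const int o3 = out_size(d3, k, stride, pad, dil);
  const long P = (long)o1 * o2 * o3;
  const int K = cg * k * k * k;

  NumericVector dx(x.size());
  NumericVector dw(w.size());
  NumericVector db(c_out);
  arma::mat W(const_cast<double*>(w.begin()), K, c_out, false, true);
  arma::mat dW(dw.begin(), K, c_out, false, true);
  arma::mat col(K, P);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (long)n * d1 * d2 * d3 * C;
    double* dxn = dx.begin() + (long)n * d1 * d2 * d3 * C;
    const double* dyn = dy.begin() + (long)n * P * c_out;
    for (int g = 0; g < groups; ++g) {
      arma::mat dYg(const_cast<double*>(dyn) + (long)g * og * P, P, og,
                    false, true);
      vol2col(xn + (long)g * cg * d1 * d2 * d3, d1, d2, d3, cg,
              k, stride, pad, dil, o1, o2, o3, col);
      dW.cols(g * og, (g + 1) * og - 1) += col * dYg;
      for (int c = 0; c < og; ++c) db[g * og + c] += arma::accu(dYg.col(c));
      arma::mat dcol = W.cols(g * og, (g + 1) * og - 1) * dYg.t();
      col2vol(dcol, dxn + (long)g * cg * d1 * d2 * d3, d1, d2, d3, cg,
              k, stride, pad, dil, o1, o2, o3);
    }
  }
  dx.attr("dim") = xdim;
  dw.attr("dim") = w.attr("dim");
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Max pooling with window k, given stride and padding; argmax indices are
// 1-based flat indices into x, returned for the backward scatter.
// [[Rcpp::export]]
List cpp_maxpool3d(NumericVector x, IntegerVector xdim,
                   int k, int stride, int pad) {
  const int d1 = xdim[0], d2 = xdim[1], d3 = xdim[2], C = xdim[3], N = xdim[4];
  const int o1 = out_size(d1, k, stride, pad, 1);
  const int o2 = out_size(d2, k, stride, pad, 1);
  const int o3 = out_size(d3, k, stride, pad, 1);
  const long P = (long)o1 * o2 * o3;
  NumericVector y(P * C * N);
  IntegerVector arg(P * C * N);
  long q = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const long base = (long)(n * C + c) * d1 * d2 * d3;
      const double* xc = x.begin() + base;
      for (int j3 = 0; j3 < o3; ++j3)
        for (int j2 = 0; j2 < o2; ++j2)
          for (int j1 = 0; j1 < o1; ++j1, ++q) {
            double best = R_NegInf; long bidx = -1;
            for (int k3 = 0; k3 < k; ++k3) {
              const int i3 = j3 * stride - pad + k3;
              if (i3 < 0 || i3 >= d3) continue;
              for (int k2 = 0; k2 < k; ++k2) {
                const int i2 = j2 * stride - pad + k2;
                if (i2 < 0 || i2 >= d2) continue;
                for (int k1 = 0; k1 < k; ++k1) {
                  const int i1 = j1 * stride - pad + k1;
                  if (i1 < 0 || i1 >= d1) continue;
                  const long idx = i1 + (long)d1 * (i2 + (long)d2 * i3);
                  if (xc[idx] > best) { best = xc[idx]; bidx = idx; }
                }
              }
            }
            y[q] = best;
            arg[q] = (int)(base + bidx) + 1;
          }
    }
  y.attr("dim") = IntegerVector::create(o1, o2, o3, C, N);
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// Trilinear resize, half-pixel-center convention (align_corners = FALSE).
// [[Rcpp::export]]
NumericVector cpp_trilinear_resize(NumericVector x, IntegerVector xdim,
                                   IntegerVector odim) {
  const int d1 = xdim[0], d2 = xdim[1], d3 = xdim[2], C = xdim[3], N = xdim[4];
  const int o1 = odim[0], o2 = odim[1], o3 = odim[2];
  const double s1 = (double)d1 / o1, s2 = (double)d2 / o2, s3 = (double)d3 / o3;
  NumericVector y((long)o1 * o2 * o3 * C * N);

  std::vector<int> lo1(o1), hi1(o1); std::vector<double> w1(o1);
  std::vector<int> lo2(o2), hi2(o2); std::vector<double> w2(o2);
  std::vector<int> lo3(o3), hi3(o3); std::vector<double> w3(o3);
  auto prep = [](int o, int d, double s, std::vector<int>& lo,
                 std::vector<int>& hi, std::vector<double>& w) {
    for (int j = 0; j < o; ++j) {
      double src = (j + 0.5) * s - 0.5;
      if (src < 0) src = 0;
      if (src > d - 1) src = d - 1;
      lo[j] = (int)std::floor(src);
      hi[j] = std::min(lo[j] + 1, d - 1);
      w[j] = src - lo[j];
    }
  };
  prep(o1, d1, s1, lo1, hi1, w1);
  prep(o2, d2, s2, lo2, hi2, w2);
  prep(o3, d3, s3, lo3, hi3, w3);

  long q = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (long)(n * C + c) * d1 * d2 * d3;
      for (int j3 = 0; j3 < o3; ++j3)
        for (int j2 = 0; j2 < o2; ++j2)
          for (int j1 = 0; j1 < o1; ++j1, ++q) {
            const double a1 = w1[j1], a2 = w2[j2], a3 = w3[j3];
            auto at = [&](int i1, int i2, int i3) {
              return xc[i1 + (long)d1 * (i2 + (long)d2 * i3)];
            };
            const double v00 = at(lo1[j1], lo2[j2], lo3[j3]) * (1 - a1) + at(hi1[j1], lo2[j2], lo3[j3]) * a1;
            const double v10 = at(lo1[j1], hi2[j2], lo3[j3]) * (1 - a1) + at(hi1[j1], hi2[j2], lo3[j3]) * a1;
            const double v01 = at(lo1[j1], lo2[j2], hi3[j3]) * (1 - a1) + at(hi1[j1], lo2[j2], hi3[j3]) * a1;
            const double v11 = at(lo1[j1], hi2[j2], hi3[j3]) * (1 - a1) + at(hi1[j1], hi2[j2], hi3[j3]) * a1;
            y[q] = (v00 * (1 - a2) + v10 * a2) * (1 - a3)
                 + (v01 * (1 - a2) + v11 * a2) * a3;
          }
    }
  y.attr("dim") = IntegerVector::create(o1, o2, o3, C, N);
  return y;
}

// Gradient of cpp_trilinear_resize: scatter dY with the same weights.
// [[Rcpp::export]]
NumericVector cpp_trilinear_resize_backward(NumericVector dy,
                                            IntegerVector xdim,
                                            IntegerVector odim) {
  const int d1 = xdim[0], d2 = xdim[1], d3 = xdim[2], C = xdim[3], N = xdim[4];
  const int o1 = odim[0], o2 = odim[1], o3 = odim[2];
  const double s1 = (double)d1 / o1, s2 = (double)d2 / o2, s3 = (double)d3 / o3;
  NumericVector dx((long)d1 * d2 * d3 * C * N);

  std::vector<int> lo1(o1), hi1(o1); std::vector<double> w1(o1);
  std::vector<int> lo2(o2), hi2(o2); std::vector<double> w2(o2);
  std::vector<int> lo3(o3), hi3(o3); std::vector<double> w3(o3);
  auto prep = [](int o, int d, double s, std::vector<int>& lo,
                 std::vector<int>& hi, std::vector<double>& w) {
    for (int j = 0; j < o; ++j) {
      double src = (j + 0.5) * s - 0.5;
      if (src < 0) src = 0;
      if (src > d - 1) src = d - 1;
      lo[j] = (int)std::floor(src);
      hi[j] = std::min(lo[j] + 1, d - 1);
      w[j] = src - lo[j];
    }
  };
  prep(o1, d1, s1, lo1, hi1, w1);
  prep(o2, d2, s2, lo2, hi2, w2);
  prep(o3, d3, s3, lo3, hi3, w3);

  long q = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* xc = dx.begin() + (long)(n * C + c) * d1 * d2 * d3;
      for (int j3 = 0; j3 < o3; ++j3)
        for (int j2 = 0; j2 < o2; ++j2)
          for (int j1 = 0; j1 < o1; ++j1, ++q) {
            const double g = dy[q];
            if (g == 0) continue;
            const double a1 = w1[j1], a2 = w2[j2], a3 = w3[j3];
            auto add = [&](int i1, int i2, int i3, double v) {
              xc[i1 + (long)d1 * (i2 + (long)d2 * i3)] += v;
            };
            add(lo1[j1], lo2[j2], lo3[j3], g * (1 - a1) * (1 - a2) * (1 - a3));
            add(hi1[j1], lo2[j2], lo3[j3], g * a1 * (1 - a2) * (1 - a3));
            add(lo1[j1], hi2[j2], lo3[j3], g * (1 - a1) * a2 * (1 - a3));
            add(hi1[j1], hi2[j2], lo3[j3], g * a1 * a2 * (1 - a3));
            add(lo1[j1], lo2[j2], hi3[j3], g * (1 - a1) * (1 - a2) * a3);
            add(hi1[j1], lo2[j2], hi3[j3], g * a1 * (1 - a2) * a3);
            add(lo1[j1], hi2[j2], hi3[j3], g * (1 - a1) * a2 * a3);
            add(hi1[j1], hi2[j2], hi3[j3], g * a1 * a2 * a3);
          }
    }
  dx.attr("dim") = xdim;
  return dx;
}

// Nearest-neighbour resize (used for label masks; keeps values binary).
// [[Rcpp::export]]
NumericVector cpp_nearest_resize(NumericVector x, IntegerVector xdim,
                                 IntegerVector odim) {
  const int d1 = xdim[0], d2 = xdim[1], d3 = xdim[2], C = xdim[3], N = xdim[4];
  const int o1 = odim[0], o2 = odim[1], o3 = odim[2];
  const double s1 = (double)d1 / o1, s2 = (double)d2 / o2, s3 = (double)d3 / o3;
  NumericVector y((long)o1 * o2 * o3 * C * N);
  std::vector<int> m1(o1), m2(o2), m3(o3);
  auto prep = [](int o, int d, double s, std::vector<int>& m) {
    for (int j = 0; j < o; ++j) {
      int i = (int)std::floor((j + 0.5) * s);
      if (i < 0) i = 0;
      if (i > d - 1) i = d - 1;
      m[j] = i;
    }
  };
  prep(o1, d1, s1, m1); prep(o2, d2, s2, m2); prep(o3, d3, s3, m3);
  long q = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (long)(n * C + c) * d1 * d2 * d3;
      for (int j3 = 0; j3 < o3; ++j3)
        for (int j2 = 0; j2 < o2; ++j2)
          for (int j1 = 0; j1 < o1; ++j1, ++q)
            y[q] = xc[m1[j1] + (long)d1 * (m2[j2] + (long)d2 * m3[j3])];
    }
  y.attr("dim") = IntegerVector::create(o1, o2, o3, C, N);
  return y;
}
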