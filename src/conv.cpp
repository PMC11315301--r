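// Compiled kernels for the neural-network layers and mask post-processing.
// Tensor layout throughout: column-major R arrays [H, W, C, B].
// Convolution weights: matrix (Cout x K*K*Cin), column index = kh + K*kw + K*K*c.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col(const double* x, int H, int W, int C,
                   int K, int s, int p, int Ho, int Wo, arma::mat& col) {
  // col is (K*K*C) x (Ho*Wo); caller zeroes it (padding entries stay 0)
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        const int row = kh + K * kw + K * K * c;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * s + kw - p;
          if (wi < 0 || wi >= W) continue;
          const double* xcol = xc + (size_t)H * wi;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * s + kh - p;
            if (hi < 0 || hi >= H) continue;
            col(row, ho + (size_t)Ho * wo) = xcol[hi];
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& col, double* gx, int H, int W, int C,
                       int K, int s, int p, int Ho, int Wo) {
  for (int c = 0; c < C; ++c) {
    double* gc = gx + (size_t)H * W * c;
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        const int row = kh + K * kw + K * K * c;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * s + kw - p;
          if (wi < 0 || wi >= W) continue;
          double* gcol = gc + (size_t)H * wi;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * s + kh - p;
            if (hi < 0 || hi >= H) continue;
            gcol[hi] += col(row, ho + (size_t)Ho * wo);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericMatrix Wt, NumericVector bias,
                             int K, int stride, int pad) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], B = d[3];
  const int Cout = Wt.nrow();
  const int Ho = (H + 2 * pad - K) / stride + 1;
  const int Wo = (W + 2 * pad - K) / stride + 1;
  arma::mat Wm(Wt.begin(), Cout, Wt.ncol(), false);
  arma::rowvec bv(bias.begin(), Cout, false);
  NumericVector y((R_xlen_t)Ho * Wo * Cout * B);
  arma::mat col(K * K * C, Ho * Wo);
  for (int b = 0; b < B; ++b) {
    col.zeros();
    im2col(x.begin() + (size_t)H * W * C * b, H, W, C, K, stride, pad, Ho, Wo, col);
    arma::mat ys = col.t() * Wm.t();  // (Ho*Wo) x Cout == output slice layout
    ys.each_row() += bv;
    std::copy(ys.begin(), ys.end(), y.begin() + (size_t)Ho * Wo * Cout * b);
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, B);
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericMatrix Wt, NumericVector gy,
                    int K, int stride, int pad, bool need_gx) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], B = d[3];
  const int Cout = Wt.nrow();
  const int Ho = (H + 2 * pad - K) / stride + 1;
  const int Wo = (W + 2 * pad - K) / stride + 1;
  arma::mat Wm(Wt.begin(), Cout, Wt.ncol(), false);
  arma::mat gW(Cout, K * K * C, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  NumericVector gx(need_gx ? x.size() : (R_xlen_t)0);
  arma::mat col(K * K * C, Ho * Wo);
  for (int b = 0; b < B; ++b) {
    col.zeros();
    im2col(x.begin() + (size_t)H * W * C * b, H, W, C, K, stride, pad, Ho, Wo, col);
    arma::mat gys(gy.begin() + (size_t)Ho * Wo * Cout * b, Ho * Wo, Cout, false);
    gW += gys.t() * col.t();
    gb += arma::sum(gys, 0).t();
    if (need_gx) {
      arma::mat gcol = Wm.t() * gys.t();  // (KKC) x (HoWo)
      col2im_add(gcol, gx.begin() + (size_t)H * W * C * b, H, W, C, K, stride, pad, Ho, Wo);
    }
  }
  if (need_gx) gx.attr("dim") = d;
  return List::create(_["gx"] = gx, _["gW"] = wrap(gW), _["gb"] = wrap(gb));
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_fwd(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], B = d[3];
  NumericVector y((R_xlen_t)4 * H * W * C * B);
  const int H2 = 2 * H, W2 = 2 * W;
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + (size_t)H * W * (c + (size_t)C * b);
      double* ys = y.begin() + (size_t)H2 * W2 * (c + (size_t)C * b);
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          const double v = xs[h + (size_t)H * w];
          double* p = ys + 2 * h + (size_t)H2 * 2 * w;
          p[0] = v; p[1] = v; p[H2] = v; p[H2 + 1] = v;
        }
    }
  y.attr("dim") = IntegerVector::create(H2, W2, C, B);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bwd(NumericVector gy) {
  IntegerVector d = gy.attr("dim");
  const int H2 = d[0], W2 = d[1], C = d[2], B = d[3];
  const int H = H2 / 2, W = W2 / 2;
  NumericVector gx((R_xlen_t)H * W * C * B);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double* gs = gy.begin() + (size_t)H2 * W2 * (c + (size_t)C * b);
      double* xs = gx.begin() + (size_t)H * W * (c + (size_t)C * b);
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          const double* p = gs + 2 * h + (size_t)H2 * 2 * w;
          xs[h + (size_t)H * w] = p[0] + p[1] + p[H2] + p[H2 + 1];
        }
    }
  gx.attr("dim") = IntegerVector::create(H, W, C, B);
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool2(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], B = d[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * B);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + (size_t)H * W * (c + (size_t)C * b);
      double* ys = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * b);
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          const double* p = xs + 2 * h + (size_t)H * 2 * w;
          ys[h + (size_t)Ho * w] = 0.25 * (p[0] + p[1] + p[H] + p[H + 1]);
        }
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  return y;
}

// 26-connectivity connected components over a slice stack [H, W, S].
// [[Rcpp::export]]
IntegerVector cpp_label_components_3d(LogicalVector mask) {
  IntegerVector d = mask.attr("dim");
  const int H = d[0], W = d[1], S = d[2];
  IntegerVector lab((R_xlen_t)H * W * S);
  std::vector<size_t> stack;
  int next = 0;
  const size_t n = (size_t)H * W * S;
  for (size_t start = 0; start < n; ++start) {
    if (!mask[start] || lab[start] != 0) continue;
    ++next;
    lab[start] = next;
    stack.push_back(start);
    while (!stack.empty()) {
      const size_t v = stack.back(); stack.pop_back();
      const int h = v % H, w = (v / H) % W, s = v / ((size_t)H * W);
      for (int ds = -1; ds <= 1; ++ds)
        for (int dw = -1; dw <= 1; ++dw)
          for (int dh = -1; dh <= 1; ++dh) {
            if (dh == 0 && dw == 0 && ds == 0) continue;
            const int hh = h + dh, ww = w + dw, ss = s + ds;
            if (hh < 0 || hh >= H || ww < 0 || ww >= W || ss < 0 || ss >= S) continue;
            const size_t u = hh + (size_t)H * (ww + (size_t)W * ss);
            if (mask[u] && lab[u] == 0) { lab[u] = next; stack.push_back(u); }
          }
    }
  }
  lab.attr("dim") = d;
  return lab;
}
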