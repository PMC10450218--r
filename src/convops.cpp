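// Numeric kernels for the network: stride-1 grouped 2-D convolution via
// im2col + GEMM, 2x2 max pooling, x2 bilinear resampling, and grid average
// pooling used by the skip-transformer tokenizer. All arrays are column-major
// with dimensions (H, W, C, N); weights are (k, k, Cin/groups, Cout).
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Fill `col` ((H*W) x (k*k*Cg)) with patches of channels [c0, c0+Cg) of one
// sample. Output position index is h + H*w; column index a + k*b + k*k*ci.
static void im2col(const double* x, int H, int W, int c0, int Cg, int k,
                   int p, arma::mat& col) {
  for (int ci = 0; ci < Cg; ++ci) {
    const double* xc = x + (size_t)(c0 + ci) * H * W;
    for (int b = 0; b < k; ++b) {
      for (int a = 0; a < k; ++a) {
        double* dst = col.colptr(a + k * b + k * k * ci);
        for (int w = 0; w < W; ++w) {
          int iw = w + b - p;
          double* d = dst + (size_t)w * H;
          if (iw < 0 || iw >= W) {
            std::fill(d, d + H, 0.0);
            continue;
          }
          const double* src = xc + (size_t)iw * H;
          for (int h = 0; h < H; ++h) {
            int ih = h + a - p;
            d[h] = (ih < 0 || ih >= H) ? 0.0 : src[ih];
          }
        }
      }
    }
  }
}

// Transpose of im2col: scatter-add `col` back into gx for one sample.
static void col2im(const arma::mat& col, double* gx, int H, int W, int c0,
                   int Cg, int k, int p) {
  for (int ci = 0; ci < Cg; ++ci) {
    double* xc = gx + (size_t)(c0 + ci) * H * W;
    for (int b = 0; b < k; ++b) {
      for (int a = 0; a < k; ++a) {
        const double* src = col.colptr(a + k * b + k * k * ci);
        for (int w = 0; w < W; ++w) {
          int iw = w + b - p;
          if (iw < 0 || iw >= W) continue;
          double* d = xc + (size_t)iw * H;
          const double* s = src + (size_t)w * H;
          for (int h = 0; h < H; ++h) {
            int ih = h + a - p;
            if (ih >= 0 && ih < H) d[ih] += s[h];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, IntegerVector xdim,
                             NumericVector w, IntegerVector wdim,
                             NumericVector bias, int pad, int groups) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int k = wdim[0], Cg = wdim[2], Cout = wdim[3];
  const int Coutg = Cout / groups;
  if (Cg * groups != C) stop("input channels not divisible into groups");
  NumericVector y(NumericVector((size_t)H * W * Cout * N));
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  const arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * Cg, Cout,
                     false, true);
  arma::mat col((size_t)H * W, (size_t)k * k * Cg);
  const bool has_bias = bias.size() == Cout;
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (size_t)n * H * W * C;
    double* ys = y.begin() + (size_t)n * H * W * Cout;
    for (int g = 0; g < groups; ++g) {
      im2col(xs, H, W, g * Cg, Cg, k, pad, col);
      arma::mat Yg(ys + (size_t)g * Coutg * H * W, (size_t)H * W, Coutg,
                   false, true);
      Yg = col * Wm.cols(g * Coutg, (g + 1) * Coutg - 1);
      if (has_bias)
        for (int c = 0; c < Coutg; ++c) Yg.col(c) += bias[g * Coutg + c];
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, IntegerVector xdim, NumericVector w,
                    IntegerVector wdim, NumericVector gy, int pad,
                    int groups, bool has_bias) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int k = wdim[0], Cg = wdim[2], Cout = wdim[3];
  const int Coutg = Cout / groups;
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = xdim;
  NumericVector gw(w.size());
  gw.attr("dim") = wdim;
  NumericVector gb(has_bias ? Cout : 0);
  const arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * Cg, Cout,
                     false, true);
  arma::mat Gw(gw.begin(), (size_t)k * k * Cg, Cout, false, true);
  arma::mat col((size_t)H * W, (size_t)k * k * Cg);
  arma::mat gcol((size_t)H * W, (size_t)k * k * Cg);
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (size_t)n * H * W * C;
    const double* gys = gy.begin() + (size_t)n * H * W * Cout;
    double* gxs = gx.begin() + (size_t)n * H * W * C;
    for (int g = 0; g < groups; ++g) {
      const arma::mat Gy(const_cast<double*>(gys) + (size_t)g * Coutg * H * W,
                         (size_t)H * W, Coutg, false, true);
      im2col(xs, H, W, g * Cg, Cg, k, pad, col);
      Gw.cols(g * Coutg, (g + 1) * Coutg - 1) += col.t() * Gy;
      gcol = Gy * Wm.cols(g * Coutg, (g + 1) * Coutg - 1).t();
      col2im(gcol, gxs, H, W, g * Cg, Cg, k, pad);
      if (has_bias)
        for (int c = 0; c < Coutg; ++c)
          gb[g * Coutg + c] += arma::accu(Gy.col(c));
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List maxpool2_fwd_cpp(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  if (H % 2 || W % 2) stop("spatial size must be even for 2x2 max pooling");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = y.attr("dim");
  size_t o = 0;
  for (int cn = 0; cn < C * N; ++cn) {
    const double* plane = x.begin() + (size_t)cn * H * W;
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h, ++o) {
        // scan the 2x2 window in column-major order; ties keep the first
        int base = 2 * h + H * 2 * w;
        int best = base;
        double bv = plane[base];
        int cand[3] = {base + 1, base + H, base + H + 1};
        for (int t = 0; t < 3; ++t)
          if (plane[cand[t]] > bv) { bv = plane[cand[t]]; best = cand[t]; }
        y[o] = bv;
        idx[o] = best;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd_cpp(IntegerVector idx, NumericVector gy,
                               IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = xdim;
  const size_t plane = (size_t)H * W, oplane = plane / 4;
  for (int cn = 0; cn < C * N; ++cn) {
    double* g = gx.begin() + (size_t)cn * plane;
    const double* gyp = gy.begin() + (size_t)cn * oplane;
    const int* ip = idx.begin() + (size_t)cn * oplane;
    for (size_t o = 0; o < oplane; ++o) g[ip[o]] += gyp[o];
  }
  return gx;
}

// Per-axis source indices/weights for x2 bilinear resampling with the
// half-pixel (align_corners = FALSE) convention.
static void up2_axis(int n, std::vector<int>& i0, std::vector<int>& i1,
                     std::vector<double>& f) {
  i0.resize(2 * n); i1.resize(2 * n); f.resize(2 * n);
  for (int o = 0; o < 2 * n; ++o) {
    double s = 0.5 * o - 0.25;
    int lo = (int)std::floor(s);
    double fr = s - lo;
    if (lo < 0) { lo = 0; fr = 0.0; }
    if (lo >= n - 1) { lo = n - 1; fr = 0.0; }
    i0[o] = lo;
    i1[o] = (lo < n - 1) ? lo + 1 : lo;
    f[o] = fr;
  }
}

// [[Rcpp::export]]
NumericVector upsample2_fwd_cpp(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  NumericVector y((size_t)4 * H * W * C * N);
  y.attr("dim") = IntegerVector::create(2 * H, 2 * W, C, N);
  std::vector<int> h0, h1, w0, w1;
  std::vector<double> fh, fw;
  up2_axis(H, h0, h1, fh);
  up2_axis(W, w0, w1, fw);
  for (int cn = 0; cn < C * N; ++cn) {
    const double* p = x.begin() + (size_t)cn * H * W;
    double* q = y.begin() + (size_t)cn * 4 * H * W;
    for (int w = 0; w < 2 * W; ++w) {
      const double* cl = p + (size_t)w0[w] * H;
      const double* cr = p + (size_t)w1[w] * H;
      double* qc = q + (size_t)w * 2 * H;
      for (int h = 0; h < 2 * H; ++h) {
        double top = (1 - fh[h]) * cl[h0[h]] + fh[h] * cl[h1[h]];
        double bot = (1 - fh[h]) * cr[h0[h]] + fh[h] * cr[h1[h]];
        qc[h] = (1 - fw[w]) * top + fw[w] * bot;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector upsample2_bwd_cpp(NumericVector gy, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = xdim;
  std::vector<int> h0, h1, w0, w1;
  std::vector<double> fh, fw;
  up2_axis(H, h0, h1, fh);
  up2_axis(W, w0, w1, fw);
  for (int cn = 0; cn < C * N; ++cn) {
    double* p = gx.begin() + (size_t)cn * H * W;
    const double* q = gy.begin() + (size_t)cn * 4 * H * W;
    for (int w = 0; w < 2 * W; ++w) {
      double* cl = p + (size_t)w0[w] * H;
      double* cr = p + (size_t)w1[w] * H;
      const double* qc = q + (size_t)w * 2 * H;
      for (int h = 0; h < 2 * H; ++h) {
        double g = qc[h];
        cl[h0[h]] += (1 - fw[w]) * (1 - fh[h]) * g;
        cl[h1[h]] += (1 - fw[w]) * fh[h] * g;
        cr[h0[h]] += fw[w] * (1 - fh[h]) * g;
        cr[h1[h]] += fw[w] * fh[h] * g;
      }
    }
  }
  return gx;
}

// Average-pool each channel plane onto a gh x gw grid of equal patches,
// producing token sequences of length gh*gw (grid index gy + gh*gx).
// [[Rcpp::export]]
NumericVector avgpool_grid_fwd_cpp(NumericVector x, IntegerVector xdim,
                                   int gh, int gw) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  if (H % gh || W % gw) stop("grid must divide the spatial size");
  const int ph = H / gh, pw = W / gw, d = gh * gw;
  NumericVector t((size_t)d * C * N);
  t.attr("dim") = IntegerVector::create(d, C, N);
  const double inv = 1.0 / ((double)ph * pw);
  for (int cn = 0; cn < C * N; ++cn) {
    const double* p = x.begin() + (size_t)cn * H * W;
    double* q = t.begin() + (size_t)cn * d;
    for (int w = 0; w < W; ++w) {
      const double* cp = p + (size_t)w * H;
      double* qg = q + (size_t)gh * (w / pw);
      for (int h = 0; h < H; ++h) qg[h / ph] += cp[h] * inv;
    }
  }
  return t;
}

// [[Rcpp::export]]
NumericVector avgpool_grid_bwd_cpp(NumericVector gt, IntegerVector xdim,
                                   int gh, int gw) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int ph = H / gh, pw = W / gw, d = gh * gw;
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = xdim;
  const double inv = 1.0 / ((double)ph * pw);
  for (int cn = 0; cn < C * N; ++cn) {
    double* p = gx.begin() + (size_t)cn * H * W;
    const double* q = gt.begin() + (size_t)cn * d;
    for (int w = 0; w < W; ++w) {
      double* cp = p + (size_t)w * H;
      const double* qg = q + (size_t)gh * (w / pw);
      for (int h = 0; h < H; ++h) cp[h] = qg[h / ph] * inv;
    }
  }
  return gx;
}

// Broadcast tokens back to a feature map: each pixel takes the token of the
// grid patch it falls in (nearest-neighbour inverse of the tokenizer).
// [[Rcpp::export]]
NumericVector tokens_to_map_fwd_cpp(NumericVector t, IntegerVector tdim,
                                    int gh, int gw, int H, int W) {
  const int d = tdim[0], C = tdim[1], N = tdim[2];
  if (d != gh * gw) stop("token length does not match grid");
  const int ph = H / gh, pw = W / gw;
  NumericVector y((size_t)H * W * C * N);
  y.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int cn = 0; cn < C * N; ++cn) {
    double* p = y.begin() + (size_t)cn * H * W;
    const double* q = t.begin() + (size_t)cn * d;
    for (int w = 0; w < W; ++w) {
      double* cp = p + (size_t)w * H;
      const double* qg = q + (size_t)gh * (w / pw);
      for (int h = 0; h < H; ++h) cp[h] = qg[h / ph];
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector tokens_to_map_bwd_cpp(NumericVector gy, IntegerVector ydim,
                                    int gh, int gw) {
  const int H = ydim[0], W = ydim[1], C = ydim[2], N = ydim[3];
  const int ph = H / gh, pw = W / gw, d = gh * gw;
  NumericVector gt((size_t)d * C * N);
  gt.attr("dim") = IntegerVector::create(d, C, N);
  for (int cn = 0; cn < C * N; ++cn) {
    const double* p = gy.begin() + (size_t)cn * H * W;
    double* q = gt.begin() + (size_t)cn * d;
    for (int w = 0; w < W; ++w) {
      const double* cp = p + (size_t)w * H;
      double* qg = q + (size_t)gh * (w / pw);
      for (int h = 0; h < H; ++h) qg[h / ph] += cp[h];
    }
  }
  return gt;
}
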