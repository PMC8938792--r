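// Low-level kernels for the segmentation network.
// Tensor layout everywhere: column-major R arrays dim = (H, W, C, N).
// Dense conv weights: dim = (k, k, C_in, C_out); depthwise: (k, k, C).
// "Same" padding in the TensorFlow sense: out = ceil(in / stride).

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int out_dim(int in, int stride) { return (in + stride - 1) / stride; }

static inline void pad_amount(int in, int k, int stride, int dilation,
                              int &pad_beg, int &out) {
  int ke = dilation * (k - 1) + 1;
  out = out_dim(in, stride);
  int total = std::max(0, (out - 1) * stride + ke - in);
  pad_beg = total / 2;
}

// im2col for one sample. x: (H, W, C) slab; col: (k*k*C) x (Ho*Wo).
// Row ordering matches column-major flatten of (k, k, C).
static void im2col(const double *x, int H, int W, int C,
                   int k, int stride, int dilation,
                   int pad_h, int pad_w, int Ho, int Wo,
                   arma::mat &col) {
  for (int c = 0; c < C; ++c) {
    const double *xc = x + (size_t)c * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        int row = kh + k * (kw + k * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad_w + kw * dilation;
          double *dst = col.colptr(0) + row; // stride across columns below
          if (wi < 0 || wi >= W) {
            for (int ho = 0; ho < Ho; ++ho)
              col(row, ho + Ho * wo) = 0.0;
            continue;
          }
          const double *xcol = xc + (size_t)wi * H;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad_h + kh * dilation;
            col(row, ho + Ho * wo) =
                (hi >= 0 && hi < H) ? xcol[hi] : 0.0;
          }
          (void)dst;
        }
      }
    }
  }
}

// col2im accumulation (transpose of im2col).
static void col2im(const arma::mat &col, int H, int W, int C,
                   int k, int stride, int dilation,
                   int pad_h, int pad_w, int Ho, int Wo,
                   double *gx) {
  for (int c = 0; c < C; ++c) {
    double *xc = gx + (size_t)c * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        int row = kh + k * (kw + k * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad_w + kw * dilation;
          if (wi < 0 || wi >= W) continue;
          double *xcol = xc + (size_t)wi * H;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad_h + kh * dilation;
            if (hi >= 0 && hi < H)
              xcol[hi] += col(row, ho + Ho * wo);
          }
        }
      }
    }
  }
}

// [[Rcpp::export(rng = false)]]
NumericVector nn_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                            int stride, int dilation) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch in conv2d");
  int pad_h, pad_w, Ho, Wo;
  pad_amount(H, k, stride, dilation, pad_h, Ho);
  pad_amount(W, k, stride, dilation, pad_w, Wo);

  arma::mat Wm(const_cast<double *>(w.begin()), k * k * Cin, Cout, false, true);
  arma::vec bv(const_cast<double *>(b.begin()), Cout, false, true);

  NumericVector y(Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat col(k * k * Cin, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, stride, dilation,
           pad_h, pad_w, Ho, Wo, col);
    arma::mat out(y.begin() + (size_t)n * Ho * Wo * Cout, Ho * Wo, Cout,
                  false, true);
    out = col.t() * Wm;
    out.each_row() += bv.t();
  }
  return y;
}

// [[Rcpp::export(rng = false)]]
List nn_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                   int stride, int dilation) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cin = wd[2], Cout = wd[3];
  int pad_h, pad_w, Ho, Wo;
  pad_amount(H, k, stride, dilation, pad_h, Ho);
  pad_amount(W, k, stride, dilation, pad_w, Wo);

  arma::mat Wm(const_cast<double *>(w.begin()), k * k * Cin, Cout, false, true);
  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(Cout);
  arma::mat gWm(gw.begin(), k * k * Cin, Cout, false, true);
  arma::vec gbv(gb.begin(), Cout, false, true);

  arma::mat col(k * k * Cin, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, stride, dilation,
           pad_h, pad_w, Ho, Wo, col);
    arma::mat g(const_cast<double *>(gy.begin()) + (size_t)n * Ho * Wo * Cout,
                Ho * Wo, Cout, false, true);
    gWm += col * g;
    gbv += arma::sum(g, 0).t();
    arma::mat gcol = Wm * g.t(); // (k*k*Cin) x (Ho*Wo)
    col2im(gcol, H, W, C, k, stride, dilation, pad_h, pad_w, Ho, Wo,
           gx.begin() + (size_t)n * H * W * C);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export(rng = false)]]
NumericVector nn_dwconv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                              int stride, int dilation) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0];
  int pad_h, pad_w, Ho, Wo;
  pad_amount(H, k, stride, dilation, pad_h, Ho);
  pad_amount(W, k, stride, dilation, pad_w, Wo);
  NumericVector y(Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);

  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *xc = x.begin() + ((size_t)n * C + c) * H * W;
      const double *wc = w.begin() + (size_t)c * k * k;
      double *yc = y.begin() + ((size_t)n * C + c) * Ho * Wo;
      double bias = b[c];
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = bias;
          for (int kw = 0; kw < k; ++kw) {
            int wi = wo * stride - pad_w + kw * dilation;
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              int hi = ho * stride - pad_h + kh * dilation;
              if (hi < 0 || hi >= H) continue;
              acc += xc[hi + (size_t)wi * H] * wc[kh + k * kw];
            }
          }
          yc[ho + (size_t)wo * Ho] = acc;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export(rng = false)]]
List nn_dwconv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                     int stride, int dilation) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0];
  int pad_h, pad_w, Ho, Wo;
  pad_amount(H, k, stride, dilation, pad_h, Ho);
  pad_amount(W, k, stride, dilation, pad_w, Wo);
  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(C);

  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *xc = x.begin() + ((size_t)n * C + c) * H * W;
      const double *wc = w.begin() + (size_t)c * k * k;
      const double *gyc = gy.begin() + ((size_t)n * C + c) * Ho * Wo;
      double *gxc = gx.begin() + ((size_t)n * C + c) * H * W;
      double *gwc = gw.begin() + (size_t)c * k * k;
      double gbc = 0.0;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double g = gyc[ho + (size_t)wo * Ho];
          gbc += g;
          for (int kw = 0; kw < k; ++kw) {
            int wi = wo * stride - pad_w + kw * dilation;
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              int hi = ho * stride - pad_h + kh * dilation;
              if (hi < 0 || hi >= H) continue;
              double xv = xc[hi + (size_t)wi * H];
              gwc[kh + k * kw] += g * xv;
              gxc[hi + (size_t)wi * H] += g * wc[kh + k * kw];
            }
          }
        }
      }
      gb[c] += gbc;
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Bilinear resize, half-pixel centers (align_corners = FALSE).
// [[Rcpp::export(rng = false)]]
NumericVector nn_bilinear_fwd(NumericVector x, int Ho, int Wo) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y(Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  double sh = (double)H / Ho, sw = (double)W / Wo;
  std::vector<int> h0(Ho), h1(Ho);
  std::vector<double> ah(Ho);
  for (int i = 0; i < Ho; ++i) {
    double s = (i + 0.5) * sh - 0.5;
    double f = std::floor(s);
    int i0 = (int)f;
    ah[i] = s - f;
    h0[i] = std::min(std::max(i0, 0), H - 1);
    h1[i] = std::min(std::max(i0 + 1, 0), H - 1);
  }
  std::vector<int> w0(Wo), w1(Wo);
  std::vector<double> aw(Wo);
  for (int j = 0; j < Wo; ++j) {
    double s = (j + 0.5) * sw - 0.5;
    double f = std::floor(s);
    int j0 = (int)f;
    aw[j] = s - f;
    w0[j] = std::min(std::max(j0, 0), W - 1);
    w1[j] = std::min(std::max(j0 + 1, 0), W - 1);
  }
  size_t plane_in = (size_t)H * W, plane_out = (size_t)Ho * Wo;
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double *xc = x.begin() + cn * plane_in;
    double *yc = y.begin() + cn * plane_out;
    for (int j = 0; j < Wo; ++j) {
      const double *c0 = xc + (size_t)w0[j] * H;
      const double *c1 = xc + (size_t)w1[j] * H;
      for (int i = 0; i < Ho; ++i) {
        double top = c0[h0[i]] * (1 - ah[i]) + c0[h1[i]] * ah[i];
        double bot = c1[h0[i]] * (1 - ah[i]) + c1[h1[i]] * ah[i];
        yc[i + (size_t)j * Ho] = top * (1 - aw[j]) + bot * aw[j];
      }
    }
  }
  return y;
}

// [[Rcpp::export(rng = false)]]
NumericVector nn_bilinear_bwd(NumericVector gy, int H, int W) {
  IntegerVector yd = gy.attr("dim");
  int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  double sh = (double)H / Ho, sw = (double)W / Wo;
  size_t plane_in = (size_t)H * W, plane_out = (size_t)Ho * Wo;
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double *gyc = gy.begin() + cn * plane_out;
    double *gxc = gx.begin() + cn * plane_in;
    for (int j = 0; j < Wo; ++j) {
      double s = (j + 0.5) * sw - 0.5;
      double f = std::floor(s);
      int j0 = (int)f;
      double a = s - f;
      int jw0 = std::min(std::max(j0, 0), W - 1);
      int jw1 = std::min(std::max(j0 + 1, 0), W - 1);
      for (int i = 0; i < Ho; ++i) {
        double t = (i + 0.5) * sh - 0.5;
        double ft = std::floor(t);
        int i0 = (int)ft;
        double b = t - ft;
        int ih0 = std::min(std::max(i0, 0), H - 1);
        int ih1 = std::min(std::max(i0 + 1, 0), H - 1);
        double g = gyc[i + (size_t)j * Ho];
        gxc[ih0 + (size_t)jw0 * H] += g * (1 - b) * (1 - a);
        gxc[ih1 + (size_t)jw0 * H] += g * b * (1 - a);
        gxc[ih0 + (size_t)jw1 * H] += g * (1 - b) * a;
        gxc[ih1 + (size_t)jw1 * H] += g * b * a;
      }
    }
  }
  return gx;
}

// Softmax cross-entropy over class dim with ignore label (< 0) and
// optional per-class weights (length K; empty = unweighted).
// logits: (H, W, K, N); labels: (H, W, N) integer 0-based, -1 = ignore.
// Per-sample loss = sum(w_y * CE) / sum(w_y); gradients normalised the
// same way so losses are weighted means.
// [[Rcpp::export(rng = false)]]
List nn_softmax_xent(NumericVector logits, IntegerVector labels,
                     bool want_probs,
                     NumericVector class_weights = NumericVector::create()) {
  IntegerVector ld = logits.attr("dim");
  int H = ld[0], W = ld[1], K = ld[2], N = ld[3];
  NumericVector gl(logits.size());
  gl.attr("dim") = ld;
  NumericVector loss(N), npix(N);
  NumericVector probs;
  if (want_probs) {
    probs = NumericVector(logits.size());
    probs.attr("dim") = ld;
  }
  size_t plane = (size_t)H * W;
  bool weighted = class_weights.size() == K;
  std::vector<double> p(K);
  for (int n = 0; n < N; ++n) {
    const double *lo = logits.begin() + (size_t)n * plane * K;
    double *g = gl.begin() + (size_t)n * plane * K;
    const int *lab = labels.begin() + (size_t)n * plane;
    double L = 0.0, wsum = 0.0;
    int cnt = 0;
    for (size_t px = 0; px < plane; ++px) {
      double m = -1e300;
      for (int k = 0; k < K; ++k) m = std::max(m, lo[px + plane * k]);
      double Z = 0.0;
      for (int k = 0; k < K; ++k) {
        p[k] = std::exp(lo[px + plane * k] - m);
        Z += p[k];
      }
      for (int k = 0; k < K; ++k) p[k] /= Z;
      if (want_probs)
        for (int k = 0; k < K; ++k)
          probs[px + plane * k + (size_t)n * plane * K] = p[k];
      int y = lab[px];
      if (y < 0) continue; // ignore: zero gradient
      if (y >= K) stop("label %d out of range for %d classes", y, K);
      ++cnt;
      double wy = weighted ? class_weights[y] : 1.0;
      wsum += wy;
      L += -wy * std::log(std::max(p[y], 1e-12));
      for (int k = 0; k < K; ++k)
        g[px + plane * k] = wy * (p[k] - (k == y ? 1.0 : 0.0));
    }
    loss[n] = wsum > 0 ? L / wsum : 0.0;
    npix[n] = cnt;
    // normalise gradient by total weight so per-sample losses are
    // (weighted) means
    if (wsum > 0) {
      double inv = 1.0 / wsum;
      for (size_t q = 0; q < plane * K; ++q) g[q] *= inv;
    }
  }
  List out = List::create(_["loss"] = loss, _["glogits"] = gl,
                          _["npix"] = npix);
  if (want_probs) out["probs"] = probs;
  return out;
}
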