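// Minimal CPU convolution engine used by the generator/discriminator.
// Layout convention: images are R arrays with dim (H, W, C, N), column-major,
// so H is the fastest index. Kernels are (k, k, Cin, Cout).
// Convolutions use explicit (possibly asymmetric) zero padding; the R side
// computes the "same"-padding amounts. Patch matrices are built in chunks of
// output columns so peak memory stays bounded for large kernels at 256x256.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
typedef arma::fmat fm;

static inline int out_size(int in, int k, int stride, int pad_a, int pad_b) {
  return (in + pad_a + pad_b - k) / stride + 1;
}

// Fill a (k*k*Cin) x (Ho*(wo1-wo0)) patch matrix for output columns
// [wo0, wo1) of one sample. Row index runs over (dh, dw, c), dh fastest,
// matching the (k, k, Cin) kernel layout.
static void im2col(const float* x, int H, int W, int C,
                   int k, int stride, int pad_top, int pad_left,
                   int Ho, int wo0, int wo1, fm& col) {
  for (int wo = wo0; wo < wo1; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      float* dst = col.colptr((size_t)(wo - wo0) * Ho + ho);
      const int h0 = ho * stride - pad_top;
      const int w0 = wo * stride - pad_left;
      for (int c = 0; c < C; ++c) {
        const float* xc = x + (size_t)c * H * W;
        for (int dw = 0; dw < k; ++dw) {
          const int w = w0 + dw;
          const bool w_ok = (w >= 0 && w < W);
          for (int dh = 0; dh < k; ++dh) {
            const int h = h0 + dh;
            const size_t r = (size_t)c * k * k + (size_t)dw * k + dh;
            dst[r] = (w_ok && h >= 0 && h < H) ? xc[(size_t)w * H + h] : 0.0f;
          }
        }
      }
    }
  }
}

// Scatter-add a patch matrix back into an image (adjoint of im2col).
static void col2im(const fm& col, float* x, int H, int W, int C,
                   int k, int stride, int pad_top, int pad_left,
                   int Ho, int wo0, int wo1) {
  for (int wo = wo0; wo < wo1; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const float* src = col.colptr((size_t)(wo - wo0) * Ho + ho);
      const int h0 = ho * stride - pad_top;
      const int w0 = wo * stride - pad_left;
      for (int c = 0; c < C; ++c) {
        float* xc = x + (size_t)c * H * W;
        for (int dw = 0; dw < k; ++dw) {
          const int w = w0 + dw;
          if (w < 0 || w >= W) continue;
          for (int dh = 0; dh < k; ++dh) {
            const int h = h0 + dh;
            if (h < 0 || h >= H) continue;
            xc[(size_t)w * H + h] += src[(size_t)c * k * k + (size_t)dw * k + dh];
          }
        }
      }
    }
  }
}

// Output-column chunk size keeping the patch matrix under ~64 MB.
static int chunk_cols(int Ho, int rows) {
  double budget = 8e6;  // doubles
  int wo_chunk = (int)(budget / ((double)rows * Ho));
  if (wo_chunk < 1) wo_chunk = 1;
  return wo_chunk;
}

// [[Rcpp::export(name = ".conv2d_forward")]]
NumericVector conv2d_forward(NumericVector x, NumericVector w,
                             Nullable<NumericVector> bias,
                             int stride, int pad_top, int pad_bottom,
                             int pad_left, int pad_right) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch between input and kernel");
  const int Ho = out_size(H, k, stride, pad_top, pad_bottom);
  const int Wo = out_size(W, k, stride, pad_left, pad_right);
  const int rows = k * k * Cin;

  fm wm(rows, Cout);
  std::copy(w.begin(), w.end(), wm.memptr());
  std::vector<float> xf((size_t)H * W * C);
  const int wo_chunk = chunk_cols(Ho, rows);
  fm col(rows, (size_t)Ho * std::min(wo_chunk, Wo));

  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  arma::frowvec b;
  const bool has_bias = bias.isNotNull();
  if (has_bias) {
    NumericVector bv(bias);
    b.set_size(Cout);
    std::copy(bv.begin(), bv.end(), b.memptr());
  }

  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    std::copy(xn, xn + (size_t)H * W * C, xf.begin());
    double* yn = y.begin() + (size_t)n * Ho * Wo * Cout;
    for (int wo0 = 0; wo0 < Wo; wo0 += wo_chunk) {
      const int wo1 = std::min(wo0 + wo_chunk, Wo);
      const size_t npos = (size_t)(wo1 - wo0) * Ho;
      fm colv(col.memptr(), rows, npos, false, true);
      im2col(xf.data(), H, W, C, k, stride, pad_top, pad_left, Ho, wo0, wo1,
             colv);
      fm yc = colv.t() * wm;
      if (has_bias) yc.each_row() += b;
      for (int co = 0; co < Cout; ++co) {
        const float* s = yc.colptr(co);
        double* d = yn + (size_t)co * Ho * Wo + (size_t)wo0 * Ho;
        for (size_t i = 0; i < npos; ++i) d[i] = (double)s[i];
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_backward")]]
List conv2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                     int stride, int pad_top, int pad_bottom,
                     int pad_left, int pad_right,
                     bool need_dx, bool need_dw, bool has_bias) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector yd = dy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int Ho = yd[0], Wo = yd[1];
  const int rows = k * k * C;

  fm wm(rows, Cout);
  std::copy(w.begin(), w.end(), wm.memptr());
  const int wo_chunk = chunk_cols(Ho, rows);
  fm col(rows, (size_t)Ho * std::min(wo_chunk, Wo));
  std::vector<float> xf((size_t)H * W * C), dxf;

  NumericVector dx;
  fm dwm;
  arma::frowvec db;
  if (need_dx) {
    dx = NumericVector((size_t)H * W * C * N);
    dx.attr("dim") = IntegerVector::create(H, W, C, N);
    dxf.resize((size_t)H * W * C);
  }
  if (need_dw) {
    dwm.zeros(rows, Cout);
    db.zeros(Cout);
  }

  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    if (need_dw) std::copy(xn, xn + (size_t)H * W * C, xf.begin());
    const double* dyn = dy.begin() + (size_t)n * Ho * Wo * Cout;
    if (need_dx) std::fill(dxf.begin(), dxf.end(), 0.0f);
    for (int wo0 = 0; wo0 < Wo; wo0 += wo_chunk) {
      const int wo1 = std::min(wo0 + wo_chunk, Wo);
      const size_t npos = (size_t)(wo1 - wo0) * Ho;
      fm dyc(npos, Cout);
      for (int co = 0; co < Cout; ++co) {
        const double* s = dyn + (size_t)co * Ho * Wo + (size_t)wo0 * Ho;
        float* d = dyc.colptr(co);
        for (size_t i = 0; i < npos; ++i) d[i] = (float)s[i];
      }
      if (need_dw) {
        fm colv(col.memptr(), rows, npos, false, true);
        im2col(xf.data(), H, W, C, k, stride, pad_top, pad_left, Ho, wo0, wo1,
               colv);
        dwm += colv * dyc;
        if (has_bias) db += arma::sum(dyc, 0);
      }
      if (need_dx) {
        fm dcol = wm * dyc.t();  // rows x npos
        col2im(dcol, dxf.data(), H, W, C, k, stride, pad_top, pad_left,
               Ho, wo0, wo1);
      }
    }
    if (need_dx) {
      double* dxn = dx.begin() + (size_t)n * H * W * C;
      for (size_t i = 0; i < dxf.size(); ++i) dxn[i] = (double)dxf[i];
    }
  }

  List out = List::create(Named("dx") = R_NilValue,
                          Named("dw") = R_NilValue,
                          Named("db") = R_NilValue);
  if (need_dx) out["dx"] = dx;
  if (need_dw) {
    NumericVector dwv(dwm.n_elem);
    for (size_t i = 0; i < dwm.n_elem; ++i) dwv[i] = (double)dwm(i);
    dwv.attr("dim") = IntegerVector::create(k, k, C, Cout);
    out["dw"] = dwv;
    if (has_bias) {
      NumericVector dbv(Cout);
      for (int i = 0; i < Cout; ++i) dbv[i] = (double)db(i);
      out["db"] = dbv;
    }
  }
  return out;
}

// 2x2 max pooling, stride 2. Returns pooled values and flat argmax indices
// (1-based into the input array) for the backward pass.
// [[Rcpp::export(name = ".maxpool2_forward")]]
List maxpool2_forward(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          const int h = 2 * ho, w = 2 * wo;
          size_t i00 = base + (size_t)w * H + h;
          size_t best = i00; double v = x[i00];
          size_t i10 = i00 + 1;        if (x[i10] > v) { v = x[i10]; best = i10; }
          size_t i01 = i00 + H;        if (x[i01] > v) { v = x[i01]; best = i01; }
          size_t i11 = i00 + H + 1;    if (x[i11] > v) { v = x[i11]; best = i11; }
          y[o] = v; idx[o] = (int)(best + 1); ++o;
        }
      }
    }
  }
  return List::create(Named("y") = y, Named("idx") = idx);
}

// [[Rcpp::export(name = ".maxpool2_backward")]]
NumericVector maxpool2_backward(NumericVector dy, IntegerVector idx,
                                IntegerVector in_dim) {
  size_t total = (size_t)in_dim[0] * in_dim[1] * in_dim[2] * in_dim[3];
  NumericVector dx(total);
  dx.attr("dim") = in_dim;
  const R_xlen_t m = dy.size();
  for (R_xlen_t i = 0; i < m; ++i) dx[idx[i] - 1] += dy[i];
  return dx;
}
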