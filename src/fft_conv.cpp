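// FFT-domain convolution for stride-1 "same" convolutions with large odd
// kernels (the 5x5/7x7/11x11 inception branches). Direct im2col inflates
// memory and bandwidth by k^2; in the frequency domain the cost per branch is
// Cin*Cout*P^2 complex multiply-adds, independent of k. Single precision
// (FFTW3f); adequate for gradient-based training and verified against the
// dense path in the test suite.
//
// Conventions (0-indexed, p = (k-1)/2, P >= H + k - 1):
//   forward:  y(i) = sum_d w(d) x(i + d - p)       [cross-correlation]
//             y(i) = conv(x, rot180(w))(i + p)
//   backward: dx(t) = conv(dy, w)(t + p)
//             dw(d) = corr(x, dy)(d - p) = IFFT(FFT(x) .* conj(FFT(dy)))

#include <Rcpp.h>
#include <fftw3.h>
#include <complex>
#include <unordered_map>
#include <vector>
#include <cstring>

using namespace Rcpp;
typedef std::complex<float> cf;

struct PlanPair {
  fftwf_plan fwd, inv;
  int P, nb;                 // padded side, complex bins = P*(P/2+1)
  float* real_buf;
  fftwf_complex* cplx_buf;
};

static std::unordered_map<int, PlanPair>& plan_cache() {
  static std::unordered_map<int, PlanPair> cache;
  return cache;
}

static PlanPair& get_plans(int P) {
  auto& cache = plan_cache();
  auto it = cache.find(P);
  if (it != cache.end()) return it->second;
  PlanPair pp;
  pp.P = P;
  pp.nb = P * (P / 2 + 1);
  pp.real_buf = (float*)fftwf_malloc(sizeof(float) * P * P);
  pp.cplx_buf = (fftwf_complex*)fftwf_malloc(sizeof(fftwf_complex) * pp.nb);
  pp.fwd = fftwf_plan_dft_r2c_2d(P, P, pp.real_buf, pp.cplx_buf,
                                 FFTW_MEASURE);
  pp.inv = fftwf_plan_dft_c2r_2d(P, P, pp.cplx_buf, pp.real_buf,
                                 FFTW_MEASURE);
  return cache.emplace(P, pp).first->second;
}

// smallest even 5-smooth number >= n (FFTW's real transforms are fastest
// on even, highly composite sizes)
static int good_size(int n) {
  for (int m = n + (n % 2);; m += 2) {
    int r = m;
    for (int f : {2, 3, 5}) while (r % f == 0) r /= f;
    if (r == 1) return m;
  }
}

// FFT of an H x W tile (column-major, leading dim H) embedded at the origin
// of a P x P zero frame.
static void fft_tile(PlanPair& pp, const double* src, int H, int W,
                     cf* dst, bool rot180 = false, int k = 0) {
  const int P = pp.P;
  std::memset(pp.real_buf, 0, sizeof(float) * P * P);
  if (!rot180) {
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h)
        pp.real_buf[(size_t)h * P + w] = (float)src[(size_t)w * H + h];
  } else {
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h)
        pp.real_buf[(size_t)(k - 1 - h) * P + (k - 1 - w)] =
          (float)src[(size_t)w * H + h];
  }
  fftwf_execute_dft_r2c(pp.fwd, pp.real_buf, pp.cplx_buf);
  std::memcpy(dst, pp.cplx_buf, sizeof(cf) * pp.nb);
}

// inverse FFT, crop the (r0 + i, r0 + j) window, write (add) into dst
static void ifft_crop(PlanPair& pp, const cf* src, double* dst,
                      int H, int W, int r0, bool add) {
  const int P = pp.P;
  const float scale = 1.0f / ((float)P * P);
  std::memcpy(pp.cplx_buf, src, sizeof(cf) * pp.nb);
  fftwf_execute_dft_c2r(pp.inv, pp.cplx_buf, pp.real_buf);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      double v = (double)(pp.real_buf[(size_t)(h + r0) * P + (w + r0)] * scale);
      if (add) dst[(size_t)w * H + h] += v;
      else dst[(size_t)w * H + h] = v;
    }
}

// per-layer forward caches (input and kernel spectra), keyed by layer id
struct FwdCache {
  int H, W, C, N, k, P;
  std::vector<cf> Xf, Wf;
};
static std::unordered_map<int, FwdCache>& fwd_cache() {
  static std::unordered_map<int, FwdCache> cache;
  return cache;
}

// [[Rcpp::export(name = ".fftconv_forward")]]
NumericVector fftconv_forward(NumericVector x, NumericVector w,
                              Nullable<NumericVector> bias,
                              int layer_id, bool keep_cache) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int p = (k - 1) / 2;
  const int P = good_size(std::max(H, W) + k - 1);
  PlanPair& pp = get_plans(P);
  const int nb = pp.nb;

  std::vector<cf> Xf((size_t)nb * C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      fft_tile(pp, x.begin() + ((size_t)n * C + c) * H * W, H, W,
               Xf.data() + ((size_t)n * C + c) * nb);

  std::vector<cf> Wf((size_t)nb * C * Cout);
  for (int co = 0; co < Cout; ++co)
    for (int c = 0; c < C; ++c)
      fft_tile(pp, w.begin() + ((size_t)co * C + c) * k * k, k, k,
               Wf.data() + ((size_t)co * C + c) * nb, true, k);

  NumericVector y((size_t)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  const double* bptr = nullptr;
  NumericVector bv;
  if (bias.isNotNull()) { bv = NumericVector(bias); bptr = bv.begin(); }

  std::vector<cf> acc(nb);
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Cout; ++co) {
      std::memset(acc.data(), 0, sizeof(cf) * nb);
      float* ac = reinterpret_cast<float*>(acc.data());
      for (int c = 0; c < C; ++c) {
        const float* xf = reinterpret_cast<const float*>(
          Xf.data() + ((size_t)n * C + c) * nb);
        const float* wf = reinterpret_cast<const float*>(
          Wf.data() + ((size_t)co * C + c) * nb);
        for (int i = 0; i < nb; ++i) {
          const float xr = xf[2 * i], xi = xf[2 * i + 1];
          const float wr = wf[2 * i], wi = wf[2 * i + 1];
          ac[2 * i] += xr * wr - xi * wi;
          ac[2 * i + 1] += xr * wi + xi * wr;
        }
      }
      double* yp = y.begin() + ((size_t)n * Cout + co) * H * W;
      ifft_crop(pp, acc.data(), yp, H, W, p, false);
      if (bptr) for (size_t i = 0; i < (size_t)H * W; ++i) yp[i] += bptr[co];
    }
  }

  if (keep_cache) {
    FwdCache fc;
    fc.H = H; fc.W = W; fc.C = C; fc.N = N; fc.k = k; fc.P = P;
    fc.Xf = std::move(Xf);
    fc.Wf = std::move(Wf);
    fwd_cache()[layer_id] = std::move(fc);
  }
  return y;
}

// [[Rcpp::export(name = ".fftconv_backward")]]
List fftconv_backward(NumericVector w, NumericVector dy, int layer_id,
                      bool need_dx, bool has_bias) {
  auto it = fwd_cache().find(layer_id);
  if (it == fwd_cache().end()) stop("no cached forward for fft conv layer");
  FwdCache& fc = it->second;
  IntegerVector wd = w.attr("dim");
  const int H = fc.H, W = fc.W, C = fc.C, N = fc.N, k = fc.k;
  const int Cout = wd[3];
  const int p = (k - 1) / 2;
  PlanPair& pp = get_plans(fc.P);
  const int nb = pp.nb;

  // spectra of dy
  std::vector<cf> dYf((size_t)nb * Cout * N);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co)
      fft_tile(pp, dy.begin() + ((size_t)n * Cout + co) * H * W, H, W,
               dYf.data() + ((size_t)n * Cout + co) * nb);

  // dw(d) = sum_n IFFT(Xf .* conj(dYf))(d - p mod P)
  NumericVector dwv((size_t)k * k * C * Cout);
  dwv.attr("dim") = IntegerVector::create(k, k, C, Cout);
  std::vector<cf> acc(nb);
  std::vector<double> ctile((size_t)fc.P * fc.P);
  for (int co = 0; co < Cout; ++co) {
    for (int c = 0; c < C; ++c) {
      std::memset(acc.data(), 0, sizeof(cf) * nb);
      float* ac = reinterpret_cast<float*>(acc.data());
      for (int n = 0; n < N; ++n) {
        const float* xf = reinterpret_cast<const float*>(
          fc.Xf.data() + ((size_t)n * C + c) * nb);
        const float* df = reinterpret_cast<const float*>(
          dYf.data() + ((size_t)n * Cout + co) * nb);
        for (int i = 0; i < nb; ++i) {
          const float xr = xf[2 * i], xi = xf[2 * i + 1];
          const float dr = df[2 * i], di = -df[2 * i + 1];
          ac[2 * i] += xr * dr - xi * di;
          ac[2 * i + 1] += xr * di + xi * dr;
        }
      }
      // full inverse transform, then pick lags d - p (mod P)
      const float scale = 1.0f / ((float)fc.P * fc.P);
      std::memcpy(pp.cplx_buf, acc.data(), sizeof(cf) * nb);
      fftwf_execute_dft_c2r(pp.inv, pp.cplx_buf, pp.real_buf);
      double* dwp = dwv.begin() + ((size_t)co * C + c) * k * k;
      for (int dw_ = 0; dw_ < k; ++dw_)
        for (int dh = 0; dh < k; ++dh) {
          int l1 = ((dh - p) % fc.P + fc.P) % fc.P;
          int l2 = ((dw_ - p) % fc.P + fc.P) % fc.P;
          dwp[(size_t)dw_ * k + dh] =
            (double)(pp.real_buf[(size_t)l1 * fc.P + l2] * scale);
        }
    }
  }

  NumericVector dbv;
  if (has_bias) {
    dbv = NumericVector(Cout);
    for (int n = 0; n < N; ++n)
      for (int co = 0; co < Cout; ++co) {
        const double* dp = dy.begin() + ((size_t)n * Cout + co) * H * W;
        double s = 0;
        for (size_t i = 0; i < (size_t)H * W; ++i) s += dp[i];
        dbv[co] += s;
      }
  }

  List out = List::create(Named("dx") = R_NilValue, Named("dw") = dwv,
                          Named("db") = has_bias ? (SEXP)dbv : R_NilValue);

  if (need_dx) {
    // dx(t) = conv(dy, w)(t + p). The spectrum of the unrotated kernel
    // embedding follows from the cached rotated one:
    //   F(w) = conj(F(rot180 w)) .* e^{-2pi i (f1 + f2)(k - 1)/P}
    // so the phase is applied once per accumulated (n, c) spectrum.
    const int P = fc.P;
    const int nc = P / 2 + 1;
    std::vector<cf> ph1(P), ph2(nc);
    for (int f = 0; f < P; ++f) {
      const double a = -2.0 * M_PI * (double)f * (k - 1) / P;
      ph1[f] = cf((float)std::cos(a), (float)std::sin(a));
    }
    for (int f = 0; f < nc; ++f) ph2[f] = ph1[f];
    NumericVector dx((size_t)H * W * C * N);
    dx.attr("dim") = IntegerVector::create(H, W, C, N);
    for (int n = 0; n < N; ++n) {
      for (int c = 0; c < C; ++c) {
        std::memset(acc.data(), 0, sizeof(cf) * nb);
        float* ac = reinterpret_cast<float*>(acc.data());
        for (int co = 0; co < Cout; ++co) {
          const float* df = reinterpret_cast<const float*>(
            dYf.data() + ((size_t)n * Cout + co) * nb);
          const float* wf = reinterpret_cast<const float*>(
            fc.Wf.data() + ((size_t)co * C + c) * nb);
          for (int i = 0; i < nb; ++i) {
            const float dr = df[2 * i], di = df[2 * i + 1];
            const float wr = wf[2 * i], wi = -wf[2 * i + 1];  // conj
            ac[2 * i] += dr * wr - di * wi;
            ac[2 * i + 1] += dr * wi + di * wr;
          }
        }
        // apply the separable phase: bin layout is row-major (f1, f2c)
        for (int f1 = 0; f1 < P; ++f1) {
          for (int f2 = 0; f2 < nc; ++f2) {
            const cf phase = ph1[f1] * ph2[f2];
            acc[(size_t)f1 * nc + f2] *= phase;
          }
        }
        ifft_crop(pp, acc.data(), dx.begin() + ((size_t)n * C + c) * H * W,
                  H, W, p, false);
      }
    }
    out["dx"] = dx;
  }

  fwd_cache().erase(layer_id);
  return out;
}

// [[Rcpp::export(name = ".fftconv_drop_cache")]]
void fftconv_drop_cache(int layer_id) {
  fwd_cache().erase(layer_id);
}
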