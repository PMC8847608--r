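// Low-level numerical kernels for the grooming classifier.
//
// Tensor layout everywhere: column-major R array with dim (D, H, W, C, N)
//   D = temporal depth, H/W = spatial, C = channels, N = batch.
// Convolutions use "same" zero padding and stride 1; pooling uses
// non-overlapping windows with floor division (stride = window).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Dims5 {
  int D, H, W, C, N;
  long vox() const { return (long)D * H * W; }
  long len() const { return vox() * C * N; }
};

Dims5 as_dims(const IntegerVector& d) {
  if (d.size() != 5) stop("tensor dims must have length 5");
  return Dims5{d[0], d[1], d[2], d[3], d[4]};
}

// Patch matrix in transposed layout: colsT is (nvox*nb x K) for a block of
// `nb` samples starting at sample n0; row index enumerates output voxels
// (d fastest, then h, w, sample). Each column r corresponds to one
// (kernel-offset, in-channel) pair and is a shifted copy of the input
// volume, so both reads and writes run contiguously along d.
template <typename MatT>
void fill_colsT(const double* x, const Dims5& xd,
                int kd, int kh, int kw, MatT& colsT, int n0, int nb) {
  const int pd = kd / 2, ph = kh / 2, pw = kw / 2;
  const long DHW = xd.vox();
  colsT.zeros();
  long r = 0;
  for (int c = 0; c < xd.C; ++c)
    for (int cw = 0; cw < kw; ++cw)
      for (int ch2 = 0; ch2 < kh; ++ch2)
        for (int cd = 0; cd < kd; ++cd, ++r) {
          const int sd0 = cd - pd, sh0 = ch2 - ph, sw0 = cw - pw;
          const int dlo = std::max(0, -sd0), dhi = std::min(xd.D, xd.D - sd0);
          auto* col = colsT.colptr(r);
          for (int nn = 0; nn < nb; ++nn) {
            const double* xc = x + ((long)(n0 + nn) * xd.C + c) * DHW;
            auto* dst0 = col + (long)nn * DHW;
            for (int w = 0; w < xd.W; ++w) {
              int sw = w + sw0;
              if (sw < 0 || sw >= xd.W) continue;
              for (int h = 0; h < xd.H; ++h) {
                int sh = h + sh0;
                if (sh < 0 || sh >= xd.H) continue;
                const double* src =
                  xc + sd0 + dlo + (long)xd.D * (sh + (long)xd.H * sw);
                auto* dst = dst0 + dlo + (long)xd.D * (h + (long)xd.H * w);
                for (int d = 0; d < dhi - dlo; ++d) dst[d] = src[d];
              }
            }
          }
        }
}

// Scatter-add transpose of fill_colsT into dx.
template <typename MatT>
void scatter_colsT(double* dx, const Dims5& xd,
                   int kd, int kh, int kw, const MatT& colsT,
                   int n0, int nb) {
  const int pd = kd / 2, ph = kh / 2, pw = kw / 2;
  const long DHW = xd.vox();
  long r = 0;
  for (int c = 0; c < xd.C; ++c)
    for (int cw = 0; cw < kw; ++cw)
      for (int ch2 = 0; ch2 < kh; ++ch2)
        for (int cd = 0; cd < kd; ++cd, ++r) {
          const int sd0 = cd - pd, sh0 = ch2 - ph, sw0 = cw - pw;
          const int dlo = std::max(0, -sd0), dhi = std::min(xd.D, xd.D - sd0);
          const auto* col = colsT.colptr(r);
          for (int nn = 0; nn < nb; ++nn) {
            double* xc = dx + ((long)(n0 + nn) * xd.C + c) * DHW;
            const auto* src0 = col + (long)nn * DHW;
            for (int w = 0; w < xd.W; ++w) {
              int sw = w + sw0;
              if (sw < 0 || sw >= xd.W) continue;
              for (int h = 0; h < xd.H; ++h) {
                int sh = h + sh0;
                if (sh < 0 || sh >= xd.H) continue;
                double* dst =
                  xc + sd0 + dlo + (long)xd.D * (sh + (long)xd.H * sw);
                const auto* src =
                  src0 + dlo + (long)xd.D * (h + (long)xd.H * w);
                for (int d = 0; d < dhi - dlo; ++d) dst[d] += src[d];
              }
            }
          }
        }
}

// Samples per block: cap the patch buffer at ~256 MB.
int block_samples(long K, long DHW, int N) {
  long cap = 32L * 1024L * 1024L / std::max(K * DHW, 1L);
  return (int)std::min((long)N, std::max(cap, 1L));
}

} // namespace

// y[d,h,w,co,n] = sum over 3x3x3(xCin) patch; returns dim (D,H,W,Cout,N).
// [[Rcpp::export]]
NumericVector cpp_conv3d_fw(NumericVector x, IntegerVector xdim,
                            NumericMatrix w, NumericVector b,
                            IntegerVector kdim) {
  Dims5 xd = as_dims(xdim);
  const int kd = kdim[0], kh = kdim[1], kw = kdim[2];
  const long K = (long)kd * kh * kw * xd.C;
  const int Cout = w.ncol();
  if ((long)w.nrow() != K) stop("weight rows != kernel size * in-channels");
  const long DHW = xd.vox();
  NumericVector y(DHW * Cout * xd.N);
  arma::fmat Wf(K, Cout);
  for (long i = 0; i < K * Cout; ++i) Wf[i] = (float)w[i];
  arma::vec bias(b.begin(), Cout, false, true);

  const int bs = block_samples(K, DHW, xd.N);
  // single-precision patch matrix and GEMM: convolution reductions are
  // short and training tolerates 1e-6-scale rounding; ~2x faster and half
  // the memory traffic of the double path
  arma::fmat colsT(DHW * bs, K);
  for (int n0 = 0; n0 < xd.N; n0 += bs) {
    int nb = std::min(bs, xd.N - n0);
    if ((long)colsT.n_rows != DHW * nb) colsT.set_size(DHW * nb, K);
    fill_colsT(x.begin(), xd, kd, kh, kw, colsT, n0, nb);
    arma::fmat ymT = colsT * Wf;
    for (int co = 0; co < Cout; ++co)
      for (int nn = 0; nn < nb; ++nn) {
        const float* src = ymT.colptr(co) + (long)nn * DHW;
        double* dst = y.begin() + DHW * (co + (long)Cout * (n0 + nn));
        const double bb = bias[co];
        for (long v = 0; v < DHW; ++v) dst[v] = src[v] + bb;
      }
  }
  y.attr("dim") = IntegerVector::create(xd.D, xd.H, xd.W, Cout, xd.N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_bw(NumericVector x, IntegerVector xdim, NumericMatrix w,
                   NumericVector dy, IntegerVector kdim,
                   bool need_dx = true) {
  Dims5 xd = as_dims(xdim);
  const int kd = kdim[0], kh = kdim[1], kw = kdim[2];
  const long K = (long)kd * kh * kw * xd.C;
  const int Cout = w.ncol();
  const long DHW = xd.vox();

  arma::fmat Wf(K, Cout);
  for (long i = 0; i < K * Cout; ++i) Wf[i] = (float)w[i];
  arma::fmat dWf(K, Cout, arma::fill::zeros);
  arma::mat dW(K, Cout, arma::fill::zeros);
  arma::rowvec db(Cout, arma::fill::zeros);
  NumericVector dx(x.size());

  const int bs = block_samples(K, DHW, xd.N);
  arma::fmat colsT(DHW * bs, K);
  arma::fmat dymT(DHW * bs, Cout);
  for (int n0 = 0; n0 < xd.N; n0 += bs) {
    int nb = std::min(bs, xd.N - n0);
    if ((long)colsT.n_rows != DHW * nb) {
      colsT.set_size(DHW * nb, K);
      dymT.set_size(DHW * nb, Cout);
    }
    fill_colsT(x.begin(), xd, kd, kh, kw, colsT, n0, nb);
    for (int co = 0; co < Cout; ++co)
      for (int nn = 0; nn < nb; ++nn) {
        const double* src = dy.begin() + DHW * (co + (long)Cout * (n0 + nn));
        float* dst = dymT.colptr(co) + (long)nn * DHW;
        for (long v = 0; v < DHW; ++v) dst[v] = (float)src[v];
      }
    dWf += colsT.t() * dymT;
    db += arma::conv_to<arma::rowvec>::from(arma::sum(dymT, 0));
    if (need_dx) {
      arma::fmat dcolsT = dymT * Wf.t();
      scatter_colsT(dx.begin(), xd, kd, kh, kw, dcolsT, n0, nb);
    }
  }
  dW = arma::conv_to<arma::mat>::from(dWf);
  dx.attr("dim") = xdim;
  return List::create(_["dx"] = dx,
                      _["dw"] = wrap(dW),
                      _["db"] = wrap(arma::vec(db.t())));
}

// Non-overlapping max pooling; records 0-based argmax indices into x.
// [[Rcpp::export]]
List cpp_maxpool3d_fw(NumericVector x, IntegerVector xdim,
                      IntegerVector pool) {
  Dims5 xd = as_dims(xdim);
  const int pd = pool[0], ph = pool[1], pw = pool[2];
  const int Do = xd.D / pd, Ho = xd.H / ph, Wo = xd.W / pw;
  if (Do < 1 || Ho < 1 || Wo < 1) stop("input smaller than pooling window");
  const long DHW = xd.vox();
  const long oDHW = (long)Do * Ho * Wo;
  NumericVector y(oDHW * xd.C * xd.N);
  NumericVector idx(y.size()); // double holds indices exactly up to 2^53

  for (int n = 0; n < xd.N; ++n)
    for (int c = 0; c < xd.C; ++c) {
      const long xoff = DHW * (c + (long)xd.C * n);
      const long yoff = oDHW * (c + (long)xd.C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho)
          for (int d_o = 0; d_o < Do; ++d_o) {
            double best = -1e300;
            long bi = -1;
            for (int cw = 0; cw < pw; ++cw)
              for (int ch2 = 0; ch2 < ph; ++ch2)
                for (int cd = 0; cd < pd; ++cd) {
                  long xi = xoff + (long)(d_o * pd + cd) +
                            (long)xd.D * ((ho * ph + ch2) +
                            (long)xd.H * (wo * pw + cw));
                  double v = x[xi];
                  if (v > best) { best = v; bi = xi; }
                }
            long yi = yoff + d_o + (long)Do * (ho + (long)Ho * wo);
            y[yi] = best;
            idx[yi] = (double)bi;
          }
    }
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo, xd.C, xd.N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3d_bw(NumericVector idx, NumericVector dy,
                               double xlen) {
  NumericVector dx((long)xlen);
  for (long i = 0; i < (long)dy.size(); ++i) dx[(long)idx[i]] += dy[i];
  return dx;
}

// Centroid (row, col), 0-based, of the largest 8-connected foreground
// component of a logical/0-1 matrix. Returns c(row, col, size); size 0 when
// no foreground pixel exists.
// [[Rcpp::export]]
NumericVector cpp_largest_cc_centroid(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  std::vector<int> lab((long)H * W, 0);
  int best_size = 0;
  double best_r = -1, best_c = -1;
  std::vector<long> stack;
  int cur = 0;
  for (long s = 0; s < (long)H * W; ++s) {
    if (mask[s] == 0 || lab[s]) continue;
    ++cur;
    stack.clear();
    stack.push_back(s);
    lab[s] = cur;
    long size = 0;
    double sr = 0, sc = 0;
    while (!stack.empty()) {
      long p = stack.back();
      stack.pop_back();
      int r = (int)(p % H), c = (int)(p / H);
      ++size;
      sr += r;
      sc += c;
      for (int dc = -1; dc <= 1; ++dc)
        for (int dr = -1; dr <= 1; ++dr) {
          if (!dr && !dc) continue;
          int rr = r + dr, cc = c + dc;
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          long q = rr + (long)H * cc;
          if (mask[q] != 0 && !lab[q]) { lab[q] = cur; stack.push_back(q); }
        }
    }
    if (size > best_size) {
      best_size = (int)size;
      best_r = sr / size;
      best_c = sc / size;
    }
  }
  return NumericVector::create(best_r, best_c, (double)best_size);
}

// [[Rcpp::export]]
NumericVector cpp_relu_fw(NumericVector x) {
  NumericVector y(x.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  for (long i = 0; i < (long)x.size(); ++i) yp[i] = xp[i] > 0 ? xp[i] : 0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// mask taken from the forward output: dy where y > 0
// [[Rcpp::export]]
NumericVector cpp_relu_bw(NumericVector y, NumericVector dy) {
  NumericVector dx(dy.size());
  const double* yp = y.begin();
  const double* dp = dy.begin();
  double* xp = dx.begin();
  for (long i = 0; i < (long)dy.size(); ++i) xp[i] = yp[i] > 0 ? dp[i] : 0;
  dx.attr("dim") = dy.attr("dim");
  return dx;
}
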