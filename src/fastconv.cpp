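#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
#include <vector>
using namespace Rcpp;

// Same-padding 2D convolution kernels (im2col + BLAS dgemm).  The unfolded
// patch matrices live in reusable static buffers so the training loop does
// not churn the R allocator.  Layout: activations are H x W x C column-major
// arrays (channels outermost); weights are (kh*kw*Cin) x Cout with kernel
// offsets enumerated dj outer / di inner, channel innermost.

static std::vector<double> g_cols1, g_cols2, g_wflip;

static void im2col_into(std::vector<double>& buf, const double* xp,
                        int H, int W, int C, int kh, int kw) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const R_xlen_t HW = (R_xlen_t)H * W;
  buf.resize(HW * (R_xlen_t)kh * kw * C);
  double* op = buf.data();
  R_xlen_t col = 0;
  for (int dj = 0; dj < kw; ++dj) {
    for (int di = 0; di < kh; ++di) {
      const int ii0 = di - ph;
      const int jj0 = dj - pw;
      for (int c = 0; c < C; ++c, ++col) {
        double* dst = op + col * HW;
        const double* src = xp + (R_xlen_t)c * HW;
        for (int j = 0; j < W; ++j) {
          const int jj = j + jj0;
          double* d2 = dst + (R_xlen_t)j * H;
          if (jj < 0 || jj >= W) {
            std::fill(d2, d2 + H, 0.0);
            continue;
          }
          const double* s2 = src + (R_xlen_t)jj * H;
          const int lo = (ii0 < 0) ? -ii0 : 0;
          const int hi = (ii0 > 0) ? H - ii0 : H;
          for (int i = 0; i < lo; ++i) d2[i] = 0.0;
          for (int i = lo; i < hi; ++i) d2[i] = s2[i + ii0];
          for (int i = hi; i < H; ++i) d2[i] = 0.0;
        }
      }
    }
  }
}

static void dgemm_nn(const double* A, const double* B, double* Cm,
                     int m, int n, int k, double beta) {
  const double one = 1.0;
  F77_CALL(dgemm)("N", "N", &m, &n, &k, &one, A, &m, B, &k, &beta, Cm, &m
                  FCONE FCONE);
}

static void dgemm_tn(const double* A, const double* B, double* Cm,
                     int m, int n, int k, double beta) {
  // C (m x n) = t(A) (m x k) %*% B (k x n), A stored k x m
  const double one = 1.0;
  F77_CALL(dgemm)("T", "N", &m, &n, &k, &one, A, &k, B, &k, &beta, Cm, &m
                  FCONE FCONE);
}

// forward: out (H x W x Cout) = conv(x, w) + b
// [[Rcpp::export]]
NumericVector cpp_conv_forward(NumericVector x, NumericMatrix w,
                               NumericVector b, int H, int W,
                               int kh, int kw) {
  const int K = w.nrow(), Cout = w.ncol();
  const int C = K / (kh * kw);
  const R_xlen_t HW = (R_xlen_t)H * W;
  im2col_into(g_cols1, REAL(x), H, W, C, kh, kw);
  NumericVector out(no_init(HW * Cout));
  out.attr("dim") = Dimension(H, W, Cout);
  dgemm_nn(g_cols1.data(), REAL(w), REAL(out), (int)HW, Cout, K, 0.0);
  double* op = REAL(out);
  for (int c = 0; c < Cout; ++c) {
    const double bc = b[c];
    double* oc = op + (R_xlen_t)c * HW;
    for (R_xlen_t i = 0; i < HW; ++i) oc[i] += bc;
  }
  return out;
}

// backward: given upstream gradient g (H x W x Cout), return
// list(gx = H x W x Cin array, gw = K x Cout matrix, gb = Cout vector).
// gx is the convolution of g with the spatially flipped, channel-transposed
// kernel; gw re-derives the patch matrix of x.
// [[Rcpp::export]]
List cpp_conv_backward(NumericVector x, NumericVector g, NumericMatrix w,
                       int H, int W, int kh, int kw) {
  const int K = w.nrow(), Cout = w.ncol();
  const int C = K / (kh * kw);
  const int nb = kh * kw;
  const R_xlen_t HW = (R_xlen_t)H * W;

  // weight gradient: t(cols(x)) %*% g
  im2col_into(g_cols1, REAL(x), H, W, C, kh, kw);
  NumericMatrix gw(K, Cout);
  dgemm_tn(g_cols1.data(), REAL(g), REAL(gw), K, Cout, (int)HW, 0.0);

  // bias gradient
  NumericVector gb(Cout);
  const double* gp = REAL(g);
  for (int c = 0; c < Cout; ++c) {
    double s = 0.0;
    const double* gc = gp + (R_xlen_t)c * HW;
    for (R_xlen_t i = 0; i < HW; ++i) s += gc[i];
    gb[c] = s;
  }

  // input gradient: cols(g) %*% wflip,
  // wflip[(b*Cout + co), ci] = w[(nb-1-b)*C + ci, co]
  g_wflip.resize((R_xlen_t)nb * Cout * C);
  const double* wp = REAL(w);
  for (int ci = 0; ci < C; ++ci) {
    double* dst = g_wflip.data() + (R_xlen_t)ci * nb * Cout;
    for (int bl = 0; bl < nb; ++bl) {
      const R_xlen_t srow = (R_xlen_t)(nb - 1 - bl) * C + ci;
      for (int co = 0; co < Cout; ++co) {
        dst[(R_xlen_t)bl * Cout + co] = wp[srow + (R_xlen_t)co * K];
      }
    }
  }
  im2col_into(g_cols2, gp, H, W, Cout, kh, kw);
  NumericVector gx(no_init(HW * C));
  gx.attr("dim") = Dimension(H, W, C);
  dgemm_nn(g_cols2.data(), g_wflip.data(), REAL(gx), (int)HW, C,
           nb * Cout, 0.0);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// kept for unit-level checks of the unfolding itself
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C, int kh, int kw) {
  im2col_into(g_cols1, REAL(x), H, W, C, kh, kw);
  const R_xlen_t HW = (R_xlen_t)H * W;
  const R_xlen_t ncol = (R_xlen_t)kh * kw * C;
  NumericVector buf(no_init(HW * ncol));
  std::copy(g_cols1.begin(), g_cols1.begin() + HW * ncol, REAL(buf));
  buf.attr("dim") = Dimension(HW, ncol);
  return NumericMatrix(buf);
}
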