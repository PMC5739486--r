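#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Batched same-padding 2-D convolution (cross-correlation) via im2col and a
// single BLAS matrix product.  Layouts, all column-major:
//   X  : (H, W, Cin, N)      feature maps, N samples
//   W  : (k, k, Cin, Cout)   odd square kernels
//   Y  : (H, W, Cout, N)
// The im2col matrix has one row per (h, w, n) output position (h fastest)
// and one column per (di, dj, c) kernel tap, matching the flattening of W.

static arma::mat build_im2col(const double* xp, int H, int Wd, int C, int N,
                              int k) {
  const int p = (k - 1) / 2;
  const int HW = H * Wd;
  const arma::uword rows = (arma::uword)N * HW;
  const int cols = k * k * C;
  arma::mat M(rows, cols, arma::fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int dj = 0; dj < k; ++dj)
        for (int di = 0; di < k; ++di) {
          const int col = di + k * (dj + k * c);
          double* Mcol = M.colptr(col);
          for (int w = 0; w < Wd; ++w) {
            const int iw = w + dj - p;
            if (iw < 0 || iw >= Wd) continue;
            const int h0 = std::max(0, p - di);
            const int h1 = std::min(H, H + p - di);
            if (h1 <= h0) continue;
            const double* src = xp + ((size_t)n * C + c) * HW +
                                (size_t)iw * H + (h0 + di - p);
            double* dst = Mcol + (size_t)n * HW + (size_t)w * H + h0;
            memcpy(dst, src, sizeof(double) * (h1 - h0));
          }
        }
  return M;
}

//' @noRd
// [[Rcpp::export]]
NumericVector conv2d_forward_cpp(NumericVector X, NumericVector W,
                                 NumericVector b) {
  IntegerVector xd = X.attr("dim"), wd = W.attr("dim");
  const int H = xd[0], Wd = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  if (wd[1] != k || wd[2] != C || b.size() != Cout)
    stop("kernel/bias dimensions inconsistent with input");
  const int HW = H * Wd;
  arma::mat M = build_im2col(X.begin(), H, Wd, C, N, k);
  const arma::mat Wm(const_cast<double*>(W.begin()), (arma::uword)k * k * C,
                     Cout, false, true);
  arma::mat Y = M * Wm;
  for (int o = 0; o < Cout; ++o) Y.col(o) += b[o];

  NumericVector out((R_xlen_t)HW * Cout * N);
  out.attr("dim") = IntegerVector::create(H, Wd, Cout, N);
  double* op = out.begin();
  for (int n = 0; n < N; ++n)
    for (int o = 0; o < Cout; ++o)
      memcpy(op + ((size_t)n * Cout + o) * HW, Y.colptr(o) + (size_t)n * HW,
             sizeof(double) * HW);
  return out;
}

//' @noRd
// [[Rcpp::export]]
List conv2d_backward_cpp(NumericVector X, NumericVector W, NumericVector dY) {
  IntegerVector xd = X.attr("dim"), wd = W.attr("dim");
  const int H = xd[0], Wd = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int p = (k - 1) / 2;
  const int HW = H * Wd;
  const arma::uword rows = (arma::uword)N * HW;
  const int cols = k * k * C;

  // dY back into (rows x Cout) layout
  arma::mat dYm(rows, Cout);
  const double* dyp = dY.begin();
  for (int n = 0; n < N; ++n)
    for (int o = 0; o < Cout; ++o)
      memcpy(dYm.colptr(o) + (size_t)n * HW,
             dyp + ((size_t)n * Cout + o) * HW, sizeof(double) * HW);

  arma::mat M = build_im2col(X.begin(), H, Wd, C, N, k);
  const arma::mat Wm(const_cast<double*>(W.begin()), (arma::uword)cols, Cout,
                     false, true);

  arma::mat dWm = M.t() * dYm;            // (cols x Cout)
  arma::rowvec db = arma::sum(dYm, 0);    // (Cout)
  arma::mat dXc = dYm * Wm.t();           // (rows x cols)

  // col2im: scatter-add the column matrix back onto the input grid
  NumericVector dX((R_xlen_t)HW * C * N);
  dX.attr("dim") = IntegerVector::create(H, Wd, C, N);
  double* dxp = dX.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int dj = 0; dj < k; ++dj)
        for (int di = 0; di < k; ++di) {
          const int col = di + k * (dj + k * c);
          const double* Mcol = dXc.colptr(col);
          for (int w = 0; w < Wd; ++w) {
            const int iw = w + dj - p;
            if (iw < 0 || iw >= Wd) continue;
            const int h0 = std::max(0, p - di);
            const int h1 = std::min(H, H + p - di);
            double* dst = dxp + ((size_t)n * C + c) * HW + (size_t)iw * H +
                          (h0 + di - p);
            const double* src = Mcol + (size_t)n * HW + (size_t)w * H + h0;
            for (int h = 0; h < h1 - h0; ++h) dst[h] += src[h];
          }
        }

  NumericVector dWout(W.size());
  dWout.attr("dim") = wd;
  memcpy(dWout.begin(), dWm.memptr(), sizeof(double) * W.size());
  return List::create(_["dX"] = dX, _["dW"] = dWout,
                      _["db"] = NumericVector(db.begin(), db.end()));
}
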