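#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Fused single-precision training kernels for one competitive block.
//
// The forward pass builds one im2col matrix at the largest kernel size; the
// taps of every smaller scale are a column subset of it, so each scale is a
// single SGEMM on a column slice.  The rectifier and the element-wise max
// across scales are fused into the same pass, and only the winning scale
// index (amax) plus the block output are kept: for a rectified block the
// backward mask of scale s is (amax == s) & (out > 0), because the winner's
// rectified response *is* the output.  The im2col matrix is cached in an
// external pointer and reused by the backward pass.

struct BlockCache {
  arma::fmat M;       // (N*H*W) x (kmax*kmax*Cin)
  int H, W, Cin, N, kmax;
};

static arma::fmat im2col_f(const double* xp, int H, int Wd, int C, int N,
                           int k) {
  const int p = (k - 1) / 2;
  const int HW = H * Wd;
  arma::fmat M((arma::uword)N * HW, (arma::uword)k * k * C,
               arma::fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int dj = 0; dj < k; ++dj)
        for (int di = 0; di < k; ++di) {
          const int col = di + k * (dj + k * c);
          float* Mcol = M.colptr(col);
          for (int w = 0; w < Wd; ++w) {
            const int iw = w + dj - p;
            if (iw < 0 || iw >= Wd) continue;
            const int h0 = std::max(0, p - di);
            const int h1 = std::min(H, H + p - di);
            const double* src = xp + ((size_t)n * C + c) * HW +
                                (size_t)iw * H + (h0 + di - p);
            float* dst = Mcol + (size_t)n * HW + (size_t)w * H + h0;
            for (int h = 0; h < h1 - h0; ++h) dst[h] = (float)src[h];
          }
        }
  return M;
}

// columns of the kmax im2col matrix holding the taps of scale k
static arma::uvec scale_cols(int k, int kmax, int C) {
  const int off = (kmax - k) / 2;
  arma::uvec idx((arma::uword)k * k * C);
  arma::uword j = 0;
  for (int c = 0; c < C; ++c)
    for (int dj = 0; dj < k; ++dj)
      for (int di = 0; di < k; ++di)
        idx[j++] = (di + off) + kmax * ((dj + off) + (arma::uword)kmax * c);
  return idx;
}

//' @noRd
// [[Rcpp::export]]
List cb_fwd_train_cpp(NumericVector X, List Ws, List bs, LogicalVector relu) {
  IntegerVector xd = X.attr("dim");
  const int H = xd[0], Wd = xd[1], C = xd[2], N = xd[3];
  const int HW = H * Wd;
  const int S = Ws.size();
  const bool do_relu = relu[0];

  int kmax = 1;
  for (int s = 0; s < S; ++s) {
    IntegerVector wd = as<NumericVector>(Ws[s]).attr("dim");
    kmax = std::max(kmax, (int)wd[0]);
  }
  XPtr<BlockCache> cache(new BlockCache, true);
  cache->M = im2col_f(X.begin(), H, Wd, C, N, kmax);
  cache->H = H; cache->W = Wd; cache->Cin = C; cache->N = N;
  cache->kmax = kmax;

  arma::fmat out;
  arma::Mat<int> amax;
  int Cout = 0;
  for (int s = 0; s < S; ++s) {
    NumericVector Wv = Ws[s];
    NumericVector bv = bs[s];
    IntegerVector wd = Wv.attr("dim");
    const int k = wd[0];
    Cout = wd[3];
    arma::fmat Wf(arma::conv_to<arma::fvec>::from(
        arma::vec(Wv.begin(), Wv.size())).memptr(),
        (arma::uword)k * k * C, Cout, true);
    arma::fmat Y = (k == kmax) ? arma::fmat(cache->M * Wf)
                               : arma::fmat(cache->M.cols(scale_cols(k, kmax, C)) * Wf);
    for (int o = 0; o < Cout; ++o) Y.col(o) += (float)bv[o];
    if (do_relu) Y.transform([](float v) { return v > 0.f ? v : 0.f; });
    if (s == 0) {
      out = Y;
      amax.zeros(Y.n_rows, Y.n_cols);
    } else {
      for (arma::uword j = 0; j < Y.n_cols; ++j) {
        float* yo = Y.colptr(j); float* oo = out.colptr(j);
        int* am = amax.colptr(j);
        for (arma::uword r = 0; r < Y.n_rows; ++r)
          if (yo[r] > oo[r]) { oo[r] = yo[r]; am[r] = s; }
      }
    }
  }

  // (rows x Cout) -> (H, W, Cout, N) double array + integer amax
  NumericVector outv((R_xlen_t)HW * Cout * N);
  IntegerVector amaxv((R_xlen_t)HW * Cout * N);
  outv.attr("dim") = IntegerVector::create(H, Wd, Cout, N);
  amaxv.attr("dim") = IntegerVector::create(H, Wd, Cout, N);
  for (int n = 0; n < N; ++n)
    for (int o = 0; o < Cout; ++o) {
      const float* src = out.colptr(o) + (size_t)n * HW;
      const int* asrc = amax.colptr(o) + (size_t)n * HW;
      double* dst = outv.begin() + ((size_t)n * Cout + o) * HW;
      int* adst = amaxv.begin() + ((size_t)n * Cout + o) * HW;
      for (int r = 0; r < HW; ++r) { dst[r] = src[r]; adst[r] = asrc[r]; }
    }
  return List::create(_["out"] = outv, _["amax"] = amaxv,
                      _["cache"] = cache);
}

//' @noRd
// [[Rcpp::export]]
List cb_bwd_train_cpp(SEXP cacheSEXP, List Ws, NumericVector out,
                      IntegerVector amax, NumericVector dOut,
                      LogicalVector relu) {
  XPtr<BlockCache> cache(cacheSEXP);
  const int H = cache->H, Wd = cache->W, C = cache->Cin, N = cache->N;
  const int kmax = cache->kmax;
  const int HW = H * Wd;
  const int S = Ws.size();
  const bool do_relu = relu[0];
  IntegerVector od = dOut.attr("dim");
  const int Cout = od[2];
  const arma::uword rows = (arma::uword)N * HW;

  arma::fmat dXc(rows, (arma::uword)kmax * kmax * C, arma::fill::zeros);
  List gW(S), gb(S);

  for (int s = 0; s < S; ++s) {
    NumericVector Wv = Ws[s];
    IntegerVector wd = Wv.attr("dim");
    const int k = wd[0];
    arma::fmat Wf(arma::conv_to<arma::fvec>::from(
        arma::vec(Wv.begin(), Wv.size())).memptr(),
        (arma::uword)k * k * C, Cout, true);

    // masked upstream gradient for this scale, in (rows x Cout) layout
    arma::fmat dZ(rows, Cout);
    for (int n = 0; n < N; ++n)
      for (int o = 0; o < Cout; ++o) {
        const size_t base = ((size_t)n * Cout + o) * HW;
        const double* dsrc = dOut.begin() + base;
        const double* osrc = out.begin() + base;
        const int* asrc = amax.begin() + base;
        float* dst = dZ.colptr(o) + (size_t)n * HW;
        for (int r = 0; r < HW; ++r) {
          const bool sel = asrc[r] == s && (!do_relu || osrc[r] > 0.0);
          dst[r] = sel ? (float)dsrc[r] : 0.f;
        }
      }

    arma::fmat dWs;
    if (k == kmax) {
      dWs = cache->M.t() * dZ;
      dXc += dZ * Wf.t();
    } else {
      arma::uvec idx = scale_cols(k, kmax, C);
      arma::fmat Msub = cache->M.cols(idx);
      dWs = Msub.t() * dZ;
      dXc.cols(idx) += dZ * Wf.t();
    }
    arma::frowvec dbs = arma::sum(dZ, 0);

    NumericVector dWv(Wv.size());
    dWv.attr("dim") = wd;
    std::copy(dWs.begin(), dWs.end(), dWv.begin());
    gW[s] = dWv;
    gb[s] = NumericVector(dbs.begin(), dbs.end());
  }

  // one col2im over the shared kmax column space
  NumericVector dX((R_xlen_t)HW * C * N);
  dX.attr("dim") = IntegerVector::create(H, Wd, C, N);
  double* dxp = dX.begin();
  const int p = (kmax - 1) / 2;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int dj = 0; dj < kmax; ++dj)
        for (int di = 0; di < kmax; ++di) {
          const int col = di + kmax * (dj + kmax * c);
          const float* Mcol = dXc.colptr(col);
          for (int w = 0; w < Wd; ++w) {
            const int iw = w + dj - p;
            if (iw < 0 || iw >= Wd) continue;
            const int h0 = std::max(0, p - di);
            const int h1 = std::min(H, H + p - di);
            double* dst = dxp + ((size_t)n * C + c) * HW + (size_t)iw * H +
                          (h0 + di - p);
            const float* src = Mcol + (size_t)n * HW + (size_t)w * H + h0;
            for (int h = 0; h < h1 - h0; ++h) dst[h] += src[h];
          }
        }
  return List::create(_["dX"] = dX, _["gW"] = gW, _["gb"] = gb);
}
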