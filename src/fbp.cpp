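#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Distance-weighted back-projection for an equispaced (flat) fan-beam
// detector, using the virtual detector through the rotation centre.
//
// qf: n_views x n_bins filtered projections, already cosine-weighted and
// ramp-filtered, with detector coordinates rescaled to the isocentre plane
// (spacing ds_iso, bin centre offsets (b + 0.5 - n_bins/2) * ds_iso).
// The reconstruction at pixel P sums (dbeta / U^2) * qf(beta, sigma) with
// U = (dso - P.e_r) / dso and sigma = (P.e_t) / U, linearly interpolated
// between bins.
//' @noRd
// [[Rcpp::export]]
NumericMatrix fan_backproject_cpp(NumericMatrix qf, double fov_mm, int grid_n,
                                  double dso, double ds_iso,
                                  double ang_range_deg) {
  const int n_views = qf.nrow(), n_bins = qf.ncol();
  const double px = fov_mm / grid_n;
  const double dbeta = (ang_range_deg * M_PI / 180.0) / n_views;
  NumericMatrix out(grid_n, grid_n);

  std::vector<double> xs(grid_n), ys(grid_n);
  for (int j = 0; j < grid_n; ++j) xs[j] = (j + 0.5 - grid_n / 2.0) * px;
  for (int i = 0; i < grid_n; ++i) ys[i] = (grid_n / 2.0 - (i + 0.5)) * px;

  for (int v = 0; v < n_views; ++v) {
    const double beta = (ang_range_deg * M_PI / 180.0) * v / n_views;
    const double cb = std::cos(beta), sb = std::sin(beta);
    const double* qv = &qf(v, 0);  // careful: column stride is n_views
    for (int j = 0; j < grid_n; ++j) {
      const double x = xs[j];
      for (int i = 0; i < grid_n; ++i) {
        const double y = ys[i];
        const double U = (dso - (x * cb + y * sb)) / dso;
        if (U <= 1e-6) continue;
        const double sigma = (-x * sb + y * cb) / U;
        const double fb = sigma / ds_iso + n_bins / 2.0 - 0.5;
        const int b0 = (int)std::floor(fb);
        if (b0 < 0 || b0 >= n_bins - 1) continue;
        const double w = fb - b0;
        const double q = (1.0 - w) * qv[(size_t)b0 * n_views] +
                         w * qv[(size_t)(b0 + 1) * n_views];
        out(i, j) += dbeta * q / (U * U);
      }
    }
  }
  return out;
}
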