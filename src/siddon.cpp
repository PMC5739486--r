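#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exact radiological path of one ray through a square pixel raster.
//
// Grid frame: u in [0, n*px] rightward (columns), v in [0, n*px] downward
// (rows), so pixel (row r, col c) covers u in [c*px,(c+1)*px],
// v in [r*px,(r+1)*px].  The walk visits every pixel the segment crosses and
// accumulates (segment length inside pixel) * (pixel value).
static double ray_path(const double* img, int n, double px,
                       double su, double sv, double pu, double pv) {
  const double du = pu - su, dv = pv - sv;
  const double L = std::sqrt(du * du + dv * dv);
  if (L <= 0.0) return 0.0;
  const double side = n * px;

  // Clip the parametric segment t in [0,1] against the grid square.
  double tmin = 0.0, tmax = 1.0;
  const double eps = 1e-12;
  if (std::fabs(du) < eps) {
    if (su <= 0.0 || su >= side) return 0.0;
  } else {
    double t1 = (0.0 - su) / du, t2 = (side - su) / du;
    if (t1 > t2) std::swap(t1, t2);
    tmin = std::max(tmin, t1);
    tmax = std::min(tmax, t2);
  }
  if (std::fabs(dv) < eps) {
    if (sv <= 0.0 || sv >= side) return 0.0;
  } else {
    double t1 = (0.0 - sv) / dv, t2 = (side - sv) / dv;
    if (t1 > t2) std::swap(t1, t2);
    tmin = std::max(tmin, t1);
    tmax = std::min(tmax, t2);
  }
  if (tmin >= tmax) return 0.0;

  // Index of the pixel containing the entry point (nudged inside).
  double t = tmin;
  double mu = su + 0.5 * (tmin + tmax) * du;   // midpoint for robust start
  double mv = sv + 0.5 * (tmin + tmax) * dv;
  (void)mu; (void)mv;
  double eu = su + (tmin + 1e-10 * (tmax - tmin)) * du;
  double ev = sv + (tmin + 1e-10 * (tmax - tmin)) * dv;
  int iu = (int)std::floor(eu / px);
  int iv = (int)std::floor(ev / px);
  if (iu < 0) iu = 0; if (iu > n - 1) iu = n - 1;
  if (iv < 0) iv = 0; if (iv > n - 1) iv = n - 1;

  const int step_u = (du > 0.0) ? 1 : -1;
  const int step_v = (dv > 0.0) ? 1 : -1;
  const double dtu = (std::fabs(du) < eps) ? R_PosInf : px / std::fabs(du);
  const double dtv = (std::fabs(dv) < eps) ? R_PosInf : px / std::fabs(dv);

  // t of the next vertical / horizontal grid-line crossing.
  double tu, tv;
  if (std::fabs(du) < eps) tu = R_PosInf;
  else {
    double bound = (step_u > 0 ? (iu + 1) : iu) * px;
    tu = (bound - su) / du;
  }
  if (std::fabs(dv) < eps) tv = R_PosInf;
  else {
    double bound = (step_v > 0 ? (iv + 1) : iv) * px;
    tv = (bound - sv) / dv;
  }

  double acc = 0.0;
  while (t < tmax - 1e-12) {
    double tnext = std::min(std::min(tu, tv), tmax);
    if (tnext > t)
      acc += (tnext - t) * L * img[(size_t)iu * n + iv];  // img column-major: [row iv, col iu]
    if (tnext >= tmax - 1e-12) break;
    if (tu <= tv) { iu += step_u; tu += dtu; }
    else          { iv += step_v; tv += dtv; }
    if (iu < 0 || iu >= n || iv < 0 || iv >= n) break;
    t = tnext;
  }
  return acc;
}

//' @noRd
// [[Rcpp::export]]
NumericMatrix siddon_project_cpp(NumericMatrix img, double fov_mm,
                                 double dso, double dcd,
                                 double det_len, int n_bins, int n_views,
                                 double ang_range_deg) {
  const int n = img.nrow();
  if (img.ncol() != n) stop("image must be square");
  const double px = fov_mm / n;
  const double half = fov_mm / 2.0;
  const double dsd = dso + dcd;
  const double bw = det_len / n_bins;
  NumericMatrix out(n_views, n_bins);
  const double* ip = img.begin();

  for (int v = 0; v < n_views; ++v) {
    const double beta = (ang_range_deg * M_PI / 180.0) * v / n_views;
    const double cb = std::cos(beta), sb = std::sin(beta);
    // source position (world mm, origin at rotation centre, y upward)
    const double sx = dso * cb, sy = dso * sb;
    for (int b = 0; b < n_bins; ++b) {
      const double s = (b + 0.5 - n_bins / 2.0) * bw;  // detector offset
      // detector bin centre: behind the centre along -e_r, offset along e_t
      const double px_w = sx - dsd * cb - s * sb;
      const double py_w = sy - dsd * sb + s * cb;
      // world -> grid frame (u right, v down, origin at top-left corner)
      const double su = sx + half,  sv = half - sy;
      const double pu = px_w + half, pv = half - py_w;
      out(v, b) = ray_path(ip, n, px, su, sv, pu, pv);
    }
  }
  return out;
}
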