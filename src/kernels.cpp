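// Low-level raster kernels: inverse-mapped similarity warps, the fused
// warp + joint-histogram pass used by the mutual-information search, and
// the log-polar origin scan used by the cross-correlation registration.
//
// Geometry conventions (shared with the R level):
//   * matrices are indexed (row = y, col = x), 0-based here;
//   * pixel centers sit on integer coordinates; image center is
//     ((W-1)/2, (H-1)/2);
//   * forward transform: scale about center, rotate about center
//     (positive = counter-clockwise as displayed, y down), then translate.
// [[Rcpp::depends(RcppArmadillo)]]
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

struct Sample {
  double value;
  bool valid;
};

// Bilinear sample at (x, y); invalid if out of bounds or any contributing
// source pixel is flagged invalid (keeps e.g. thickness values from being
// blended with out-of-annulus padding).
inline Sample sample_bilinear(const NumericMatrix& px, const LogicalMatrix& valid,
                              double x, double y) {
  Sample s{0.0, false};
  const int H = px.nrow(), W = px.ncol();
  if (x < 0.0 || y < 0.0 || x > W - 1.0 || y > H - 1.0) return s;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  double fx = x - x0, fy = y - y0;
  int x1 = (fx > 0.0) ? x0 + 1 : x0;
  int y1 = (fy > 0.0) ? y0 + 1 : y0;
  if (x1 > W - 1 || y1 > H - 1) return s;  // only when fx/fy > 0 at the edge
  if (!(valid(y0, x0) && valid(y0, x1) && valid(y1, x0) && valid(y1, x1))) return s;
  double v00 = px(y0, x0), v01 = px(y0, x1), v10 = px(y1, x0), v11 = px(y1, x1);
  s.value = (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11);
  s.valid = true;
  return s;
}

inline Sample sample_nearest(const NumericMatrix& px, const LogicalMatrix& valid,
                             double x, double y) {
  Sample s{0.0, false};
  const int H = px.nrow(), W = px.ncol();
  int xn = (int)std::floor(x + 0.5), yn = (int)std::floor(y + 0.5);
  if (xn < 0 || yn < 0 || xn > W - 1 || yn > H - 1) return s;
  if (!valid(yn, xn)) return s;
  s.value = px(yn, xn);
  s.valid = true;
  return s;
}

// Inverse map of the forward transform: q = R(-theta) (p - c - t) / s + c.
// `inv_scale` is the precomputed reciprocal of the scale factor.
inline void inverse_map(double x, double y, double cx, double cy,
                        double tx, double ty, double ct, double st,
                        double inv_scale, double& qx, double& qy) {
  double dx = x - cx - tx, dy = y - cy - ty;
  qx = (ct * dx - st * dy) * inv_scale + cx;
  qy = (st * dx + ct * dy) * inv_scale + cy;
}

}  // namespace

// [[Rcpp::export]]
List cpp_warp_similarity(NumericMatrix px, LogicalMatrix valid,
                         double tx, double ty, double theta_rad, double scale,
                         bool bilinear) {
  const int H = px.nrow(), W = px.ncol();
  const double cx = (W - 1) / 2.0, cy = (H - 1) / 2.0;
  const double ct = std::cos(theta_rad), st = std::sin(theta_rad);
  const double inv_s = 1.0 / scale;
  NumericMatrix out(H, W);
  LogicalMatrix outvalid(H, W);
  for (int x = 0; x < W; ++x) {  // column-major friendly
    for (int y = 0; y < H; ++y) {
      double qx, qy;
      inverse_map(x, y, cx, cy, tx, ty, ct, st, inv_s, qx, qy);
      Sample s = bilinear ? sample_bilinear(px, valid, qx, qy)
                          : sample_nearest(px, valid, qx, qy);
      out(y, x) = s.value;
      outvalid(y, x) = s.valid;
    }
  }
  return List::create(_["pixels"] = out, _["valid"] = outvalid);
}

// Joint intensity histogram of (reference, target warped by the candidate
// transform), restricted to pixels valid in both, without materialising the
// warped image. Equal-width bins over [lo, hi]. Invalid pixels are NaN-coded
// in the inputs (one matrix per image instead of pixels + mask, halving the
// scattered memory traffic of the search); NaN corners propagate through the
// bilinear sum exactly like the all-corners-valid rule of the warp.
// [[Rcpp::export]]
NumericMatrix cpp_mi_joint_hist(NumericMatrix ref_packed, NumericMatrix tgt_packed,
                                double tx, double ty, double theta_rad, double scale,
                                int n_bins, double lo, double hi) {
  const int H = ref_packed.nrow(), W = ref_packed.ncol();
  const double cx = (W - 1) / 2.0, cy = (H - 1) / 2.0;
  const double ct = std::cos(theta_rad), st = std::sin(theta_rad);
  const double inv_s = 1.0 / scale;
  const double inv_binw = n_bins / (hi - lo);
  NumericMatrix hist(n_bins, n_bins);
  for (int x = 0; x < W; ++x) {  // column-major friendly
    for (int y = 0; y < H; ++y) {
      double rv = ref_packed(y, x);
      if (std::isnan(rv)) continue;
      double qx, qy;
      inverse_map(x, y, cx, cy, tx, ty, ct, st, inv_s, qx, qy);
      if (qx < 0.0 || qy < 0.0 || qx > W - 1.0 || qy > H - 1.0) continue;
      int x0 = (int)qx, y0 = (int)qy;
      double fx = qx - x0, fy = qy - y0;
      int x1 = (fx > 0.0) ? x0 + 1 : x0;
      int y1 = (fy > 0.0) ? y0 + 1 : y0;
      if (x1 > W - 1 || y1 > H - 1) continue;
      double v = (1 - fy) * ((1 - fx) * tgt_packed(y0, x0) + fx * tgt_packed(y0, x1)) +
                 fy * ((1 - fx) * tgt_packed(y1, x0) + fx * tgt_packed(y1, x1));
      if (std::isnan(v)) continue;
      int bi = (int)((rv - lo) * inv_binw);
      int bj = (int)((v - lo) * inv_binw);
      bi = std::min(std::max(bi, 0), n_bins - 1);
      bj = std::min(std::max(bj, 0), n_bins - 1);
      hist(bi, bj) += 1.0;
    }
  }
  return hist;
}

// Log-polar resampling about an origin; zero outside the frame.
// Row i = angle bin (counter-clockwise as displayed), col j = log-radius bin.
// [[Rcpp::export]]
arma::mat cpp_logpolar_sample(const arma::mat& img, double ox, double oy,
                              int n_angle, int n_logr, double r_min, double r_max) {
  const int H = img.n_rows, W = img.n_cols;
  const double dtheta = 2.0 * M_PI / n_angle;
  const double dlog = std::log(r_max / r_min) / (n_logr - 1);
  arma::mat lp(n_angle, n_logr, arma::fill::zeros);
  std::vector<double> cs(n_angle), sn(n_angle), rr(n_logr);
  for (int i = 0; i < n_angle; ++i) { cs[i] = std::cos(i * dtheta); sn[i] = std::sin(i * dtheta); }
  for (int j = 0; j < n_logr; ++j) rr[j] = r_min * std::exp(j * dlog);
  for (int i = 0; i < n_angle; ++i) {
    for (int j = 0; j < n_logr; ++j) {
      double x = ox + rr[j] * cs[i];
      double y = oy - rr[j] * sn[i];  // y down, angle counter-clockwise on screen
      if (x < 0.0 || y < 0.0 || x > W - 1.0 || y > H - 1.0) continue;
      int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
      double fx = x - x0, fy = y - y0;
      int x1 = (fx > 0.0) ? x0 + 1 : x0;
      int y1 = (fy > 0.0) ? y0 + 1 : y0;
      if (x1 > W - 1 || y1 > H - 1) continue;
      lp(i, j) = (1 - fy) * ((1 - fx) * img(y0, x0) + fx * img(y0, x1)) +
                 fy * ((1 - fx) * img(y1, x0) + fx * img(y1, x1));
    }
  }
  return lp;
}

// Scan candidate origins in the target mask: for each origin, correlate the
// (fixed) reference log-polar image against the target's log-polar image,
// circularly along the angle axis and linearly (zero-padded to `pad` columns,
// shifts limited to |v| <= max_shift) along the log-radius axis. Returns the
// global peak and per-origin peak values. Candidates are visited in the order
// given; strict improvement keeps the earliest (callers order them closest-
// to-center first so degenerate ties resolve toward small translations).
// [[Rcpp::export]]
List cpp_lpcc_scan(const arma::mat& ref_lp, const arma::mat& tgt,
                   const arma::mat& origins, int n_angle, int n_logr,
                   double r_min, double r_max, int pad, int max_shift,
                   bool normalize) {
  const int n_orig = origins.n_rows;
  arma::mat refpad(n_angle, pad, arma::fill::zeros);
  refpad.cols(0, n_logr - 1) = ref_lp;
  arma::cx_mat Fref = arma::conj(arma::fft2(refpad));
  const double ref_norm = arma::norm(ref_lp, "fro");
  arma::vec peaks(n_orig);
  double best = -arma::datum::inf;
  int best_o = -1, best_u = 0, best_v = 0;
  arma::mat lppad(n_angle, pad);
  for (int o = 0; o < n_orig; ++o) {
    arma::mat lp = cpp_logpolar_sample(tgt, origins(o, 0), origins(o, 1),
                                       n_angle, n_logr, r_min, r_max);
    lppad.zeros();
    lppad.cols(0, n_logr - 1) = lp;
    arma::mat C = arma::real(arma::ifft2(Fref % arma::fft2(lppad)));
    if (normalize) {
      double nrm = ref_norm * arma::norm(lp, "fro");
      if (nrm > 0) C /= nrm;
    }
    double opeak = -arma::datum::inf;
    // visit radius shifts in order of |v|, then angle shifts in order of |u|
    for (int vs = 0; vs <= 2 * max_shift; ++vs) {
      int v = (vs % 2 == 0) ? vs / 2 : -(vs + 1) / 2;
      int vcol = (v >= 0) ? v : pad + v;
      for (int us = 0; us < n_angle; ++us) {
        int u = (us % 2 == 0) ? us / 2 : -(us + 1) / 2;
        if (2 * u == -n_angle) u = n_angle / 2;  // canonical range (-n/2, n/2]
        int urow = (u >= 0) ? u : n_angle + u;
        double val = C(urow, vcol);
        if (val > opeak) opeak = val;
        if (val > best) {
          best = val; best_o = o; best_u = u; best_v = v;
        }
      }
    }
    peaks[o] = opeak;
  }
  return List::create(_["origin_index"] = best_o + 1,
                      _["angle_shift"] = best_u,
                      _["logr_shift"] = best_v,
                      _["peak_value"] = best,
                      _["origin_peaks"] = peaks);
}
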