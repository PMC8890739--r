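#include <RcppArmadillo.h>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Accumulate Gaussian particle images onto a sensor.
// u, v: particle positions in pixel coordinates (1-based, fractional);
// amp: intensity scale per particle (total spot mass = amp * 2 pi sigma^2);
// sigma: Gaussian width in px (e^{-2} image diameter = 4 * sigma).
// Each spot is integrated over the pixel area (erf differences), which
// avoids the peak locking that point-sampled Gaussians induce in
// correlation estimators, and truncated at `radius` pixels.
// [[Rcpp::export]]
NumericMatrix cpp_render_spots(NumericVector u, NumericVector v,
                               NumericVector amp, NumericVector sigma,
                               int nrow, int ncol, double radius) {
  NumericMatrix img(nrow, ncol);
  const int n = u.size();
  const double inv_sqrt2 = 1.0 / std::sqrt(2.0);
  for (int p = 0; p < n; ++p) {
    const double up = u[p], vp = v[p];
    const double s = sigma[p];
    const double iss = inv_sqrt2 / s;
    const double a = amp[p] * s * s * (M_PI / 2.0);
    const int c0 = std::max(1, (int)std::ceil(up - radius));
    const int c1 = std::min(ncol, (int)std::floor(up + radius));
    const int r0 = std::max(1, (int)std::ceil(vp - radius));
    const int r1 = std::min(nrow, (int)std::floor(vp + radius));
    if (c0 > c1 || r0 > r1) continue;
    for (int c = c0; c <= c1; ++c) {
      const double du = c - up;
      const double Du = a * (std::erf((du + 0.5) * iss) -
                             std::erf((du - 0.5) * iss));
      for (int r = r0; r <= r1; ++r) {
        const double dv = r - vp;
        const double Dv = std::erf((dv + 0.5) * iss) -
          std::erf((dv - 0.5) * iss);
        img(r - 1, c - 1) += Du * Dv;
      }
    }
  }
  return img;
}
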