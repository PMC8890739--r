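#include <RcppArmadillo.h>
#include <complex>
#include <map>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
typedef std::complex<double> cplx;

// Iterative radix-2 FFT with cached twiddle factors; window sizes are
// powers of two by construction, so no general-length machinery is needed.
static const std::vector<cplx>& twiddles(int n, bool inverse) {
  static std::map<std::pair<int, int>, std::vector<cplx>> cache;
  auto key = std::make_pair(n, inverse ? 1 : 0);
  auto it = cache.find(key);
  if (it != cache.end()) return it->second;
  std::vector<cplx> w(n / 2);
  const double sgn = inverse ? 1.0 : -1.0;
  for (int k = 0; k < n / 2; ++k)
    w[k] = std::polar(1.0, sgn * 2.0 * M_PI * k / n);
  return cache.emplace(key, std::move(w)).first->second;
}

static void fft1d(cplx* a, int n, int stride, bool inverse,
                  const std::vector<cplx>& w) {
  // bit-reversal permutation
  for (int i = 1, j = 0; i < n; ++i) {
    int bit = n >> 1;
    for (; j & bit; bit >>= 1) j ^= bit;
    j ^= bit;
    if (i < j) std::swap(a[i * stride], a[j * stride]);
  }
  for (int len = 2; len <= n; len <<= 1) {
    const int step = n / len;
    for (int i = 0; i < n; i += len) {
      for (int k = 0; k < len / 2; ++k) {
        cplx u = a[(i + k) * stride];
        cplx v = a[(i + k + len / 2) * stride] * w[k * step];
        a[(i + k) * stride] = u + v;
        a[(i + k + len / 2) * stride] = u - v;
      }
    }
  }
}

// in-place 2D FFT of an n x n complex buffer (column-major)
static void fft2d(cplx* m, int n, bool inverse) {
  const std::vector<cplx>& w = twiddles(n, inverse);
  for (int c = 0; c < n; ++c) fft1d(m + c * n, n, 1, inverse, w);
  for (int r = 0; r < n; ++r) fft1d(m + r, n, n, inverse, w);
}

// One FFT cross-correlation of two mean-subtracted square tiles.
// Returns (dx, dy, peak_ratio, status): displacement of tile b relative to
// tile a in pixels (x = columns, y = rows), ratio of highest to
// second-highest correlation peak, and status 0 = ok, 1 = no signal
// (constant tile), 2 = displacement beyond the quarter-window range.
static arma::vec xcorr_tile(const double* a, const double* b, int win,
                            std::vector<cplx>& bufA, std::vector<cplx>& bufB) {
  arma::vec out(4, arma::fill::zeros);
  const int n2 = win * win;
  double ma = 0, mb = 0;
  for (int i = 0; i < n2; ++i) { ma += a[i]; mb += b[i]; }
  ma /= n2; mb /= n2;
  double va = 0, vb = 0;
  for (int i = 0; i < n2; ++i) {
    const double da = a[i] - ma, db = b[i] - mb;
    bufA[i] = cplx(da, 0.0);
    bufB[i] = cplx(db, 0.0);
    va += da * da; vb += db * db;
  }
  if (va <= 1e-12 || vb <= 1e-12) { out(3) = 1; return out; }

  fft2d(bufA.data(), win, false);
  fft2d(bufB.data(), win, false);
  for (int i = 0; i < n2; ++i) bufA[i] = std::conj(bufA[i]) * bufB[i];
  fft2d(bufA.data(), win, true);
  // correlation plane (unnormalized scale is irrelevant for peak logic)

  int pr = 0, pc = 0;
  double c0 = -1e300;
  for (int c = 0; c < win; ++c)
    for (int r = 0; r < win; ++r) {
      const double val = bufA[c * win + r].real();
      if (val > c0) { c0 = val; pr = r; pc = c; }
    }

  // second-highest peak outside the 3x3 (circular) neighborhood
  double second = -1e300;
  for (int c = 0; c < win; ++c) {
    int ddc = std::abs(c - pc); ddc = std::min(ddc, win - ddc);
    for (int r = 0; r < win; ++r) {
      if (ddc <= 1) {
        int ddr = std::abs(r - pr); ddr = std::min(ddr, win - ddr);
        if (ddr <= 1) continue;
      }
      const double val = bufA[c * win + r].real();
      if (val > second) second = val;
    }
  }
  const double ratio = c0 / std::max(second, 1e-12 * std::abs(c0) + 1e-300);

  // 3-point sub-pixel fit per axis (Gaussian on log-values when all three
  // samples are positive, parabolic otherwise)
  auto corr_at = [&](int r, int c) {
    return bufA[((c + win) % win) * win + (r + win) % win].real();
  };
  auto subfit = [&](double cm, double cc, double cp) {
    if (cm > 0 && cc > 0 && cp > 0) {
      const double lm = std::log(cm), lc = std::log(cc), lp = std::log(cp);
      const double den = 2.0 * lm - 4.0 * lc + 2.0 * lp;
      if (std::abs(den) > 1e-300) return (lm - lp) / den;
    }
    const double den = 2.0 * cm - 4.0 * cc + 2.0 * cp;
    if (std::abs(den) > 1e-300) return (cm - cp) / den;
    return 0.0;
  };
  double dy = subfit(corr_at(pr - 1, pc), c0, corr_at(pr + 1, pc));
  double dx = subfit(corr_at(pr, pc - 1), c0, corr_at(pr, pc + 1));
  if (!std::isfinite(dx)) dx = 0.0;
  if (!std::isfinite(dy)) dy = 0.0;
  dx = std::max(-1.0, std::min(1.0, dx));
  dy = std::max(-1.0, std::min(1.0, dy));

  // unwrap integer peak position to signed displacement
  const double ix = pc <= win / 2 ? pc : pc - win;
  const double iy = pr <= win / 2 ? pr : pr - win;
  out(0) = ix + dx;
  out(1) = iy + dy;
  out(2) = ratio;
  if (std::abs(out(0)) > win / 4.0 || std::abs(out(1)) > win / 4.0) out(3) = 2;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_xcorr_tile(NumericMatrix a, NumericMatrix b) {
  const int win = a.nrow();
  std::vector<cplx> bufA(win * win), bufB(win * win);
  arma::vec r = xcorr_tile(a.begin(), b.begin(), win, bufA, bufB);
  return NumericVector(r.begin(), r.end());
}

// Batch correlation of interrogation windows.
// Frames are indexed (row = v/y pixel, col = u/x pixel); cx, cy are
// 1-based window-center pixel coordinates; the window of frame b is offset
// by the integer predictor (px, py). Returns an n x 4 matrix of
// (dx, dy, peak_ratio, status); displacements include the predictor.
// Windows falling partly outside either frame get status 3.
// [[Rcpp::export]]
NumericMatrix cpp_correlate_windows(NumericMatrix a, NumericMatrix b,
                                    IntegerVector cx, IntegerVector cy,
                                    int win,
                                    IntegerVector px, IntegerVector py) {
  const int n = cx.size();
  const int h = win / 2;
  const int nra = a.nrow(), nca = a.ncol();
  NumericMatrix out(n, 4);
  std::vector<double> wa(win * win), wb(win * win);
  std::vector<cplx> bufA(win * win), bufB(win * win);
  for (int i = 0; i < n; ++i) {
    const int ax0 = cx[i] - h - 1, ay0 = cy[i] - h - 1;   // 0-based corners
    const int bx0 = ax0 + px[i], by0 = ay0 + py[i];
    if (ax0 < 0 || ay0 < 0 || ax0 + win > nca || ay0 + win > nra ||
        bx0 < 0 || by0 < 0 || bx0 + win > nca || by0 + win > nra) {
      out(i, 3) = 3;
      continue;
    }
    for (int c = 0; c < win; ++c) {
      const double* acol = &a(0, ax0 + c);
      const double* bcol = &b(0, bx0 + c);
      for (int r = 0; r < win; ++r) {
        wa[c * win + r] = acol[ay0 + r];
        wb[c * win + r] = bcol[by0 + r];
      }
    }
    arma::vec res = xcorr_tile(wa.data(), wb.data(), win, bufA, bufB);
    out(i, 0) = res(0) + px[i];
    out(i, 1) = res(1) + py[i];
    out(i, 2) = res(2);
    out(i, 3) = res(3);
  }
  return out;
}
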