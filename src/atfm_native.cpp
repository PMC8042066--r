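// Native kernels for the aTFM pipeline: evaluation of the cubic-spline
// astigmatic PSF model (with analytic derivatives), the damped
// Newton/Levenberg Poisson maximum-likelihood fitter, and median filters
// used by the trajectory / displacement-field stages.

#include <Rcpp.h>
#include <cmath>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Spline PSF model container
//
// coef holds piecewise-cubic z-coefficients on a fine (oversampled) lateral
// grid, as an R array of dim c(nf, nf, nzi, 4): [row(y), col(x), z-interval,
// coefficient]. Fine grid point i sits at (i - (nf-1)/2) * fh nanometres from
// the PSF centre; z interval j covers [z0 + j*dz, z0 + (j+1)*dz].
// Lateral interpolation between fine grid points is Catmull-Rom (C1).
// ---------------------------------------------------------------------------

struct PsfModelC {
  const double *coef;
  int nf, nzi;
  double z0, dz, fh;
};

static inline void cr_weights(double t, double *w, double *dw) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = 0.5 * (-t3 + 2.0 * t2 - t);
  w[1] = 0.5 * (3.0 * t3 - 5.0 * t2 + 2.0);
  w[2] = 0.5 * (-3.0 * t3 + 4.0 * t2 + t);
  w[3] = 0.5 * (t3 - t2);
  if (dw) {
    dw[0] = 0.5 * (-3.0 * t2 + 4.0 * t - 1.0);
    dw[1] = 0.5 * (9.0 * t2 - 10.0 * t);
    dw[2] = 0.5 * (-9.0 * t2 + 8.0 * t + 1.0);
    dw[3] = 0.5 * (3.0 * t2 - 2.0 * t);
  }
}

// value and (optionally) gradient of the unit-intensity PSF at offset
// (ux, uy) from the PSF centre and axial position z. Outside the lateral
// template support the PSF is taken as zero.
static void psf_eval(const PsfModelC &m, double ux, double uy, double z,
                     bool deriv, double *out) {
  out[0] = out[1] = out[2] = out[3] = 0.0;
  double fi = ux / m.fh + (m.nf - 1) / 2.0;
  double fj = uy / m.fh + (m.nf - 1) / 2.0;
  int i0 = (int)std::floor(fi), j0 = (int)std::floor(fj);
  if (i0 < 1 || i0 > m.nf - 3 || j0 < 1 || j0 > m.nf - 3) return;
  double tx = fi - i0, ty = fj - j0;
  int k = (int)std::floor((z - m.z0) / m.dz);
  if (k < 0) k = 0;
  if (k > m.nzi - 1) k = m.nzi - 1;
  double tz = z - (m.z0 + k * m.dz);
  double wx[4], dwx[4], wy[4], dwy[4];
  cr_weights(tx, wx, deriv ? dwx : (double *)0);
  cr_weights(ty, wy, deriv ? dwy : (double *)0);
  const size_t s_ix = (size_t)m.nf;
  const size_t s_k = (size_t)m.nf * m.nf;
  const size_t s_c = s_k * (size_t)m.nzi;
  for (int a = 0; a < 4; a++) {
    int iy = j0 - 1 + a;
    for (int b = 0; b < 4; b++) {
      int ix = i0 - 1 + b;
      size_t base = (size_t)iy + s_ix * ix + s_k * k;
      double c0 = m.coef[base];
      double c1 = m.coef[base + s_c];
      double c2 = m.coef[base + 2 * s_c];
      double c3 = m.coef[base + 3 * s_c];
      double v = c0 + tz * (c1 + tz * (c2 + tz * c3));
      double w = wy[a] * wx[b];
      out[0] += w * v;
      if (deriv) {
        double vz = c1 + tz * (2.0 * c2 + 3.0 * c3 * tz);
        out[1] += wy[a] * dwx[b] * v;
        out[2] += dwy[a] * wx[b] * v;
        out[3] += w * vz;
      }
    }
  }
  if (deriv) {
    out[1] /= m.fh;
    out[2] /= m.fh;
  }
}

// Expected-intensity patch (and derivatives w.r.t. emitter dx, dy, z) for a
// unit-intensity emitter at lateral offset (dx, dy) from the window centre.
// Patch pixel (r, c), 0-based, has centre ((c - (w-1)/2) * px, (r ... ) * px).
// [[Rcpp::export]]
List cpp_psf_patch(NumericVector coef, int nf, int nzi, double z0, double dz,
                   double fh, double dx, double dy, double z, int window,
                   double pixel_size, bool deriv) {
  PsfModelC m;
  m.coef = REAL(coef);
  m.nf = nf;
  m.nzi = nzi;
  m.z0 = z0;
  m.dz = dz;
  m.fh = fh;
  NumericMatrix P(window, window), Dx, Dy, Dz;
  if (deriv) {
    Dx = NumericMatrix(window, window);
    Dy = NumericMatrix(window, window);
    Dz = NumericMatrix(window, window);
  }
  double half = (window - 1) / 2.0;
  double out[4];
  for (int r = 0; r < window; r++) {
    double py = (r - half) * pixel_size;
    for (int c = 0; c < window; c++) {
      double px = (c - half) * pixel_size;
      psf_eval(m, px - dx, py - dy, z, deriv, out);
      P(r, c) = out[0];
      if (deriv) {
        Dx(r, c) = -out[1];  // d/d(dx) = -d/d(ux)
        Dy(r, c) = -out[2];
        Dz(r, c) = out[3];
      }
    }
  }
  if (deriv)
    return List::create(_["P"] = P, _["Dx"] = Dx, _["Dy"] = Dy, _["Dz"] = Dz);
  return List::create(_["P"] = P);
}

// solve A x = b in place for a small dense system; returns false if singular
static bool solve_small(double A[5][5], double b[5], int n) {
  for (int col = 0; col < n; col++) {
    int best = col;
    double amax = std::fabs(A[col][col]);
    for (int r = col + 1; r < n; r++)
      if (std::fabs(A[r][col]) > amax) {
        amax = std::fabs(A[r][col]);
        best = r;
      }
    if (amax < 1e-300) return false;
    if (best != col) {
      for (int c = 0; c < n; c++) std::swap(A[col][c], A[best][c]);
      std::swap(b[col], b[best]);
    }
    for (int r = col + 1; r < n; r++) {
      double f = A[r][col] / A[col][col];
      for (int c = col; c < n; c++) A[r][c] -= f * A[col][c];
      b[r] -= f * b[col];
    }
  }
  for (int r = n - 1; r >= 0; r--) {
    double s = b[r];
    for (int c = r + 1; c < n; c++) s -= A[r][c] * b[c];
    b[r] = s / A[r][r];
  }
  return true;
}

struct FitWork {
  std::vector<double> mu, jx, jy, jz;
};

// negative Poisson log-likelihood (up to the k! term) and, if requested,
// gradient g and Fisher-scoring matrix F for theta = (dx, dy, z, N, bg)
static double nll_eval(const PsfModelC &m, const double *data, int w,
                       double pixel_size, const double *th, double *g,
                       double F[5][5]) {
  double half = (w - 1) / 2.0;
  double out[4];
  double nll = 0.0;
  if (g) {
    for (int i = 0; i < 5; i++) {
      g[i] = 0.0;
      for (int j = 0; j < 5; j++) F[i][j] = 0.0;
    }
  }
  for (int r = 0; r < w; r++) {
    double py = (r - half) * pixel_size;
    for (int c = 0; c < w; c++) {
      double px = (c - half) * pixel_size;
      psf_eval(m, px - th[0], py - th[1], th[2], g != 0, out);
      double mu = th[3] * out[0] + th[4];
      if (mu < 1e-10) mu = 1e-10;
      double k = data[r + w * c];
      nll += mu - k * std::log(mu);
      if (g) {
        double d[5];
        d[0] = -th[3] * out[1];
        d[1] = -th[3] * out[2];
        d[2] = th[3] * out[3];
        d[3] = out[0];
        d[4] = 1.0;
        double resid = 1.0 - k / mu;
        for (int i = 0; i < 5; i++) {
          g[i] += resid * d[i];
          for (int j = i; j < 5; j++) F[i][j] += d[i] * d[j] / mu;
        }
      }
    }
  }
  if (g)
    for (int i = 0; i < 5; i++)
      for (int j = 0; j < i; j++) F[i][j] = F[j][i];
  return nll;
}

static double full_loglik(const PsfModelC &m, const double *data, int w,
                          double pixel_size, const double *th) {
  double half = (w - 1) / 2.0;
  double out[4];
  double ll = 0.0;
  for (int r = 0; r < w; r++) {
    double py = (r - half) * pixel_size;
    for (int c = 0; c < w; c++) {
      double px = (c - half) * pixel_size;
      psf_eval(m, px - th[0], py - th[1], th[2], false, out);
      double mu = th[3] * out[0] + th[4];
      if (mu < 1e-10) mu = 1e-10;
      double k = data[r + w * c];
      ll += k * std::log(mu) - mu - std::lgamma(k + 1.0);
    }
  }
  return ll;
}

// Damped Newton (Levenberg-style Fisher scoring) Poisson MLE of a single
// emitter: theta = (dx, dy, z, N, bg). init and bounds in nanometres /
// photons. Converges when the largest position update falls below tol (nm).
// [[Rcpp::export]]
List cpp_fit_mle(NumericMatrix data, NumericVector coef, int nf, int nzi,
                 double z0, double dz, double fh, double pixel_size,
                 NumericVector init, NumericVector zlim, int maxit = 50,
                 double tol = 0.01) {
  PsfModelC m;
  m.coef = REAL(coef);
  m.nf = nf;
  m.nzi = nzi;
  m.z0 = z0;
  m.dz = dz;
  m.fh = fh;
  int w = data.nrow();
  const double *dat = REAL(data);
  double th[5];
  for (int i = 0; i < 5; i++) th[i] = init[i];
  double latmax = 2.0 * pixel_size;
  double zlo = zlim[0], zhi = zlim[1];
  th[2] = std::min(std::max(th[2], zlo), zhi);
  th[3] = std::max(th[3], 1.0);
  th[4] = std::max(th[4], 0.0);

  double g[5], F[5][5];
  double nll = nll_eval(m, dat, w, pixel_size, th, g, F);
  double ll_init = full_loglik(m, dat, w, pixel_size, th);
  double lambda = 1e-3;
  bool converged = false;
  int it = 0;
  for (it = 0; it < maxit && !converged; it++) {
    bool accepted = false;
    for (int inner = 0; inner < 12 && !accepted; inner++) {
      double A[5][5], b[5];
      for (int i = 0; i < 5; i++) {
        for (int j = 0; j < 5; j++) A[i][j] = F[i][j];
        A[i][i] *= (1.0 + lambda);
        A[i][i] += 1e-12;
        b[i] = -g[i];
      }
      if (!solve_small(A, b, 5)) {
        lambda *= 10.0;
        continue;
      }
      double trial[5];
      for (int i = 0; i < 5; i++) trial[i] = th[i] + b[i];
      trial[0] = std::min(std::max(trial[0], -latmax), latmax);
      trial[1] = std::min(std::max(trial[1], -latmax), latmax);
      trial[2] = std::min(std::max(trial[2], zlo), zhi);
      trial[3] = std::max(trial[3], 1.0);
      trial[4] = std::max(trial[4], 0.0);
      double nll_t = nll_eval(m, dat, w, pixel_size, trial, (double *)0,
                              (double (*)[5])0);
      if (nll_t <= nll) {
        double dpos = std::max(std::fabs(trial[0] - th[0]),
                               std::max(std::fabs(trial[1] - th[1]),
                                        std::fabs(trial[2] - th[2])));
        for (int i = 0; i < 5; i++) th[i] = trial[i];
        nll = nll_t;
        lambda = std::max(lambda / 3.0, 1e-9);
        accepted = true;
        if (dpos < tol) converged = true;
      } else {
        lambda *= 10.0;
      }
    }
    if (!accepted) break;  // no acceptable step: treat as stalled
    if (!converged) nll = nll_eval(m, dat, w, pixel_size, th, g, F);
  }
  double ll = full_loglik(m, dat, w, pixel_size, th);
  return List::create(_["par"] = NumericVector(th, th + 5), _["loglik"] = ll,
                      _["loglik_init"] = ll_init, _["nll"] = nll,
                      _["converged"] = converged, _["iterations"] = it);
}

static inline double median_of(std::vector<double> &v) {
  size_t n = v.size();
  size_t h = n / 2;
  std::nth_element(v.begin(), v.begin() + h, v.end());
  double m = v[h];
  if (n % 2 == 0) {
    double lo = *std::max_element(v.begin(), v.begin() + h);
    m = 0.5 * (m + lo);
  }
  return m;
}

// 2D running median with window truncation at the borders. An even width w
// covers offsets -w/2 ... w/2 - 1. NA cells are skipped; a cell that is NA
// on input stays NA on output.
// [[Rcpp::export]]
NumericMatrix cpp_median_filter2(NumericMatrix x, int width) {
  int nr = x.nrow(), nc = x.ncol();
  int lo = -(width / 2), hi = width - 1 - width / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve((size_t)width * width);
  for (int r = 0; r < nr; r++) {
    for (int c = 0; c < nc; c++) {
      if (NumericMatrix::is_na(x(r, c))) {
        out(r, c) = NA_REAL;
        continue;
      }
      buf.clear();
      int r0 = std::max(0, r + lo), r1 = std::min(nr - 1, r + hi);
      int c0 = std::max(0, c + lo), c1 = std::min(nc - 1, c + hi);
      for (int cc = c0; cc <= c1; cc++)
        for (int rr = r0; rr <= r1; rr++) {
          double v = x(rr, cc);
          if (!NumericMatrix::is_na(v)) buf.push_back(v);
        }
      out(r, c) = buf.empty() ? NA_REAL : median_of(buf);
    }
  }
  return out;
}

// median of every row of a matrix (used for per-grid-point temporal medians)
// [[Rcpp::export]]
NumericVector cpp_row_median(NumericMatrix x) {
  int nr = x.nrow(), nc = x.ncol();
  NumericVector out(nr);
  std::vector<double> buf(nc);
  for (int r = 0; r < nr; r++) {
    for (int c = 0; c < nc; c++) buf[c] = x(r, c);
    std::vector<double> b(buf);
    out[r] = median_of(b);
  }
  return out;
}
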