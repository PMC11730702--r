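#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Smooth heightfield z = f(x, y) built from a sum of Gaussian bumps.
// bumps: n x 4 matrix with columns (center_x, center_y, sigma, amplitude).
static inline double hf_eval(const NumericMatrix& bumps, double x, double y,
                             double* gx = 0, double* gy = 0) {
  double z = 0, dgx = 0, dgy = 0;
  const int n = bumps.nrow();
  for (int i = 0; i < n; ++i) {
    double dx = x - bumps(i, 0), dy = y - bumps(i, 1);
    double s2 = bumps(i, 2) * bumps(i, 2);
    double e = bumps(i, 3) * std::exp(-0.5 * (dx * dx + dy * dy) / s2);
    z += e;
    if (gx) { dgx += -e * dx / s2; dgy += -e * dy / s2; }
  }
  if (gx) { *gx = dgx; *gy = dgy; }
  return z;
}

// Heightfield value and gradient at arbitrary (x, y).
// [[Rcpp::export]]
List heightfield_eval_cpp(NumericMatrix bumps, NumericVector x, NumericVector y) {
  const int n = x.size();
  NumericVector z(n), gx(n), gy(n);
  for (int i = 0; i < n; ++i) {
    double a, b;
    z[i] = hf_eval(bumps, x[i], y[i], &a, &b);
    gx[i] = a; gy[i] = b;
  }
  return List::create(_["z"] = z, _["gx"] = gx, _["gy"] = gy);
}

// First intersection of rays with the heightfield surface, by marching along
// each ray and bisecting the bracketed sign change of g(t) = z(t) - f(x, y).
// The surface exists only over |x| <= domain, |y| <= domain. Rays are given
// in world coordinates (origins n x 3, dirs n x 3, dirs need not be unit).
// Returns ray parameter t (NA when no hit within [tmin, tmax]).
// [[Rcpp::export]]
NumericVector raycast_heightfield_cpp(NumericMatrix bumps, NumericMatrix origins,
                                      NumericMatrix dirs, double tmin, double tmax,
                                      int nsteps, double domain) {
  const int n = origins.nrow();
  NumericVector tout(n, NA_REAL);
  const double dt = (tmax - tmin) / nsteps;
  for (int i = 0; i < n; ++i) {
    double ox = origins(i,0), oy = origins(i,1), oz = origins(i,2);
    double dx = dirs(i,0), dy = dirs(i,1), dz = dirs(i,2);
    double tprev = tmin;
    double gprev = (oz + tprev * dz) - hf_eval(bumps, ox + tprev * dx, oy + tprev * dy);
    bool found = false;
    for (int s = 1; s <= nsteps && !found; ++s) {
      double t = tmin + s * dt;
      double px = ox + t * dx, py = oy + t * dy;
      double g = (oz + t * dz) - hf_eval(bumps, px, py);
      if (gprev < 0 && g >= 0) {
        // bisection refine
        double lo = tprev, hi = t;
        for (int it = 0; it < 60; ++it) {
          double mid = 0.5 * (lo + hi);
          double gm = (oz + mid * dz) -
            hf_eval(bumps, ox + mid * dx, oy + mid * dy);
          if (gm < 0) lo = mid; else hi = mid;
        }
        double th = 0.5 * (lo + hi);
        double hx = ox + th * dx, hy = oy + th * dy;
        if (std::fabs(hx) <= domain && std::fabs(hy) <= domain) {
          tout[i] = th;
          found = true;
        }
        // crossing outside the domain: keep marching (surface absent there)
      }
      tprev = t; gprev = g;
    }
  }
  return tout;
}
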