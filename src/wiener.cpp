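#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// First-passage quantities for a Wiener process with drift v and diffusion
// coefficient s between absorbing boundaries at 0 and a, started at z.
// Internally everything is reduced to normalised coordinates
//   w  = z / a            (relative start, 0 < w < 1)
//   vn = v * a / s^2      (normalised drift)
//   tau = t * s^2 / a^2   (normalised time)
// Series are evaluated adaptively; the density switches between the
// small-time image series and the large-time trigonometric series.

static const double PISQ = M_PI * M_PI;
static const double TAU_FLOOR = 1e-7;   // below this, absorbed mass is negligible

// P(hit a before 0); expm1 form is stable down to |2va/s^2| ~ 1e-8,
// below that a first-order expansion around v = 0 is used.
static double absorb_upper_raw(double v, double a, double z, double s) {
  double k = 2.0 * v / (s * s);
  if (std::fabs(k * a) < 1e-8)
    return z / a + k * z * (a - z) / (2.0 * a);
  return std::expm1(-k * z) / std::expm1(-k * a);
}

// Defective density of absorption at the LOWER boundary at time t.
static double pdf_lower_raw(double t, double v, double a, double z, double s) {
  if (t <= 0.0) return 0.0;
  double asq = a * a / (s * s);
  double tau = t / asq;
  double w = z / a;
  double vn = v * a / (s * s);
  double pre = std::exp(-vn * w - 0.5 * vn * vn * tau) / asq;
  if (pre == 0.0 || !std::isfinite(pre)) return 0.0;

  double f0;
  if (tau < 0.1) {
    // small-time (method of images) series in normalised time
    double c = 1.0 / std::sqrt(2.0 * M_PI * tau * tau * tau);
    double sum = w * std::exp(-w * w / (2.0 * tau));
    for (int k = 1; k <= 100; ++k) {
      double u1 = w + 2.0 * k, u2 = w - 2.0 * k;
      double t1 = u1 * std::exp(-u1 * u1 / (2.0 * tau));
      double t2 = u2 * std::exp(-u2 * u2 / (2.0 * tau));
      sum += t1 + t2;
      if (std::fabs(t1) + std::fabs(t2) < 1e-15 && k >= 2) break;
    }
    f0 = c * sum;
  } else {
    // large-time trigonometric series; exp(-k^2 c) and sin(k pi w) are
    // advanced by multiplicative / Chebyshev recurrences
    double r = std::exp(-0.5 * PISQ * tau);   // damp_k = r^(k^2)
    double u = r;                             // r^(k^2)
    double mstep = r * r * r;                 // r^(2k+1)
    double r2 = r * r;
    double s1 = std::sin(M_PI * w), s0 = 0.0;
    double c2 = 2.0 * std::cos(M_PI * w);
    double sum = 0.0;
    for (int k = 1; k <= 20000; ++k) {
      sum += k * s1 * u;
      if (k * u < 1e-13 && k >= 3) break;
      double s2 = c2 * s1 - s0; s0 = s1; s1 = s2;
      u *= mstep; mstep *= r2;
    }
    f0 = M_PI * sum;
  }
  if (f0 < 0.0) f0 = 0.0;
  return pre * f0;
}

// Defective CDF of absorption at the LOWER boundary by time t.  The
// large-time series integrates term by term in closed form, so
//   F(t) = P_lower - pi * e^{-vn w} * sum_k k sin(k pi w)
//                     exp(-(vn^2 + k^2 pi^2) tau / 2) * 2/(vn^2 + k^2 pi^2)
static double cdf_lower_raw(double t, double v, double a, double z, double s) {
  if (t <= 0.0) return 0.0;
  double asq = a * a / (s * s);
  double tau = t / asq;
  double w = z / a;
  double vn = v * a / (s * s);
  double plow = 1.0 - absorb_upper_raw(v, a, z, s);
  if (tau < TAU_FLOOR) return 0.0;
  double pre = std::exp(-vn * w);
  // damp_k = exp(-0.5 (vn^2 + k^2 pi^2) tau) = E * r^(k^2); recurrences as
  // in the density avoid per-term exp/sin calls
  double E = std::exp(-0.5 * vn * vn * tau);
  double r = std::exp(-0.5 * PISQ * tau);
  double u = r, mstep = r * r * r, r2 = r * r;
  double s1 = std::sin(M_PI * w), s0 = 0.0;
  double c2 = 2.0 * std::cos(M_PI * w);
  double sum = 0.0;
  for (int k = 1; k <= 50000; ++k) {
    double den = vn * vn + k * (double)k * PISQ;
    double damp = E * u;
    sum += 2.0 * k * s1 * damp / den;
    if (2.0 * k * damp / den < 1e-13 && k >= 3) break;
    double s2 = c2 * s1 - s0; s0 = s1; s1 = s2;
    u *= mstep; mstep *= r2;
  }
  double F = plow - M_PI * pre * sum;
  if (F < 0.0) F = 0.0;
  if (F > plow) F = plow;
  return F;
}

// [[Rcpp::export]]
double cpp_absorb_upper(double v, double a, double z, double s) {
  return absorb_upper_raw(v, a, z, s);
}

// [[Rcpp::export]]
NumericVector cpp_wiener_pdf(NumericVector t, double v, double a, double z,
                             double s, bool upper) {
  // upper boundary by reflection: f_upper(t; v, a, z) = f_lower(t; -v, a, a-z)
  double vv = upper ? -v : v;
  double zz = upper ? a - z : z;
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = pdf_lower_raw(t[i], vv, a, zz, s);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_wiener_cdf(NumericVector t, double v, double a, double z,
                             double s, bool upper) {
  double vv = upper ? -v : v;
  double zz = upper ? a - z : z;
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = cdf_lower_raw(t[i], vv, a, zz, s);
  return out;
}

// Marginal upper-boundary absorption probability over quadrature grids for
// trial-to-trial drift (vs, wv) and starting point (zs, wz); weights are
// normalised to sum to 1 on the R side.
// [[Rcpp::export]]
double cpp_rdm_prob_upper(NumericVector vs, NumericVector wv,
                          NumericVector zs, NumericVector wz,
                          double a, double s) {
  double acc = 0.0;
  for (int i = 0; i < vs.size(); ++i)
    for (int j = 0; j < zs.size(); ++j)
      acc += wv[i] * wz[j] * absorb_upper_raw(vs[i], a, zs[j], s);
  return acc;
}

// Marginal defective RT CDF at times t for the named boundary, integrating
// over drift nodes (vs, wv), start nodes (zs, wz) and non-decision-time
// nodes (ters, wt).  The (v, z) pair is the outer loop so that all
// decision-time-independent quantities (absorption probability, sin/cos of
// the relative start, drift prefactor) are computed once per pair.
// [[Rcpp::export]]
NumericVector cpp_rdm_cdf(NumericVector t, NumericVector vs, NumericVector wv,
                          NumericVector zs, NumericVector wz,
                          NumericVector ters, NumericVector wt,
                          double a, double s, bool upper) {
  int n = t.size();
  NumericVector out(n);
  double asq = a * a / (s * s);
  for (int i = 0; i < vs.size(); ++i) {
    double vv = upper ? -vs[i] : vs[i];
    double vn = vv * a / (s * s);
    for (int j = 0; j < zs.size(); ++j) {
      double zz = upper ? a - zs[j] : zs[j];
      double w = zz / a;
      double wgt = wv[i] * wz[j];
      double plow = 1.0 - absorb_upper_raw(vv, a, zz, s);
      double pre = std::exp(-vn * w);
      double sinw = std::sin(M_PI * w);
      double cosw2 = 2.0 * std::cos(M_PI * w);
      for (int m = 0; m < n; ++m) {
        double acc = 0.0;
        for (int k = 0; k < ters.size(); ++k) {
          double td = t[m] - ters[k];
          if (td <= 0.0) continue;
          double tau = td / asq;
          double F;
          if (tau < TAU_FLOOR) {
            F = 0.0;
          } else {
            double E = std::exp(-0.5 * vn * vn * tau);
            double r = std::exp(-0.5 * PISQ * tau);
            double u = r, mstep = r * r * r, r2 = r * r;
            double s1 = sinw, s0 = 0.0;
            double sum = 0.0;
            for (int kk = 1; kk <= 50000; ++kk) {
              double den = vn * vn + kk * (double)kk * PISQ;
              double damp = E * u;
              sum += 2.0 * kk * s1 * damp / den;
              if (2.0 * kk * damp / den < 1e-13 && kk >= 3) break;
              double s2 = cosw2 * s1 - s0; s0 = s1; s1 = s2;
              u *= mstep; mstep *= r2;
            }
            F = plow - M_PI * pre * sum;
            if (F < 0.0) F = 0.0;
            if (F > plow) F = plow;
          }
          acc += wt[k] * F;
        }
        out[m] += wgt * acc;
      }
    }
  }
  return out;
}

// Euler-Maruyama trial simulator with the Broadie-Glasserman/Gobet boundary
// continuity correction (effective boundaries pulled inward by
// 0.5826 * s * sqrt(dt)), which reduces the O(sqrt(dt)) first-passage bias
// to O(dt).  Uses R's RNG so set.seed() governs reproducibility.
// Returns a matrix with columns: latency (s), upper-hit flag (0/1).
// [[Rcpp::export]]
NumericMatrix cpp_simulate_trials(int n, double v, double a, double z,
                                  double ter, double eta, double sz,
                                  double st, double s, double dt) {
  NumericMatrix out(n, 2);
  const double beta = 0.5826;
  double corr = beta * s * std::sqrt(dt);
  if (corr > 0.25 * a) corr = 0.25 * a;  // guard pathological dt
  double lo = corr, hi = a - corr;
  double sdt = s * std::sqrt(dt);
  const long max_steps = 100000000L;  // 10^8 * dt seconds hard cap
  for (int i = 0; i < n; ++i) {
    double vt = (eta > 0.0) ? R::rnorm(v, eta) : v;
    double x = (sz > 0.0) ? R::runif(z - sz / 2.0, z + sz / 2.0) : z;
    double tt = (st > 0.0) ? R::runif(ter - st / 2.0, ter + st / 2.0) : ter;
    long k = 0;
    while (x > lo && x < hi && k < max_steps) {
      x += vt * dt + sdt * R::norm_rand();
      ++k;
    }
    out(i, 0) = tt + k * dt;
    out(i, 1) = (x >= hi) ? 1.0 : 0.0;
  }
  return out;
}
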