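#include <Rcpp.h>
using namespace Rcpp;

// First-passage-time machinery for a Wiener diffusion between absorbing
// boundaries 0 and a, with drift v, unit diffusion coefficient and relative
// start w = z/a (w = 1/2 throughout the package: unbiased start).
//
// All "lower" quantities refer to absorption at the lower boundary (0).
// Upper-boundary quantities follow by reflection:
//   f_upper(t; v, w) = f_lower(t; -v, 1 - w).
//
// Two classical series are used with a crossover on scaled time tau = t/a^2:
// an image (small-time) expansion and an eigenfunction (large-time)
// expansion.  Series are truncated once the term envelope drops below
// TERM_EPS (well under the 1e-10 the estimation layer needs).

static const double TERM_EPS = 1e-13;
static const double TAU_CROSSOVER = 0.12;

// P(absorbed at lower boundary eventually)
static double prob_lower(double a, double v, double w) {
  if (std::fabs(v * a) < 1e-10) return 1.0 - w;
  if (v > 0) {
    // (expm1(-2vaw) - expm1(-2va)) / (-expm1(-2va)); exponents <= 0
    double e1 = std::expm1(-2.0 * v * a * w);
    double e2 = std::expm1(-2.0 * v * a);
    return (e1 - e2) / (0.0 - e2);
  }
  // multiply numerator and denominator by exp(2va): exponents <= 0 for v < 0
  return std::expm1(2.0 * v * a * (1.0 - w)) / std::expm1(2.0 * v * a);
}

// defective density of absorption time at the lower boundary
static double density_lower_one(double t, double a, double v, double w) {
  if (!(t > 0.0)) return 0.0;
  double aa = a * a;
  double tau = t / aa;
  double lmult = -v * a * w - 0.5 * v * v * t - std::log(aa);
  double f;
  if (tau < TAU_CROSSOVER) {
    // image expansion, scaled time
    double s = (w)*std::exp(-(w) * (w) / (2.0 * tau));
    for (int k = 1; k < 1000; ++k) {
      double m1 = w + 2.0 * k;
      double m2 = w - 2.0 * k;
      double t1 = m1 * std::exp(-m1 * m1 / (2.0 * tau));
      double t2 = m2 * std::exp(-m2 * m2 / (2.0 * tau));
      s += t1 + t2;
      if (std::fabs(t1) + std::fabs(t2) < TERM_EPS) break;
    }
    f = s / std::sqrt(2.0 * M_PI * tau * tau * tau);
  } else {
    double s = 0.0;
    for (int k = 1; k < 10000; ++k) {
      double env = k * std::exp(-0.5 * k * k * M_PI * M_PI * tau);
      s += env * std::sin(k * M_PI * w);
      if (env < TERM_EPS && k > 2) break;
    }
    f = M_PI * s;
  }
  double out = f * std::exp(lmult);
  return (R_finite(out) && out > 0.0) ? out : 0.0;
}

// integral over (0, t] of one image term of the density, folded with its
// exponential prefactor for numerical stability; m = z + 2ka, z = w*a.
static double cdf_image_term(double t, double m, double z, double v) {
  double sq = std::sqrt(t);
  double s = (m > 0.0) ? 1.0 : -1.0;
  double am = std::fabs(m);
  double l1 = R::pnorm((-s * v * t - am) / sq, 0.0, 1.0, 1, 1);
  double l2 = R::pnorm((s * v * t - am) / sq, 0.0, 1.0, 1, 1);
  return s * (std::exp(v * (m - z) + l1) + std::exp(-v * (m + z) + l2));
}

static double cdf_lower_small(double t, double a, double v, double w) {
  double z = w * a;
  double sum = cdf_image_term(t, z, z, v);
  for (int k = 1; k < 500; ++k) {
    double t1 = cdf_image_term(t, z + 2.0 * k * a, z, v);
    double t2 = cdf_image_term(t, z - 2.0 * k * a, z, v);
    sum += t1 + t2;
    if (std::fabs(t1) + std::fabs(t2) < TERM_EPS && k > 1) break;
  }
  return sum;
}

static double cdf_lower_large(double t, double a, double v, double w) {
  double P = prob_lower(a, v, w);
  double aa = a * a;
  double lpref = -v * a * w + std::log(M_PI / aa);
  double sum = 0.0;
  for (int k = 1; k < 10000; ++k) {
    double lambda = 0.5 * (v * v + k * k * M_PI * M_PI / aa);
    double env = k * std::exp(-lambda * t) / lambda;
    sum += env * std::sin(k * M_PI * w);
    if (env < TERM_EPS && k > 2) break;
  }
  double val = P - std::exp(lpref) * sum;
  if (val < 0.0) val = 0.0;
  if (val > P) val = P;
  return val;
}

static double cdf_lower_one(double t, double a, double v, double w) {
  if (!(t > 0.0)) return 0.0;
  double tau = t / (a * a);
  if (tau < TAU_CROSSOVER) {
    double val = cdf_lower_small(t, a, v, w);
    if (val < 0.0) val = 0.0;
    return val;
  }
  return cdf_lower_large(t, a, v, w);
}

//' @noRd
// [[Rcpp::export(name = ".wfpt_density_cpp")]]
NumericVector wfpt_density_cpp(NumericVector t, double a, double v, double w,
                               bool lower) {
  double vv = lower ? v : -v;
  double ww = lower ? w : 1.0 - w;
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    if (!R_finite(t[i])) stop("non-finite time passed to the FPT density");
    out[i] = density_lower_one(t[i], a, vv, ww);
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".wfpt_cdf_cpp")]]
NumericVector wfpt_cdf_cpp(NumericVector t, double a, double v, double w,
                           bool lower) {
  double vv = lower ? v : -v;
  double ww = lower ? w : 1.0 - w;
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    if (ISNAN(t[i])) stop("NA time passed to the FPT distribution");
    if (t[i] == R_PosInf) {
      out[i] = prob_lower(a, vv, ww);
    } else {
      out[i] = cdf_lower_one(t[i], a, vv, ww);
    }
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".prob_lower_cpp")]]
double prob_lower_cpp(double a, double v, double w) {
  return prob_lower(a, v, w);
}

// P(hit boundary, Td + Ter <= t) with Ter ~ U(t0 - st0/2, t0 + st0/2):
// average of the decision-time CDF over the clamped uniform window
// (Gauss-Legendre nodes on [0,1] supplied by the caller); st0 = 0 is a
// pure shift.
static double conv_cdf_one(double t, double a, double v, bool lower,
                           double t0, double st0,
                           const NumericVector& glx,
                           const NumericVector& glw) {
  double vv = lower ? v : -v;
  if (st0 < 1e-9) {
    double td = t - t0;
    return (td > 0.0) ? cdf_lower_one(td, a, vv, 0.5) : 0.0;
  }
  double lo = t0 - 0.5 * st0;
  double hi = t0 + 0.5 * st0;
  double up = (t < hi) ? t : hi;
  double len = up - lo;
  if (len <= 0.0) return 0.0;
  double acc = 0.0;
  int m = glx.size();
  for (int j = 0; j < m; ++j)
    acc += glw[j] * cdf_lower_one(t - (lo + len * glx[j]), a, vv, 0.5);
  return acc * len / st0;
}

// CDF of the signed total RT (errors on the negative axis)
//' @noRd
// [[Rcpp::export(name = ".signed_cdf_cpp")]]
NumericVector signed_cdf_cpp(NumericVector ts, double a, double v,
                             double t0, double st0, NumericVector glx,
                             NumericVector glw) {
  double q = prob_lower(a, v, 0.5);  // error probability
  int n = ts.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double s = ts[i];
    double val;
    if (s < 0.0)
      val = q - conv_cdf_one(-s, a, v, true, t0, st0, glx, glw);
    else
      val = q + conv_cdf_one(s, a, v, false, t0, st0, glx, glw);
    if (val < 0.0) val = 0.0;
    if (val > 1.0) val = 1.0;
    out[i] = val;
  }
  return out;
}

// sup over both one-sided limits of every empirical jump point of
// |model signed CDF - empirical signed CDF|
//' @noRd
// [[Rcpp::export(name = ".ks_stat_cpp")]]
double ks_stat_cpp(NumericVector jumps, NumericVector ecdf_hi,
                   NumericVector ecdf_lo, double a, double v, double t0,
                   double st0, NumericVector glx, NumericVector glw) {
  NumericVector fm = signed_cdf_cpp(jumps, a, v, t0, st0, glx, glw);
  double d = 0.0;
  for (int i = 0; i < jumps.size(); ++i) {
    double d1 = std::fabs(fm[i] - ecdf_hi[i]);
    double d2 = std::fabs(fm[i] - ecdf_lo[i]);
    if (d1 > d) d = d1;
    if (d2 > d) d = d2;
  }
  return d;
}

// Euler-Maruyama simulation of the decision process with a Brownian-bridge
// crossing correction (the probability that the path crossed a boundary
// inside a step even though both endpoints are interior is
// exp(-2 d0 d1 / dt); sampling it removes the O(sqrt(dt)) overshoot bias).
// One trial per drift entry; start at a/2, absorbed at 0 (error) or a
// (correct).  Uses R's RNG so results are reproducible under set.seed().
//' @noRd
// [[Rcpp::export(name = ".sim_wiener_cpp")]]
List sim_wiener_cpp(NumericVector v, double a, double t0, double st0,
                    double dt) {
  int n = v.size();
  IntegerVector correct(n);
  NumericVector rt(n);
  double z0 = 0.5 * a;
  double sdt = std::sqrt(dt);
  // bridge check only when exp(-2 d0 d1 / dt) > ~1e-12
  double near = 14.0 * dt;
  for (int i = 0; i < n; ++i) {
    double x = z0;
    double steps = 0.0;
    int hit = -1;
    for (;;) {
      double x0 = x;
      x += v[i] * dt + sdt * norm_rand();
      steps += 1.0;
      if (x >= a) { hit = 1; break; }
      if (x <= 0.0) { hit = 0; break; }
      double du = (a - x0) * (a - x);
      if (du < near && unif_rand() < std::exp(-2.0 * du / dt)) {
        hit = 1; break;
      }
      double dl = x0 * x;
      if (dl < near && unif_rand() < std::exp(-2.0 * dl / dt)) {
        hit = 0; break;
      }
      if (steps > 4e7) { hit = (x > z0) ? 1 : 0; break; }  // safety valve
    }
    double ter = t0 + ((st0 > 0.0) ? st0 * (unif_rand() - 0.5) : 0.0);
    correct[i] = hit;
    rt[i] = steps * dt + ter;
  }
  return List::create(_["correct"] = correct, _["rt"] = rt);
}
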