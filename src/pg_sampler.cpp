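// Polya-Gamma random variate generation.
//
// PG(1, c) uses the exact alternating-series rejection sampler on the
// tilted Jacobi J*(1, c/2) density (Devroye-type); PG(b, c) for integer b
// is a sum of b independent PG(1, c) draws.  A truncated sum-of-gammas
// representation (200 terms plus a deterministic mean correction for the
// discarded tail) is provided as a portable fallback and for non-integer b.
//
// All randomness comes from R's RNG so that set.seed() governs every draw.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double TRUNC = 0.64;  // series switch point of the J* density

// n-th coefficient of the alternating series bounding the J*(1, z) density
static double a_coef(int n, double x) {
  double np5 = n + 0.5;
  if (x > TRUNC)
    return M_PI * np5 * std::exp(-np5 * np5 * M_PI * M_PI * x / 2.0);
  double r = 2.0 / (M_PI * x);
  return M_PI * np5 * r * std::sqrt(r) * std::exp(-2.0 * np5 * np5 / x);
}

// inverse-Gaussian(mu = 1/z, lambda = 1) truncated to (0, TRUNC)
static double rtigauss(double z) {
  double t = TRUNC;
  double x = t + 1.0;
  if (z < 1.0 / t) {  // mu > t: rejection from the truncated chi-based proposal
    while (true) {
      double e1, e2;
      do {
        e1 = R::exp_rand();
        e2 = R::exp_rand();
      } while (e1 * e1 > 2.0 * e2 / t);
      x = t / ((1.0 + t * e1) * (1.0 + t * e1));
      if (R::unif_rand() <= std::exp(-0.5 * z * z * x)) break;
    }
  } else {           // mu <= t: draw IG and retry until inside (0, t)
    double mu = 1.0 / z;
    x = t + 1.0;
    while (x > t) {
      double y = R::norm_rand();
      y = y * y;
      double muy = mu * y;
      x = mu + 0.5 * mu * muy - 0.5 * mu * std::sqrt(4.0 * muy + muy * muy);
      if (R::unif_rand() > mu / (mu + x)) x = mu * mu / x;
    }
  }
  return x;
}

// log standard-normal CDF via erfc (cheaper than the full pnorm path);
// falls back to R's implementation in the extreme tail
static inline double log_phi(double x) {
  double p = 0.5 * std::erfc(-x * M_SQRT1_2);
  if (p > 0.0) return std::log(p);
  return R::pnorm(x, 0.0, 1.0, 1, 1);
}

// probability that the two-piece proposal uses the exponential tail
static double mass_texpon(double z) {
  double t = TRUNC;
  double fz = M_PI * M_PI / 8.0 + z * z / 2.0;
  double b = std::sqrt(1.0 / t) * (t * z - 1.0);
  double a = -std::sqrt(1.0 / t) * (t * z + 1.0);
  double x0 = std::log(fz) + fz * t;
  double xb = x0 - z + log_phi(b);
  double xa = x0 + z + log_phi(a);
  double qdivp = 4.0 / M_PI * (std::exp(xb) + std::exp(xa));
  return 1.0 / (1.0 + qdivp);
}

// one exact PG(1, c) draw
double rpg1(double c) {
  double z = std::fabs(c) * 0.5;
  double fz = M_PI * M_PI / 8.0 + z * z / 2.0;
  double p = mass_texpon(z);
  while (true) {
    double x;
    if (R::unif_rand() < p)
      x = TRUNC + R::exp_rand() / fz;
    else
      x = rtigauss(z);
    // squeeze acceptance by the alternating partial sums
    double s = a_coef(0, x);
    double y = R::unif_rand() * s;
    int n = 0;
    while (true) {
      ++n;
      if (n % 2 == 1) {
        s -= a_coef(n, x);
        if (y <= s) return x / 4.0;  // J*(1,z)/4 ~ PG(1, c)
      } else {
        s += a_coef(n, x);
        if (y > s) break;
      }
    }
  }
}

// truncated sum-of-gammas draw of PG(b, c); the discarded tail is replaced
// by its exact expectation so the sampler is unbiased in the mean
double rpg_gamma(double b, double c, int trunc) {
  double c2 = (c / (2.0 * M_PI)) * (c / (2.0 * M_PI));
  double total = 0.0, mean_trunc = 0.0;
  for (int k = 1; k <= trunc; ++k) {
    double d = (k - 0.5) * (k - 0.5) + c2;
    total += R::rgamma(b, 1.0) / d;
    mean_trunc += b / d;
  }
  total /= (2.0 * M_PI * M_PI);
  mean_trunc /= (2.0 * M_PI * M_PI);
  double mean_exact =
      (c == 0.0) ? b / 4.0 : b / (2.0 * c) * std::tanh(c / 2.0);
  return total + (mean_exact - mean_trunc);
}

// [[Rcpp::export]]
NumericVector cpp_rpg(int n, double b, NumericVector c, std::string method,
                      int trunc = 200) {
  if (b <= 0) stop("PG shape parameter b must be positive");
  NumericVector out(n);
  bool int_b = std::fabs(b - std::round(b)) < 1e-12;
  bool devroye = (method == "devroye");
  if (devroye && !int_b)
    stop("the exact sampler requires integer b; use method = \"gamma\"");
  int ib = int_b ? (int)std::lround(b) : 0;
  for (int i = 0; i < n; ++i) {
    double ci = c[c.size() == 1 ? 0 : i];
    if (devroye) {
      double s = 0.0;
      for (int k = 0; k < ib; ++k) s += rpg1(ci);
      out[i] = s;
    } else {
      out[i] = rpg_gamma(b, ci, trunc);
    }
  }
  return out;
}
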