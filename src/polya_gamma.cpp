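#include <Rcpp.h>

// Sampler for the Polya-Gamma distribution PG(1, z), used for logistic data
// augmentation: with omega_i ~ PG(1, eta_i), the Bernoulli-logit likelihood
// becomes conditionally Gaussian in the regression coefficients.
// Rejection sampler of Polson, Scott & Windle (2013), built on Devroye's
// alternating-series method for the Jacobi-type density J*(1, z): proposal is
// a mixture of a truncated inverse-Gaussian (left of t = 0.64) and an
// exponential tail, with series evaluation for acceptance.

static const double TRUNC = 0.64;
static const double PISQ8 = M_PI * M_PI / 8.0;

// n-th coefficient of the alternating series bounding the J*(1,0) density,
// piecewise form for small/large x
static double a_coef(int n, double x) {
  double k = (n + 0.5) * M_PI;
  if (x > TRUNC) {
    return k * std::exp(-0.5 * k * k * x);
  }
  // k (2/(pi x))^{3/2} exp(-2 (n+1/2)^2 / x), written without log calls
  const double c32 = 0.5079490874739279;  // (2/pi)^{3/2}
  return k * c32 / (x * std::sqrt(x)) *
    std::exp(-2.0 * (n + 0.5) * (n + 0.5) / x);
}

// standard normal upper-tail-safe log CDF via erfc
static inline double pnorm_log(double q) {
  double e = 0.5 * std::erfc(-q * M_SQRT1_2);
  return (e > 0.0) ? std::log(e) : -INFINITY;
}

// probability that the proposal draw comes from the exponential right tail
static double mass_texpon(double z) {
  double t = TRUNC;
  double fz = PISQ8 + 0.5 * z * z;
  double b = std::sqrt(1.0 / t) * (t * z - 1.0);
  double a = -std::sqrt(1.0 / t) * (t * z + 1.0);
  double x0 = std::log(fz) + fz * t;
  double xb = x0 - z + pnorm_log(b);
  double xa = x0 + z + pnorm_log(a);
  double qdivp = 4.0 / M_PI * (std::exp(xb) + std::exp(xa));
  return 1.0 / (1.0 + qdivp);
}

// inverse-Gaussian(1/z, 1) truncated to (0, TRUNC)
static double rtigauss(double z) {
  double t = TRUNC;
  double x = t + 1.0;
  if (z < 1.0 / t) {
    // mean above the truncation point: rejection from scaled chi-square tail
    double alpha = 0.0;
    while (unif_rand() > alpha) {
      double e1, e2;
      do {
        e1 = exp_rand();
        e2 = exp_rand();
      } while (e1 * e1 > 2.0 * e2 / t);
      x = t / ((1.0 + t * e1) * (1.0 + t * e1));
      alpha = std::exp(-0.5 * z * z * x);
    }
  } else {
    double mu = 1.0 / z;
    while (x > t) {
      double y = norm_rand();
      y = y * y;
      double muy = mu * y;
      x = mu + 0.5 * mu * muy - 0.5 * mu * std::sqrt(4.0 * muy + muy * muy);
      if (unif_rand() > mu / (mu + x)) x = mu * mu / x;
    }
  }
  return x;
}

// one draw from PG(1, z); PG(1,z) = J*(1, z/2) / 4
double rpg1(double z) {
  z = 0.5 * std::fabs(z);
  double fz = PISQ8 + 0.5 * z * z;
  for (;;) {
    double x;
    if (unif_rand() < mass_texpon(z)) {
      x = TRUNC + exp_rand() / fz;
    } else {
      x = rtigauss(z);
    }
    // squeeze via the alternating series: partial sums bracket the density
    double s = a_coef(0, x);
    double y = unif_rand() * s;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        s -= a_coef(n, x);
        if (y <= s) return 0.25 * x;
      } else {
        s += a_coef(n, x);
        if (y > s) break;
      }
    }
  }
}

// [[Rcpp::export(rng = true)]]
Rcpp::NumericVector rpg_cpp(int n, double z) {
  Rcpp::NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rpg1(z);
  return out;
}
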