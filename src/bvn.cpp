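// Bivariate normal orthant probabilities and ordinal (polychoric) cell
// machinery. The CDF follows the Drezner-Wesolowsky/Genz Gauss-Legendre
// scheme in double precision; accuracy ~1e-15, cross-checked against
// mvtnorm::pmvnorm in the test suite.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double phid(double x) {
  return R::pnorm(x, 0.0, 1.0, 1, 0);
}

// Upper-orthant probability P(X > h, Y > k) for standard bivariate normal
// with correlation r.
static double bvnu(double h, double k, double r) {
  if (ISNAN(h) || ISNAN(k) || ISNAN(r)) return NA_REAL;
  if (h == R_PosInf || k == R_PosInf) return 0.0;
  if (h == R_NegInf) return (k == R_NegInf) ? 1.0 : phid(-k);
  if (k == R_NegInf) return phid(-h);
  if (r == 0.0) return phid(-h) * phid(-k);

  static const double w6[3] = {0.1713244923791705, 0.3607615730481384,
                               0.4679139345726904};
  static const double x6[3] = {0.9324695142031522, 0.6612093864662647,
                               0.2386191860831970};
  static const double w12[6] = {0.04717533638651177, 0.1069393259953183,
                                0.1600783285433464,  0.2031674267230659,
                                0.2334925365383547,  0.2491470458134029};
  static const double x12[6] = {0.9815606342467191, 0.9041172563704750,
                                0.7699026741943050, 0.5873179542866171,
                                0.3678314989981802, 0.1252334085114692};
  static const double w20[10] = {0.01761400713915212, 0.04060142980038694,
                                 0.06267204833410906, 0.08327674157670475,
                                 0.1019301198172404,  0.1181945319615184,
                                 0.1316886384491766,  0.1420961093183821,
                                 0.1491729864726037,  0.1527533871307259};
  static const double x20[10] = {0.9931285991850949,  0.9639719272779138,
                                 0.9122344282513259,  0.8391169718222188,
                                 0.7463319064601508,  0.6360536807265150,
                                 0.5108670019508271,  0.3737060887154196,
                                 0.2277858511416451,  0.07652652113349733};
  const double twopi = 6.283185307179586;
  const double *w, *x;
  int lg;
  double ar = std::fabs(r);
  if (ar < 0.3)       { lg = 3;  w = w6;  x = x6;  }
  else if (ar < 0.75) { lg = 6;  w = w12; x = x12; }
  else                { lg = 10; w = w20; x = x20; }

  double hk = h * k, bvn = 0.0;
  if (ar < 0.925) {
    double hs = (h * h + k * k) / 2.0;
    double asr = std::asin(r) / 2.0;
    for (int i = 0; i < lg; i++) {
      for (int is = -1; is <= 1; is += 2) {
        double sn = std::sin(asr * (is * x[i] + 1.0));
        bvn += w[i] * std::exp((sn * hk - hs) / (1.0 - sn * sn));
      }
    }
    bvn = bvn * asr / twopi + phid(-h) * phid(-k);
  } else {
    if (r < 0.0) { k = -k; hk = -hk; }
    if (ar < 1.0) {
      double as = (1.0 - r) * (1.0 + r);
      double a = std::sqrt(as);
      double bs = (h - k) * (h - k);
      double c = (4.0 - hk) / 8.0;
      double d = (12.0 - hk) / 16.0;
      double asr = -(bs / as + hk) / 2.0;
      if (asr > -100.0) {
        bvn = a * std::exp(asr) *
              (1.0 - c * (bs - as) * (1.0 - d * bs / 5.0) / 3.0 +
               c * d * as * as / 5.0);
      }
      if (-hk < 100.0) {
        double b = std::sqrt(bs);
        bvn -= std::exp(-hk / 2.0) * std::sqrt(twopi) * phid(-b / a) * b *
               (1.0 - c * bs * (1.0 - d * bs / 5.0) / 3.0);
      }
      a = a / 2.0;
      for (int i = 0; i < lg; i++) {
        for (int is = -1; is <= 1; is += 2) {
          double xs = a * (is * x[i] + 1.0);
          xs = xs * xs;
          double rs = std::sqrt(1.0 - xs);
          double asr2 = -(bs / xs + hk) / 2.0;
          if (asr2 > -100.0) {
            bvn += a * w[i] * std::exp(asr2) *
                   (std::exp(-hk * (1.0 - rs) / (2.0 * (1.0 + rs))) / rs -
                    (1.0 + c * xs * (1.0 + d * xs)));
          }
        }
      }
      bvn = -bvn / twopi;
    }
    if (r > 0.0) {
      bvn += phid(-std::max(h, k));
    } else {
      bvn = -bvn;
      if (k > h) bvn += phid(k) - phid(h);
    }
  }
  if (bvn < 0.0) bvn = 0.0;
  if (bvn > 1.0) bvn = 1.0;
  return bvn;
}

// Joint CDF P(X <= a, Y <= b).
static inline double bvn_cdf(double a, double b, double r) {
  return bvnu(-a, -b, r);
}

//' @noRd
// [[Rcpp::export]]
NumericVector cpp_bvn_cdf(NumericVector a, NumericVector b, NumericVector r) {
  int n = a.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = bvn_cdf(a[i], b[i], r[i]);
  return out;
}

// Cell probabilities of a pair of ordinal items under the latent-Gaussian
// model: thresholds tau1 (length c1-1), tau2 (length c2-1), latent
// correlation rho. Returns a c1 x c2 matrix.
// [[Rcpp::export]]
NumericMatrix cpp_ordinal_cells(NumericVector tau1, NumericVector tau2,
                                double rho) {
  int c1 = tau1.size() + 1, c2 = tau2.size() + 1;
  // cumulative grid including -Inf/+Inf borders
  std::vector<double> t1(c1 + 1), t2(c2 + 1);
  t1[0] = R_NegInf; t1[c1] = R_PosInf;
  for (int i = 0; i < c1 - 1; i++) t1[i + 1] = tau1[i];
  t2[0] = R_NegInf; t2[c2] = R_PosInf;
  for (int j = 0; j < c2 - 1; j++) t2[j + 1] = tau2[j];
  std::vector<double> F((c1 + 1) * (c2 + 1));
  for (int i = 0; i <= c1; i++)
    for (int j = 0; j <= c2; j++)
      F[i * (c2 + 1) + j] = bvn_cdf(t1[i], t2[j], rho);
  NumericMatrix out(c1, c2);
  for (int i = 0; i < c1; i++) {
    for (int j = 0; j < c2; j++) {
      double p = F[(i + 1) * (c2 + 1) + j + 1] - F[i * (c2 + 1) + j + 1] -
                 F[(i + 1) * (c2 + 1) + j] + F[i * (c2 + 1) + j];
      out(i, j) = (p > 0.0) ? p : 0.0;
    }
  }
  return out;
}

// Negative log-likelihood of an observed contingency table under the
// latent-Gaussian model, used by the two-step polychoric estimator.
// [[Rcpp::export]]
double cpp_polychoric_negll(NumericMatrix counts, NumericVector tau1,
                            NumericVector tau2, double rho) {
  NumericMatrix p = cpp_ordinal_cells(tau1, tau2, rho);
  double ll = 0.0;
  for (int i = 0; i < counts.nrow(); i++) {
    for (int j = 0; j < counts.ncol(); j++) {
      if (counts(i, j) > 0) {
        double pij = p(i, j);
        if (pij < 1e-12) pij = 1e-12;
        ll += counts(i, j) * std::log(pij);
      }
    }
  }
  return -ll;
}

// E[X * Y] for a pair of ordinal items with given score vectors.
// [[Rcpp::export]]
double cpp_ordinal_cross_moment(NumericVector tau1, NumericVector tau2,
                                double rho, NumericVector scores1,
                                NumericVector scores2) {
  NumericMatrix p = cpp_ordinal_cells(tau1, tau2, rho);
  double e = 0.0;
  for (int i = 0; i < p.nrow(); i++)
    for (int j = 0; j < p.ncol(); j++)
      e += scores1[i] * scores2[j] * p(i, j);
  return e;
}
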