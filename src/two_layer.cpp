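// Fast kernels for the two-layer CW reflectance: the Hankel-transformed
// surface flux evaluated on a fixed Gauss-Legendre rule, vectorized over
// per-sample absorption coefficients. Same formulas as the R reference
// implementation (two_layer_flux_q); the R version remains the readable
// definition and the oracle in tests.

#include <Rcpp.h>
#include <cmath>

// Full evaluation: reflectance for each sample j with upper/lower absorption
// (mua1[j], mua2[j]). w2pi are the quadrature weights already multiplied by
// q * J0(q rho) / (2 pi).
// [[Rcpp::export(name = ".two_layer_refl_cpp")]]
Rcpp::NumericVector two_layer_refl_cpp(Rcpp::NumericVector q,
                                       Rcpp::NumericVector w2pi,
                                       Rcpp::NumericVector mua1,
                                       double musp1,
                                       Rcpp::NumericVector mua2,
                                       double musp2,
                                       double s, double zb, double z0) {
  const int nq = q.size(), ns = mua1.size();
  if (mua2.size() != ns) Rcpp::stop("mua1/mua2 length mismatch");
  const double D1 = 1.0 / (3.0 * musp1), D2 = 1.0 / (3.0 * musp2);
  Rcpp::NumericVector out(ns);
  std::vector<double> q2(nq);
  for (int i = 0; i < nq; ++i) q2[i] = q[i] * q[i];
  for (int j = 0; j < ns; ++j) {
    const double m1 = mua1[j] / D1, m2 = mua2[j] / D2;
    double acc = 0.0;
    for (int i = 0; i < nq; ++i) {
      const double k1 = std::sqrt(q2[i] + m1);
      const double k2 = std::sqrt(q2[i] + m2);
      const double a1 = D1 * k1, a2 = D2 * k2;
      const double E1 = std::exp(-2.0 * k1 * (s + zb));
      const double E2 = std::exp(-2.0 * k1 * (s - z0));
      const double pre = std::cosh(k1 * zb) * std::exp(-k1 * (z0 + zb));
      const double num = a1 * (1.0 + E2) + a2 * (1.0 - E2);
      const double den = a1 * (1.0 + E1) + a2 * (1.0 - E1);
      acc += w2pi[i] * pre * num / den;
    }
    out[j] = acc;
  }
  return out;
}

// Setup for repeated evaluations with fixed upper layer: precomputes all
// k1-dependent factors per (node, sample).
// [[Rcpp::export(name = ".two_layer_setup_cpp")]]
Rcpp::List two_layer_setup_cpp(Rcpp::NumericVector q,
                               Rcpp::NumericVector mua1,
                               double musp1,
                               double s, double zb, double z0) {
  const int nq = q.size(), ns = mua1.size();
  const double D1 = 1.0 / (3.0 * musp1);
  Rcpp::NumericMatrix N1(nq, ns), N2(nq, ns), Dd1(nq, ns), Dd2(nq, ns);
  for (int j = 0; j < ns; ++j) {
    const double m1 = mua1[j] / D1;
    for (int i = 0; i < nq; ++i) {
      const double k1 = std::sqrt(q[i] * q[i] + m1);
      const double a1 = D1 * k1;
      const double E1 = std::exp(-2.0 * k1 * (s + zb));
      const double E2 = std::exp(-2.0 * k1 * (s - z0));
      const double pre = std::cosh(k1 * zb) * std::exp(-k1 * (z0 + zb));
      N1(i, j) = pre * a1 * (1.0 + E2);
      N2(i, j) = pre * (1.0 - E2);
      Dd1(i, j) = a1 * (1.0 + E1);
      Dd2(i, j) = 1.0 - E1;
    }
  }
  return Rcpp::List::create(Rcpp::Named("N1") = N1, Rcpp::Named("N2") = N2,
                            Rcpp::Named("D1") = Dd1, Rcpp::Named("D2") = Dd2);
}

// Evaluation against a setup: only the lower-layer absorption varies.
// [[Rcpp::export(name = ".two_layer_eval_cpp")]]
Rcpp::NumericVector two_layer_eval_cpp(Rcpp::List setup,
                                       Rcpp::NumericVector q,
                                       Rcpp::NumericVector w2pi,
                                       Rcpp::NumericVector mua2,
                                       double musp2) {
  Rcpp::NumericMatrix N1 = setup["N1"], N2 = setup["N2"],
                      Dd1 = setup["D1"], Dd2 = setup["D2"];
  const int nq = q.size(), ns = mua2.size();
  if (N1.ncol() != ns) Rcpp::stop("setup/sample count mismatch");
  const double D2 = 1.0 / (3.0 * musp2);
  Rcpp::NumericVector out(ns);
  std::vector<double> q2(nq);
  for (int i = 0; i < nq; ++i) q2[i] = q[i] * q[i];
  for (int j = 0; j < ns; ++j) {
    const double m2 = mua2[j] / D2;
    double acc = 0.0;
    const double *n1 = &N1(0, j), *n2 = &N2(0, j);
    const double *d1 = &Dd1(0, j), *d2 = &Dd2(0, j);
    for (int i = 0; i < nq; ++i) {
      const double a2 = D2 * std::sqrt(q2[i] + m2);
      acc += w2pi[i] * (n1[i] + a2 * n2[i]) / (d1[i] + a2 * d2[i]);
    }
    out[j] = acc;
  }
  return out;
}
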