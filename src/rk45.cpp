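#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Dormand-Prince 5(4) pair, FSAL.
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
                    a64 = 49.0 / 176, a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
// embedded 4th-order weights
static const double e1 = 5179.0 / 57600, e3 = 7571.0 / 16695, e4 = 393.0 / 640,
                    e5 = -92097.0 / 339200, e6 = 187.0 / 2100, e7 = 1.0 / 40;

// RHS of dx/dt = N f(x), flux_j = coef_j * prod_k x_k^expo(j,k)
// expo holds small nonnegative integer exponents (mass-action orders).
static inline void rhs(const double* x, const double* coef,
                       const int* expo, const double* stoich,
                       int ns, int nf, double* flux, double* dx) {
  for (int j = 0; j < nf; ++j) {
    double v = coef[j];
    const int* ej = expo + (size_t)j * ns;
    for (int k = 0; k < ns; ++k) {
      int e = ej[k];
      while (e-- > 0) v *= x[k];
    }
    flux[j] = v;
  }
  for (int k = 0; k < ns; ++k) {
    double s = 0.0;
    const double* nk = stoich + (size_t)k * nf; // row k stored contiguously
    for (int j = 0; j < nf; ++j) s += nk[j] * flux[j];
    dx[k] = s;
  }
}

// [[Rcpp::export(name = ".rk45_mass_action")]]
List rk45_mass_action(NumericVector x0, NumericVector t_eval,
                      NumericMatrix stoich_t, NumericVector coef,
                      IntegerMatrix expo_t, double atol, double rtol,
                      double hmax_frac = 0.1) {
  const int ns = x0.size();
  const int nf = coef.size();
  const int nt = t_eval.size();
  // stoich_t: nf x ns (transposed stoichiometry) so row k of N is column k
  // expo_t:   ns x nf so exponents of flux j are column j
  std::vector<double> stoich((size_t)ns * nf);
  for (int k = 0; k < ns; ++k)
    for (int j = 0; j < nf; ++j) stoich[(size_t)k * nf + j] = stoich_t(j, k);
  std::vector<int> expo((size_t)nf * ns);
  for (int j = 0; j < nf; ++j)
    for (int k = 0; k < ns; ++k) expo[(size_t)j * ns + k] = expo_t(k, j);

  NumericMatrix out(nt, ns);
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> k1(ns), k2(ns), k3(ns), k4(ns), k5(ns), k6(ns), k7(ns),
      xt(ns), x5(ns), flux(nf);
  for (int k = 0; k < ns; ++k) out(0, k) = x[k];

  double t = t_eval[0];
  const double t_end = t_eval[nt - 1];
  const double span = t_end - t;
  bool ok = true;
  double t_fail = NA_REAL;
  int i_fail = NA_INTEGER;
  long n_steps = 0;

  if (nt == 1 || span <= 0.0) {
    if (span < 0.0) stop("t_eval must be non-decreasing");
  }

  rhs(x.data(), coef.begin(), expo.data(), stoich.data(), ns, nf, flux.data(),
      k1.data());
  double h = span * 0.01;
  if (h <= 0.0) h = 1e-8;
  const double hmax = span * hmax_frac > 0 ? span * hmax_frac : 1e-8;
  if (h > hmax) h = hmax;
  const double hmin = std::max(span, 1.0) * 1e-14;
  int next_out = 1;

  while (next_out < nt && ok) {
    // emit any output point we are already standing on (incl. duplicates)
    while (next_out < nt &&
           t_eval[next_out] - t <= 1e-12 * std::max(1.0, std::fabs(t))) {
      for (int k = 0; k < ns; ++k) out(next_out, k) = x[k];
      ++next_out;
    }
    if (next_out >= nt) break;
    // clip the step so we land exactly on the next requested output point
    if (t + h > t_eval[next_out]) h = t_eval[next_out] - t;
    // stages
    for (int k = 0; k < ns; ++k) xt[k] = x[k] + h * a21 * k1[k];
    rhs(xt.data(), coef.begin(), expo.data(), stoich.data(), ns, nf,
        flux.data(), k2.data());
    for (int k = 0; k < ns; ++k)
      xt[k] = x[k] + h * (a31 * k1[k] + a32 * k2[k]);
    rhs(xt.data(), coef.begin(), expo.data(), stoich.data(), ns, nf,
        flux.data(), k3.data());
    for (int k = 0; k < ns; ++k)
      xt[k] = x[k] + h * (a41 * k1[k] + a42 * k2[k] + a43 * k3[k]);
    rhs(xt.data(), coef.begin(), expo.data(), stoich.data(), ns, nf,
        flux.data(), k4.data());
    for (int k = 0; k < ns; ++k)
      xt[k] = x[k] + h * (a51 * k1[k] + a52 * k2[k] + a53 * k3[k] + a54 * k4[k]);
    rhs(xt.data(), coef.begin(), expo.data(), stoich.data(), ns, nf,
        flux.data(), k5.data());
    for (int k = 0; k < ns; ++k)
      xt[k] = x[k] + h * (a61 * k1[k] + a62 * k2[k] + a63 * k3[k] +
                          a64 * k4[k] + a65 * k5[k]);
    rhs(xt.data(), coef.begin(), expo.data(), stoich.data(), ns, nf,
        flux.data(), k6.data());
    for (int k = 0; k < ns; ++k)
      x5[k] = x[k] + h * (b1 * k1[k] + b3 * k3[k] + b4 * k4[k] + b5 * k5[k] +
                          b6 * k6[k]);
    rhs(x5.data(), coef.begin(), expo.data(), stoich.data(), ns, nf,
        flux.data(), k7.data());

    // error estimate (5th vs embedded 4th)
    double err = 0.0;
    bool finite = true;
    for (int k = 0; k < ns; ++k) {
      double x4 = x[k] + h * (e1 * k1[k] + e3 * k3[k] + e4 * k4[k] +
                              e5 * k5[k] + e6 * k6[k] + e7 * k7[k]);
      double sc = atol + rtol * std::max(std::fabs(x[k]), std::fabs(x5[k]));
      double d = (x5[k] - x4) / sc;
      err += d * d;
      if (!std::isfinite(x5[k])) {
        finite = false;
        if (i_fail == NA_INTEGER) i_fail = k + 1;
      }
    }
    err = std::sqrt(err / ns);

    if (!finite) {
      // retry with a smaller step; give up at hmin
      h *= 0.25;
      if (h < hmin) {
        ok = false;
        t_fail = t;
      }
      continue;
    }

    if (err <= 1.0) { // accept
      double t_new = t + h;
      if (std::fabs(t_eval[next_out] - t_new) <=
          1e-9 * std::max(1.0, std::fabs(t_new))) {
        for (int k = 0; k < ns; ++k) out(next_out, k) = x5[k];
        ++next_out;
      }
      t = t_new;
      std::swap(x, x5);
      std::swap(k1, k7); // FSAL
      ++n_steps;
      if (n_steps > 2000000) {
        ok = false;
        t_fail = t;
        break;
      }
      double fac = 0.9 * std::pow(std::max(err, 1e-10), -0.2);
      if (fac > 5.0) fac = 5.0;
      h *= fac;
      if (h > hmax) h = hmax;
      if (h < hmin) h = hmin;
    } else { // reject
      double fac = std::max(0.9 * std::pow(err, -0.2), 0.2);
      h *= fac;
      if (h < hmin) {
        ok = false;
        t_fail = t;
        for (int k = 0; k < ns; ++k)
          if (!std::isfinite(x[k])) { i_fail = k + 1; break; }
      }
    }
  }

  return List::create(_["states"] = out, _["ok"] = ok, _["t_fail"] = t_fail,
                      _["state_fail"] = i_fail, _["n_steps"] = (double)n_steps);
}
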