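#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Direct-form II transposed IIR pass with supplied initial state.
// a[0] is assumed to be 1 (coefficients normalized on the R side).
// The state is held in a fixed-size register array, specialized for the
// common filter orders, so the serial recurrence stays in registers.
template <int NT>
static void iir_pass_fixed(const double* b, const double* a,
                           std::vector<double>& x, const double* zi) {
  double z[NT - 1];
  for (int i = 0; i < NT - 1; ++i) z[i] = zi[i];
  const int n = static_cast<int>(x.size());
  for (int k = 0; k < n; ++k) {
    const double xk = x[k];
    const double yk = b[0] * xk + z[0];
    for (int i = 0; i < NT - 2; ++i)
      z[i] = b[i + 1] * xk + z[i + 1] - a[i + 1] * yk;
    z[NT - 2] = b[NT - 1] * xk - a[NT - 1] * yk;
    x[k] = yk;
  }
}

static void iir_pass_generic(const std::vector<double>& b,
                             const std::vector<double>& a,
                             std::vector<double>& x,
                             std::vector<double> z) {
  const int nt = static_cast<int>(b.size());
  const int n = static_cast<int>(x.size());
  for (int k = 0; k < n; ++k) {
    const double xk = x[k];
    const double yk = b[0] * xk + z[0];
    for (int i = 0; i < nt - 2; ++i)
      z[i] = b[i + 1] * xk + z[i + 1] - a[i + 1] * yk;
    z[nt - 2] = b[nt - 1] * xk - a[nt - 1] * yk;
    x[k] = yk;
  }
}

static void iir_pass(const std::vector<double>& b, const std::vector<double>& a,
                     std::vector<double>& x, const std::vector<double>& z) {
  switch (b.size()) {
  case 3: iir_pass_fixed<3>(b.data(), a.data(), x, z.data()); break;
  case 5: iir_pass_fixed<5>(b.data(), a.data(), x, z.data()); break;
  case 9: iir_pass_fixed<9>(b.data(), a.data(), x, z.data()); break;
  default: iir_pass_generic(b, a, x, z);
  }
}

// Steady-state filter state for a constant input of 1 (so that a constant
// input x0 with state x0*zi yields a constant output g*x0, g the DC gain).
static std::vector<double> step_state(const std::vector<double>& b,
                                      const std::vector<double>& a) {
  const int nt = static_cast<int>(b.size());
  double sb = 0.0, sa = 0.0;
  for (int i = 0; i < nt; ++i) { sb += b[i]; sa += a[i]; }
  const double g = sb / sa;
  std::vector<double> z(nt - 1, 0.0);
  double acc = 0.0;
  for (int i = nt - 2; i >= 0; --i) {
    acc += b[i + 1] - g * a[i + 1];
    z[i] = acc;
  }
  return z;
}

// Zero-phase (forward-backward) IIR filtering of each column of x, with
// odd-reflection edge padding of length 3*(ntaps-1), matching the usual
// filtfilt edge treatment.
// [[Rcpp::export(name = ".filtfiltMat")]]
NumericMatrix filtfilt_mat(NumericVector b, NumericVector a, NumericMatrix x) {
  const int nt = b.size();
  if (a.size() != b.size()) stop("b and a must have equal length");
  if (nt < 2) stop("need at least a first-order filter");
  std::vector<double> bv(b.begin(), b.end()), av(a.begin(), a.end());
  const int n = x.nrow(), nc = x.ncol();
  const int npad = std::min(3 * (nt - 1), n - 1);
  if (n <= npad) stop("signal too short for the requested filter");
  const std::vector<double> zi = step_state(bv, av);
  NumericMatrix out(n, nc);
  const int m = n + 2 * npad;
  std::vector<double> w(m);
  for (int j = 0; j < nc; ++j) {
    for (int k = 0; k < npad; ++k)
      w[k] = 2.0 * x(0, j) - x(npad - k, j);
    for (int k = 0; k < n; ++k) w[npad + k] = x(k, j);
    for (int k = 0; k < npad; ++k)
      w[npad + n + k] = 2.0 * x(n - 1, j) - x(n - 2 - k, j);

    std::vector<double> z0(zi);
    for (size_t i = 0; i < z0.size(); ++i) z0[i] *= w[0];
    iir_pass(bv, av, w, z0);
    std::reverse(w.begin(), w.end());
    std::vector<double> z1(zi);
    for (size_t i = 0; i < z1.size(); ++i) z1[i] *= w[0];
    iir_pass(bv, av, w, z1);
    std::reverse(w.begin(), w.end());
    for (int k = 0; k < n; ++k) out(k, j) = w[npad + k];
  }
  return out;
}
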