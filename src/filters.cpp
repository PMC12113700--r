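#include <Rcpp.h>
using namespace Rcpp;

static inline void run_sos(const double* sos, int ns, double* y, R_xlen_t n,
                           bool reverse) {
  for (int s = 0; s < ns; ++s) {
    const double b0 = sos[s], b1 = sos[s + ns], b2 = sos[s + 2 * ns];
    const double a1 = sos[s + 4 * ns], a2 = sos[s + 5 * ns];
    double z1 = 0.0, z2 = 0.0;
    if (!reverse) {
      for (R_xlen_t i = 0; i < n; ++i) {
        const double xi = y[i];
        const double yi = b0 * xi + z1;
        z1 = b1 * xi - a1 * yi + z2;
        z2 = b2 * xi - a2 * yi;
        y[i] = yi;
      }
    } else {
      for (R_xlen_t i = n - 1; i >= 0; --i) {
        const double xi = y[i];
        const double yi = b0 * xi + z1;
        z1 = b1 * xi - a1 * yi + z2;
        z2 = b2 * xi - a2 * yi;
        y[i] = yi;
      }
    }
  }
}

// Cascade of biquad sections, direct form II transposed, zero initial state.
// sos: n_sections x 6 matrix, rows (b0, b1, b2, a0, a1, a2) with a0 == 1.
// [[Rcpp::export]]
NumericVector sosfilt_cpp(NumericMatrix sos, NumericVector x) {
  NumericVector y = clone(x);
  run_sos(REAL(sos), sos.nrow(), REAL(y), y.size(), false);
  return y;
}

// Forward-backward (zero-phase) cascade application in one pass, avoiding
// the reversal copies a pure-R filtfilt would need.
// [[Rcpp::export]]
NumericVector sosfiltfilt_cpp(NumericMatrix sos, NumericVector x) {
  NumericVector y = clone(x);
  run_sos(REAL(sos), sos.nrow(), REAL(y), y.size(), false);
  run_sos(REAL(sos), sos.nrow(), REAL(y), y.size(), true);
  return y;
}

// Longest run of samples clipped at +rail or -rail (exact equality).
// [[Rcpp::export]]
int max_clip_run_cpp(NumericVector x, double rail) {
  int best = 0, run = 0;
  const R_xlen_t n = x.size();
  const double* p = REAL(x);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (p[i] == rail || p[i] == -rail) {
      ++run;
      if (run > best) best = run;
    } else {
      run = 0;
    }
  }
  return best;
}
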