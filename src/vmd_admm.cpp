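#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// ADMM core of the variational mode decomposition, operating on the
// positive-frequency half of the mirrored spectrum.  fp: analytic spectrum
// (positive half), fr: normalized frequencies of those bins, omega0:
// initial center frequencies.  Returns the converged mode spectra and
// center frequencies.  Real/imaginary parts are carried in plain double
// arrays; the Wiener-filter denominator is real, so each update is a
// handful of multiplies per bin.
// [[Rcpp::export]]
List vmd_admm(ComplexVector fp, NumericVector fr, NumericVector omega0,
              double alpha, double tau, double tol, int max_iter,
              bool dc_mode) {
  const int n = fp.size();
  const int K = omega0.size();
  std::vector<double> fre(n), fim(n), lre(n, 0.0), lim(n, 0.0);
  std::vector<double> sre(n, 0.0), sim(n, 0.0);       // running sum of modes
  for (int i = 0; i < n; ++i) { fre[i] = fp[i].r; fim[i] = fp[i].i; }
  std::vector<std::vector<double>> ure(K, std::vector<double>(n, 0.0));
  std::vector<std::vector<double>> uim(K, std::vector<double>(n, 0.0));
  std::vector<double> omega(omega0.begin(), omega0.end());
  const double* frp = REAL(fr);
  bool converged = false;
  int it = 0;
  while (it < max_iter) {
    ++it;
    double num = 0.0, den = 0.0;
    for (int k = 0; k < K; ++k) {
      double* ur = ure[k].data();
      double* ui = uim[k].data();
      double wnum = 0.0, wden = 0.0;
      const double om = omega[k];
      for (int i = 0; i < n; ++i) {
        const double sr = sre[i] - ur[i];
        const double si = sim[i] - ui[i];
        const double d = frp[i] - om;
        const double inv = 1.0 / (1.0 + alpha * d * d);
        const double nr = (fre[i] - sr - 0.5 * lre[i]) * inv;
        const double ni = (fim[i] - si - 0.5 * lim[i]) * inv;
        const double dr = nr - ur[i], di = ni - ui[i];
        num += dr * dr + di * di;
        den += ur[i] * ur[i] + ui[i] * ui[i];
        sre[i] = sr + nr; sim[i] = si + ni;
        ur[i] = nr; ui[i] = ni;
        const double w = nr * nr + ni * ni;
        wnum += frp[i] * w;
        wden += w;
      }
      if (!(dc_mode && k == 0) && wden > 0.0) omega[k] = wnum / wden;
    }
    if (tau > 0.0)
      for (int i = 0; i < n; ++i) {
        lre[i] += tau * (sre[i] - fre[i]);
        lim[i] += tau * (sim[i] - fim[i]);
      }
    if (den > 0.0 && num / den < tol) { converged = true; break; }
  }
  ComplexMatrix U(n, K);
  for (int k = 0; k < K; ++k)
    for (int i = 0; i < n; ++i) {
      U(i, k).r = ure[k][i];
      U(i, k).i = uim[k][i];
    }
  return List::create(_["u"] = U,
                      _["omega"] = NumericVector(omega.begin(), omega.end()),
                      _["iterations"] = it, _["converged"] = converged);
}
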