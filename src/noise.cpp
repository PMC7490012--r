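// Frequency-domain assembly for the 1/f noise generator: fills a Hermitian
// complex spectrum (two independent real series packed per column) using
// R's RNG, with no intermediate allocations.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// amp: length half-1 spectral amplitudes for bins 1..half-1.
// Returns nfft x n_pair complex matrix ready for an inverse FFT; the real
// and imaginary parts of each output column are two independent real
// 1/f series.
// [[Rcpp::export]]
arma::cx_mat cpp_noise_spectrum(int nfft, const arma::vec& amp, int n_pair) {
  const int half = nfft / 2;
  if ((int)amp.n_elem != half - 1) stop("amp must have nfft/2 - 1 entries");
  arma::cx_mat Z(nfft, n_pair, arma::fill::zeros);
  for (int j = 0; j < n_pair; ++j) {
    for (int k = 1; k < half; ++k) {
      const double a = amp(k - 1);
      const double re1 = norm_rand() * a, im1 = norm_rand() * a;
      const double re2 = norm_rand() * a, im2 = norm_rand() * a;
      // z1 + i z2 at bin k; conj(z1) + i conj(z2) mirrored at nfft - k
      Z(k, j) = arma::cx_double(re1 - im2, im1 + re2);
      Z(nfft - k, j) = arma::cx_double(re1 + im2, re2 - im1);
    }
  }
  return Z;
}
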