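// FFT convolution engine for the Gabor jet maps.
//
// Computes, for one real-valued channel raster, the complex cross-
// correlation with every kernel of the bank at a requested set of pixels.
// Kernel spectra arrive pre-conjugated and padded from R (cached there);
// the image is zero-padded to P x P, transformed once, and each kernel
// product inverse-transformed. Done in C++ because the per-kernel complex
// elementwise products and inverse transforms dominate the pipeline's
// runtime and R-level complex arithmetic allocates heavily.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
List gabor_conv_cpp(const arma::mat& channel, const List& kernel_ffts,
                    const arma::uvec& pix_iy, const arma::uvec& pix_ix,
                    const int P) {
  const arma::uword n = channel.n_rows;
  const arma::uword np = pix_iy.n_elem;
  const arma::uword nk = kernel_ffts.size();

  arma::cx_mat pad(P, P, arma::fill::zeros);
  pad.submat(0, 0, n - 1, n - 1) =
      arma::cx_mat(channel, arma::mat(n, n, arma::fill::zeros));
  arma::cx_mat F = arma::fft2(pad);

  arma::uvec lin(np);
  for (arma::uword p = 0; p < np; ++p) lin[p] = pix_iy[p] + pix_ix[p] * P;

  arma::mat out_re(np, nk), out_im(np, nk);
  arma::cx_mat prod(P, P), cc(P, P);
  for (arma::uword j = 0; j < nk; ++j) {
    arma::cx_mat K = as<arma::cx_mat>(kernel_ffts[j]);
    prod = F % K;
    cc = arma::ifft2(prod);
    const std::complex<double>* cm = cc.memptr();
    double* orp = out_re.colptr(j);
    double* oip = out_im.colptr(j);
    for (arma::uword p = 0; p < np; ++p) {
      orp[p] = cm[lin[p]].real();
      oip[p] = cm[lin[p]].imag();
    }
  }
  return List::create(Named("re") = out_re, Named("im") = out_im);
}
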