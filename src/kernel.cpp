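// RBF kernel blocks in single precision: the Gram matrix of the SVM grid
// search is the largest dense computation in the pipeline, and float gemm
// runs about twice as fast as double while the kernel entries only need a
// few significant digits for SMO.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
arma::mat rbf_kernel_cpp(const arma::mat& A, const arma::mat& B,
                         double gamma) {
  fmat Af = conv_to<fmat>::from(A);
  fmat Bf = conv_to<fmat>::from(B);
  fvec an = sum(square(Af), 1);
  fvec bn = sum(square(Bf), 1);
  fmat D = Af * Bf.t();
  D *= -2.0f;
  D.each_col() += an;
  D.each_row() += bn.t();
  D.transform([gamma](float v) {
    return std::exp(-(float)gamma * (v > 0.0f ? v : 0.0f));
  });
  return conv_to<mat>::from(D);
}
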