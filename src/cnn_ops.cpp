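// Valid 1-D convolution forward/backward for the pulse CNN.
//
// Batch activations are (batch*length x channels) column-major matrices,
// sample blocks stacked along the rows; weights are (kernel*channels x
// filters) with kernel-tap-major rows. A shifted sample block is then a
// strided submatrix of the activation matrix, so the convolution is a sum
// over kernel taps of plain dgemm calls on views — no im2col buffers.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif

using Rcpp::NumericMatrix;
using Rcpp::NumericVector;

static const double one = 1.0;

// [[Rcpp::export]]
NumericMatrix cpp_conv_forward(const NumericMatrix& A, const NumericMatrix& W,
                               const NumericVector& bias, int B, int L, int K) {
  const int C = A.ncol();
  const int F = W.ncol();
  const int Lout = L - K + 1;
  const int ldA = A.nrow();   // B * L
  const int ldW = W.nrow();   // K * C
  const int ldZ = B * Lout;

  NumericMatrix Z(ldZ, F);
  double* z = Z.begin();
  for (int f = 0; f < F; ++f)
    for (int r = 0; r < ldZ; ++r) z[f * ldZ + r] = bias[f];

  const double* a = A.begin();
  const double* w = W.begin();
  for (int b = 0; b < B; ++b) {
    for (int k = 0; k < K; ++k) {
      F77_CALL(dgemm)("N", "N", &Lout, &F, &C, &one,
                      a + b * L + k, &ldA,
                      w + k * C, &ldW, &one,
                      z + b * Lout, &ldZ FCONE FCONE);
    }
  }
  return Z;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv_backward(const NumericMatrix& A, const NumericMatrix& dZ,
                             const NumericMatrix& W, int B, int L, int K,
                             bool need_dA) {
  const int C = A.ncol();
  const int F = W.ncol();
  const int Lout = L - K + 1;
  const int ldA = A.nrow();
  const int ldW = W.nrow();
  const int ldZ = dZ.nrow();  // B * Lout

  NumericMatrix dW(K * C, F);
  NumericVector db(F);
  NumericMatrix dA(need_dA ? ldA : 1, need_dA ? C : 1);

  const double* a = A.begin();
  const double* w = W.begin();
  const double* dz = dZ.begin();
  double* dw = dW.begin();
  double* da = dA.begin();

  for (int f = 0; f < F; ++f) {
    double s = 0.0;
    const double* col = dz + f * ldZ;
    for (int r = 0; r < ldZ; ++r) s += col[r];
    db[f] = s;
  }

  for (int b = 0; b < B; ++b) {
    for (int k = 0; k < K; ++k) {
      // dW_k += A_(b,k)^T dZ_b
      F77_CALL(dgemm)("T", "N", &C, &F, &Lout, &one,
                      a + b * L + k, &ldA,
                      dz + b * Lout, &ldZ, &one,
                      dw + k * C, &ldW FCONE FCONE);
      if (need_dA) {
        // dA_(b,k) += dZ_b W_k^T  (overlapping strided blocks, sequential)
        F77_CALL(dgemm)("N", "T", &Lout, &C, &F, &one,
                        dz + b * Lout, &ldZ,
                        w + k * C, &ldW, &one,
                        da + b * L + k, &ldA FCONE FCONE);
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dW") = dW, Rcpp::Named("db") = db,
                            Rcpp::Named("dA") = dA);
}
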