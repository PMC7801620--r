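// Dilated 1-D convolution kernels for the batched [N, L, C] layout.
//
// For a full column range of every channel slice, the operand
// "samples (n, t+off) x channels c" is already a valid column-major
// matrix inside the input cube: columns (channels) are N*L apart and
// each column's N*Tout entries are contiguous. Each kernel tap is
// therefore one BLAS dgemm with a strided leading dimension -- no
// im2col materialization and no copies. The R-level straight-loop
// oracle in the test suite is the correctness reference.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <R_ext/BLAS.h>

#ifndef FCONE
# define FCONE
#endif

using namespace arma;

// X: cube [N, L, Cin]; W: cube [k, Cin, F]; valid convolution with the
// given dilation. Returns pre-activation cube [N, Tout, F].
// [[Rcpp::export(name = ".conv_forward")]]
arma::cube conv_forward(const arma::cube& X, const arma::cube& W,
                        const int dilation) {
  const uword N = X.n_rows, L = X.n_cols, Cin = X.n_slices;
  const uword k = W.n_rows, F = W.n_slices;
  const uword span = (k - 1) * dilation;
  if (L <= span) Rcpp::stop("input shorter than the kernel span");
  if (W.n_cols != Cin) Rcpp::stop("channel mismatch");
  const uword Tout = L - span;
  cube Z(N, Tout, F, fill::zeros);

  const int M = (int)(N * Tout);      // rows of the tap operand
  const int Kc = (int)Cin;            // inner dimension
  const int Fn = (int)F;
  const int lda = (int)(N * L);       // channel stride inside X
  const double one = 1.0;
  // Per-tap weight matrix Wj [Cin x F]: Wj(c, f) = W(j, c, f).
  mat Wj(Cin, F);
  for (uword j = 0; j < k; ++j) {
    for (uword f = 0; f < F; ++f)
      for (uword c = 0; c < Cin; ++c) Wj(c, f) = W(j, c, f);
    const double* A = X.memptr() + (uword)(j * dilation) * N;
    F77_CALL(dgemm)("N", "N", &M, &Fn, &Kc, &one, A, &lda,
                    Wj.memptr(), &Kc, &one, Z.memptr(), &M
                    FCONE FCONE);
  }
  return Z;
}

// Gradients of the same convolution. X is the layer input, dZ the
// upstream gradient (already multiplied by the activation derivative).
// Returns the kernel gradient and, when need_dx, the input gradient.
// [[Rcpp::export(name = ".conv_backward")]]
Rcpp::List conv_backward(const arma::cube& X, const arma::cube& W,
                         const arma::cube& dZ, const int dilation,
                         const bool need_dx) {
  const uword N = X.n_rows, L = X.n_cols, Cin = X.n_slices;
  const uword k = W.n_rows, F = W.n_slices;
  const uword Tout = dZ.n_cols;
  cube gW(k, Cin, F, fill::zeros);
  cube dX;
  if (need_dx) dX.zeros(N, L, Cin);

  const int M = (int)(N * Tout);
  const int Kc = (int)Cin;
  const int Fn = (int)F;
  const int lda = (int)(N * L);
  const double one = 1.0, zero = 0.0;
  mat Gj(Cin, F);
  mat Wj(Cin, F);
  for (uword j = 0; j < k; ++j) {
    const uword off = (uword)(j * dilation) * N;
    // gW_j [Cin x F] = A_j^T (M x Cin) * dZ (M x F)
    F77_CALL(dgemm)("T", "N", &Kc, &Fn, &M, &one, X.memptr() + off, &lda,
                    dZ.memptr(), &M, &zero, Gj.memptr(), &Kc
                    FCONE FCONE);
    for (uword f = 0; f < F; ++f)
      for (uword c = 0; c < Cin; ++c) gW(j, c, f) = Gj(c, f);
    if (need_dx) {
      for (uword f = 0; f < F; ++f)
        for (uword c = 0; c < Cin; ++c) Wj(c, f) = W(j, c, f);
      // dX_j (M x Cin, strided) += dZ (M x F) * Wj^T (F x Cin)
      F77_CALL(dgemm)("N", "T", &M, &Kc, &Fn, &one, dZ.memptr(), &M,
                      Wj.memptr(), &Kc, &one, dX.memptr() + off, &lda
                      FCONE FCONE);
    }
  }
  if (need_dx) {
    return Rcpp::List::create(Rcpp::Named("gW") = gW,
                              Rcpp::Named("dX") = dX);
  }
  return Rcpp::List::create(Rcpp::Named("gW") = gW);
}

// Elementwise ReLU. Keeping these in compiled code avoids repeated
// full-size logical temporaries in the training loop.
// [[Rcpp::export(name = ".relu_fwd")]]
arma::cube relu_fwd(const arma::cube& Z) {
  cube H = Z;
  double* p = H.memptr();
  const uword n = H.n_elem;
  for (uword i = 0; i < n; ++i) if (p[i] < 0.0) p[i] = 0.0;
  return H;
}

// dZ = dH * (pre > 0), elementwise.
// [[Rcpp::export(name = ".relu_bwd")]]
arma::cube relu_bwd(const arma::cube& dH, const arma::cube& pre) {
  cube dZ = dH;
  double* p = dZ.memptr();
  const double* q = pre.memptr();
  const uword n = dZ.n_elem;
  for (uword i = 0; i < n; ++i) if (q[i] <= 0.0) p[i] = 0.0;
  return dZ;
}

// Backward of temporal global average pooling: spread dpooled [N, F]
// uniformly over the T time positions, scaled by 1/T.
// [[Rcpp::export(name = ".gap_bwd")]]
arma::cube gap_bwd(const arma::mat& dpooled, const int T) {
  const uword N = dpooled.n_rows, F = dpooled.n_cols;
  cube dH(N, (uword)T, F);
  for (uword f = 0; f < F; ++f) {
    double* s = dH.slice_memptr(f);
    for (uword t = 0; t < (uword)T; ++t) {
      for (uword n = 0; n < N; ++n) {
        s[t * N + n] = dpooled(n, f) / (double)T;
      }
    }
  }
  return dH;
}
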