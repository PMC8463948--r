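// 1-D convolution over batched multi-channel segments.
//
// Layout: a batch of `nseg` segments, each `C_in` channels by `L` samples,
// is stored as a C_in x (L * nseg) matrix (segments concatenated along
// columns).  Weights are C_out x (C_in * k) with the channel index fastest
// within each kernel tap.  Padding is "same" for the given stride:
// Lout = ceil(L / stride).
//
// Stride-1 convolutions (the majority) avoid im2col entirely: because the
// per-segment "same" padding totals exactly k - 1 columns, a kernel window
// anchored anywhere in the padded batch never mixes samples of two
// segments, so each kernel tap contributes one GEMM on a contiguous view
// of the padded batch.  Strided convolutions use an im2col buffer whose
// columns are single memcpys (taps address adjacent padded columns).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void same_pad(int L, int k, int stride, int& Lout, int& pad_left,
                     int& pad_total) {
  Lout = (L + stride - 1) / stride;
  pad_total = (Lout - 1) * stride + k - L;
  if (pad_total < 0) pad_total = 0;
  pad_left = pad_total / 2;
}

static uvec tap_base(int nseg, int Lout, int stride, int Lp) {
  uvec base((size_t)Lout * nseg);
  size_t c = 0;
  for (int s = 0; s < nseg; ++s) {
    const size_t off = (size_t)s * Lp;
    for (int t = 0; t < Lout; ++t) base(c++) = off + (size_t)t * stride;
  }
  return base;
}

static mat pad_batch(const mat& X, int L, int nseg, int pad_left,
                     int pad_total) {
  const int Lp = L + pad_total;
  mat Xpad(X.n_rows, (size_t)Lp * nseg, fill::zeros);
  if (pad_total == 0) { Xpad = X; return Xpad; }
  for (int s = 0; s < nseg; ++s) {
    Xpad.cols((size_t)s * Lp + pad_left, (size_t)s * Lp + pad_left + L - 1) =
      X.cols((size_t)s * L, (size_t)s * L + L - 1);
  }
  return Xpad;
}

static mat im2col(const mat& Xpad, const uvec& base, int C, int k) {
  mat Xcol(C * k, base.n_elem);
  for (size_t c = 0; c < base.n_elem; ++c) {
    std::memcpy(Xcol.colptr(c), Xpad.colptr(base(c)),
                sizeof(double) * C * k);
  }
  return Xcol;
}

// valid (non-boundary) output columns of a stride-1 full sweep live at
// s * Lp + t, t = 0..Lout-1
static mat extract_valid(const mat& Yfull, int nseg, int Lout, int Lp) {
  mat Y(Yfull.n_rows, (size_t)Lout * nseg);
  for (int s = 0; s < nseg; ++s) {
    Y.cols((size_t)s * Lout, (size_t)s * Lout + Lout - 1) =
      Yfull.cols((size_t)s * Lp, (size_t)s * Lp + Lout - 1);
  }
  return Y;
}

static mat scatter_valid(const mat& Y, int nseg, int Lout, int Lp,
                         int n_rows, size_t full_cols) {
  mat Yfull(n_rows, full_cols, fill::zeros);
  for (int s = 0; s < nseg; ++s) {
    Yfull.cols((size_t)s * Lp, (size_t)s * Lp + Lout - 1) =
      Y.cols((size_t)s * Lout, (size_t)s * Lout + Lout - 1);
  }
  return Yfull;
}

// [[Rcpp::export]]
arma::mat conv1d_fwd(const arma::mat& X, const arma::mat& W,
                     const arma::vec& bias, int L, int nseg,
                     int k, int stride) {
  int Lout, pad_left, pad_total;
  same_pad(L, k, stride, Lout, pad_left, pad_total);
  const int C = X.n_rows;
  const int Lp = L + pad_total;
  mat Xpad = pad_batch(X, L, nseg, pad_left, pad_total);
  mat Y;
  if (stride == 1) {
    const size_t nfull = Xpad.n_cols - (k - 1);
    mat Yfull(W.n_rows, nfull, fill::zeros);
    for (int j = 0; j < k; ++j) {
      Yfull += W.cols(j * C, (j + 1) * C - 1) *
               Xpad.cols(j, j + nfull - 1);
    }
    Y = extract_valid(Yfull, nseg, Lout, Lp);
  } else {
    mat Xcol = im2col(Xpad, tap_base(nseg, Lout, stride, Lp), C, k);
    Y = W * Xcol;
  }
  Y.each_col() += bias;
  return Y;
}

// [[Rcpp::export]]
Rcpp::List conv1d_bwd(const arma::mat& X, const arma::mat& W,
                      const arma::mat& dY, int L, int nseg,
                      int k, int stride) {
  int Lout, pad_left, pad_total;
  same_pad(L, k, stride, Lout, pad_left, pad_total);
  const int C = X.n_rows;
  const int Lp = L + pad_total;
  mat Xpad = pad_batch(X, L, nseg, pad_left, pad_total);
  mat dW(W.n_rows, W.n_cols);
  vec db = sum(dY, 1);
  mat dXpad(C, Xpad.n_cols, fill::zeros);
  if (stride == 1) {
    const size_t nfull = Xpad.n_cols - (k - 1);
    mat dYfull = scatter_valid(dY, nseg, Lout, Lp, dY.n_rows, nfull);
    for (int j = 0; j < k; ++j) {
      dW.cols(j * C, (j + 1) * C - 1) =
        dYfull * Xpad.cols(j, j + nfull - 1).t();
      dXpad.cols(j, j + nfull - 1) +=
        W.cols(j * C, (j + 1) * C - 1).t() * dYfull;
    }
  } else {
    uvec base = tap_base(nseg, Lout, stride, Lp);
    mat Xcol = im2col(Xpad, base, C, k);
    dW = dY * Xcol.t();
    mat dXcol = W.t() * dY;
    for (size_t c = 0; c < base.n_elem; ++c) {
      const double* src = dXcol.colptr(c);
      double* dst = dXpad.colptr(base(c));
      for (int i = 0; i < C * k; ++i) dst[i] += src[i];
    }
  }
  mat dX(C, X.n_cols);
  if (pad_total == 0) {
    dX = dXpad;
  } else {
    for (int s = 0; s < nseg; ++s) {
      dX.cols((size_t)s * L, (size_t)s * L + L - 1) =
        dXpad.cols((size_t)s * Lp + pad_left,
                   (size_t)s * Lp + pad_left + L - 1);
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// Output length of a same-padded strided conv (exported for shape logic).
// [[Rcpp::export]]
int conv1d_out_len(int L, int stride) {
  return (L + stride - 1) / stride;
}
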