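// Fused batch-norm (+ optional ReLU) over channel rows, with single-pass
// accumulation; statistics are taken across all columns (time x segments).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List bn_fwd_cpp(const arma::mat& x, const arma::vec& gamma,
                      const arma::vec& beta, const arma::vec& rmean,
                      const arma::vec& rvar, bool training,
                      double momentum, double eps, bool relu) {
  const uword C = x.n_rows, n = x.n_cols;
  vec mu(C), var_(C);
  if (training) {
    mu = mean(x, 1);
    var_.zeros();
    for (uword j = 0; j < n; ++j) {
      const double* xc = x.colptr(j);
      for (uword i = 0; i < C; ++i) {
        const double d = xc[i] - mu(i);
        var_(i) += d * d;
      }
    }
    var_ /= (double)n;
  } else {
    mu = rmean;
    var_ = rvar;
  }
  vec istd = 1.0 / sqrt(var_ + eps);
  vec a = gamma % istd;
  vec b = beta - a % mu;
  mat y(C, n);
  for (uword j = 0; j < n; ++j) {
    const double* xc = x.colptr(j);
    double* yc = y.colptr(j);
    for (uword i = 0; i < C; ++i) {
      double v = a(i) * xc[i] + b(i);
      if (relu && v < 0) v = 0;
      yc[i] = v;
    }
  }
  vec new_rmean = rmean, new_rvar = rvar;
  if (training) {
    new_rmean = momentum * rmean + (1 - momentum) * mu;
    new_rvar = momentum * rvar + (1 - momentum) * var_;
  }
  return Rcpp::List::create(
    Rcpp::Named("y") = y, Rcpp::Named("mu") = mu,
    Rcpp::Named("istd") = istd,
    Rcpp::Named("rmean") = new_rmean, Rcpp::Named("rvar") = new_rvar);
}

// Backward of the fused op.  `y` is the forward output (used only for the
// ReLU mask when `relu`); `x` is the forward input.  In training mode the
// batch statistics' dependence on x is accounted for; in inference mode
// the map is a fixed affine transform.
// [[Rcpp::export]]
Rcpp::List bn_bwd_cpp(const arma::mat& dy, const arma::mat& y,
                      const arma::mat& x, const arma::vec& mu,
                      const arma::vec& istd, const arma::vec& gamma,
                      bool training, bool relu) {
  const uword C = x.n_rows, n = x.n_cols;
  vec s1(C, fill::zeros), s2(C, fill::zeros);
  for (uword j = 0; j < n; ++j) {
    const double* dc = dy.colptr(j);
    const double* xc = x.colptr(j);
    const double* yc = relu ? y.colptr(j) : nullptr;
    for (uword i = 0; i < C; ++i) {
      double d = dc[i];
      if (relu && yc[i] <= 0) d = 0;
      s1(i) += d;
      s2(i) += d * (xc[i] - mu(i)) * istd(i);
    }
  }
  mat dx(C, n);
  if (training) {
    const vec m1 = s1 / (double)n, m2 = s2 / (double)n;
    for (uword j = 0; j < n; ++j) {
      const double* dc = dy.colptr(j);
      const double* xc = x.colptr(j);
      const double* yc = relu ? y.colptr(j) : nullptr;
      double* o = dx.colptr(j);
      for (uword i = 0; i < C; ++i) {
        double d = dc[i];
        if (relu && yc[i] <= 0) d = 0;
        const double xhat = (xc[i] - mu(i)) * istd(i);
        o[i] = istd(i) * gamma(i) * (d - m1(i) - xhat * m2(i));
      }
    }
  } else {
    for (uword j = 0; j < n; ++j) {
      const double* dc = dy.colptr(j);
      const double* yc = relu ? y.colptr(j) : nullptr;
      double* o = dx.colptr(j);
      for (uword i = 0; i < C; ++i) {
        double d = dc[i];
        if (relu && yc[i] <= 0) d = 0;
        o[i] = istd(i) * gamma(i) * d;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dgamma") = s2,
                            Rcpp::Named("dbeta") = s1);
}
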