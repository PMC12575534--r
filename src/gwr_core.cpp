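// Local weighted least-squares engine for geographically weighted
// regression.  For each calibration location i the kernel turns the
// distance column D(,i) into weights w, and beta_i solves
// (X' W X) b = X' W y.  The hat matrix row at i is x_i' (X'WX)^-1 X'W.
// Optionally the full per-location projection matrices C_i = (X'WX)^-1 X'W
// are stacked into a cube (p x n x n) for the coefficient-variability
// F test, whose quadratic forms need the matrices B_k with rows
// e_k' C_i.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static vec kernel_weights_cpp(const vec& d, double bw, int family) {
  if (family == 0) {                       // gaussian
    return exp(-0.5 * square(d / bw));
  }
  vec u = d / bw;                          // bisquare, compact support
  vec w = square(1.0 - square(u));
  w.elem(find(u >= 1.0)).zeros();
  return w;
}

// [[Rcpp::export]]
Rcpp::List gwr_core_cpp(const arma::mat& X, const arma::vec& y,
                        const arma::mat& D, double bw, int family,
                        bool want_cube) {
  const uword n = X.n_rows, p = X.n_cols;
  mat beta(n, p), S(n, n);
  cube C;
  if (want_cube) C.set_size(p, n, n);

  for (uword i = 0; i < n; ++i) {
    vec w = kernel_weights_cpp(D.col(i), bw, family);
    if (accu(w > 0.0) < p) {
      Rcpp::stop("singular local design at location %d: only %d positively "
                 "weighted observations for %d coefficients; increase the "
                 "bandwidth", (int)(i + 1), (int)accu(w > 0.0), (int)p);
    }
    mat Xw = X.each_col() % w;             // W X
    mat M = X.t() * Xw;                    // X' W X
    mat Ci;                                // (X'WX)^-1 X'W  (p x n)
    bool ok = solve(Ci, M, Xw.t(), solve_opts::no_approx);
    if (!ok || !Ci.is_finite()) {
      Rcpp::stop("singular local design at location %d: weighted design "
                 "matrix not invertible; increase the bandwidth",
                 (int)(i + 1));
    }
    beta.row(i) = (Ci * y).t();
    S.row(i) = X.row(i) * Ci;
    if (want_cube) C.slice(i) = Ci;
  }

  Rcpp::List out = Rcpp::List::create(Rcpp::Named("beta") = beta,
                                      Rcpp::Named("hat") = S);
  if (want_cube) out["proj"] = C;
  return out;
}

// Leave-one-out cross-validation score: prediction at i uses zero
// self-weight.  Returns +Inf when any local solve is degenerate, so the
// bandwidth optimizer treats such bandwidths as inadmissible.
// [[Rcpp::export]]
double gwr_cv_cpp(const arma::mat& X, const arma::vec& y,
                  const arma::mat& D, double bw, int family) {
  const uword n = X.n_rows, p = X.n_cols;
  double score = 0.0;
  for (uword i = 0; i < n; ++i) {
    vec w = kernel_weights_cpp(D.col(i), bw, family);
    w(i) = 0.0;
    if (accu(w > 0.0) < p) return datum::inf;
    mat Xw = X.each_col() % w;
    mat M = X.t() * Xw;
    vec b;
    bool ok = solve(b, M, Xw.t() * y, solve_opts::no_approx);
    if (!ok || !b.is_finite()) return datum::inf;
    double e = y(i) - dot(X.row(i), b);
    score += e * e;
  }
  return score;
}
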