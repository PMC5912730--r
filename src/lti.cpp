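#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Exact propagation of the linear compartment system
//   dx/dt = A x + b * r(t)
// with piecewise-constant r(t) on a uniform grid. Over one interval of
// length h with constant rate r the update is
//   x(t0 + h) = e^{A h} x(t0) + (int_0^h e^{A s} ds) b r,
// both factors read off the matrix exponential of the (d+1)x(d+1)
// augmented matrix [[A, b], [0, 0]]. Exact to floating precision for any
// A, including singular ones (k10 = 0), which is why no matrix inverse
// appears here.
//
// A is in min^-1; `step` and `times` must be in minutes. `times` must be
// sorted ascending and lie within [0, n_rates * step].
// [[Rcpp::export]]
arma::mat lti_propagate_cpp(const arma::mat& A, const arma::vec& b,
                            const arma::vec& rates, double step,
                            const arma::vec& times, const arma::vec& x0) {
  const uword d = A.n_rows;
  mat M(d + 1, d + 1, fill::zeros);
  M.submat(0, 0, d - 1, d - 1) = A;
  M.col(d).head(d) = b;

  const mat E = expmat(M * step);
  const mat Ad = E.submat(0, 0, d - 1, d - 1);
  const vec f = E.col(d).head(d);

  mat out(d, times.n_elem);
  vec x = x0;
  uword ti = 0;
  const double eps = step * 1e-9;

  while (ti < times.n_elem && times(ti) <= eps) {
    out.col(ti) = x0;
    ++ti;
  }
  for (uword i = 0; i < rates.n_elem && ti < times.n_elem; ++i) {
    const double t0 = i * step;
    const double t1 = (i + 1) * step;
    while (ti < times.n_elem && times(ti) < t1 - eps) {
      const double tau = times(ti) - t0;
      const mat Et = expmat(M * tau);
      out.col(ti) = Et.submat(0, 0, d - 1, d - 1) * x +
                    Et.col(d).head(d) * rates(i);
      ++ti;
    }
    x = Ad * x + f * rates(i);
    while (ti < times.n_elem && std::abs(times(ti) - t1) <= eps) {
      out.col(ti) = x;
      ++ti;
    }
  }
  if (ti < times.n_elem)
    Rcpp::stop("evaluation time beyond schedule horizon");
  return out;
}
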