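#include <Rcpp.h>
using namespace Rcpp;

// Soft-thresholded cyclic coordinate descent for the penalised quadratic
// subproblem  min 1/2 b'Ab - c'b + lambda * |b|_1  with A positive
// semidefinite. Full sweeps alternate with active-set sweeps; q = A b is
// cached so each coordinate update is O(p).
// [[Rcpp::export(name = ".cd_quad_cpp")]]
NumericVector cd_quad_cpp(const NumericMatrix& A, const NumericVector& c_vec,
                          const NumericVector& b_init, double lambda,
                          double tol, int max_cycles) {
  const int p = b_init.size();
  NumericVector b = clone(b_init);
  std::vector<double> q(p, 0.0);
  for (int j = 0; j < p; ++j) {
    if (b[j] != 0.0) {
      for (int i = 0; i < p; ++i) q[i] += A(i, j) * b[j];
    }
  }
  auto sweep = [&](bool active_only) -> double {
    double delta = 0.0;
    for (int j = 0; j < p; ++j) {
      if (active_only && b[j] == 0.0) continue;
      const double ajj = A(j, j);
      if (ajj <= 0.0) continue;
      const double zj = c_vec[j] - q[j] + ajj * b[j];
      const double az = std::fabs(zj) - lambda;
      const double bj = az > 0.0 ? (zj > 0.0 ? az : -az) / ajj : 0.0;
      const double diff = bj - b[j];
      if (diff != 0.0) {
        for (int i = 0; i < p; ++i) q[i] += A(i, j) * diff;
        if (std::fabs(diff) > delta) delta = std::fabs(diff);
        b[j] = bj;
      }
    }
    return delta;
  };
  for (int round = 0; round < 10; ++round) {
    if (sweep(false) < tol) break;
    for (int cycle = 0; cycle < max_cycles; ++cycle) {
      if (sweep(true) < tol) break;
    }
  }
  return b;
}
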