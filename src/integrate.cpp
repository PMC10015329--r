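#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama integration of the coupled double-well SDE
//   dx_i = [ -(x_i - r1)(x_i - r2)(x_i - r3) + D * sum_j a_ij x_j + u ] dt
//          + s * sqrt(dt) * Z_{i,step}
// Normal deviates come from R's RNG (node order within each step), so a
// set.seed() call on the R side makes trajectories bitwise reproducible.
//
// States are recorded at steps record_start, record_start + record_every, ...
// up to n_steps (step 0 is the initial condition). Returns an
// n_records x N matrix.
// [[Rcpp::export]]
NumericMatrix em_integrate_cpp(const IntegerMatrix& adj, const NumericVector& x0,
                               double r1, double r2, double r3,
                               double D, double u, double s,
                               double dt, int n_steps,
                               int record_start, int record_every) {
  const int N = x0.size();
  if (adj.nrow() != N || adj.ncol() != N)
    stop("adjacency dimension does not match state vector length");
  if (record_start < 0 || record_start > n_steps)
    stop("record_start out of range");

  // sparse edge index: for each node, the list of neighbours
  std::vector< std::vector<int> > nbr(N);
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < N; ++j)
      if (adj(i, j) != 0) nbr[i].push_back(j);

  const int n_records = (n_steps - record_start) / record_every + 1;
  NumericMatrix out(n_records, N);

  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> xn(N);
  const double sq = s * std::sqrt(dt);
  int rec = 0;
  if (record_start == 0) {
    for (int i = 0; i < N; ++i) out(0, i) = x[i];
    rec = 1;
  }

  for (int step = 1; step <= n_steps; ++step) {
    NumericVector z;
    if (s > 0.0) z = rnorm(N);
    for (int i = 0; i < N; ++i) {
      double coup = 0.0;
      const std::vector<int>& nb = nbr[i];
      for (size_t k = 0; k < nb.size(); ++k) coup += x[nb[k]];
      double drift = -(x[i] - r1) * (x[i] - r2) * (x[i] - r3) + D * coup + u;
      double xi = x[i] + drift * dt;
      if (s > 0.0) xi += sq * z[i];
      if (!std::isfinite(xi))
        stop("integration diverged (non-finite state) at step %d, node %d",
             step, i + 1);
      xn[i] = xi;
    }
    x.swap(xn);
    if (step >= record_start && (step - record_start) % record_every == 0) {
      for (int i = 0; i < N; ++i) out(rec, i) = x[i];
      ++rec;
    }
  }
  return out;
}
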