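#include <Rcpp.h>
using namespace Rcpp;

// Metropolis-Hastings single-toggle sampler for one STERGM phase.
//
// adj0:       n x n 0/1 starting state (the previous day's network with the
//             phase's constraint already applied; fixed dyads keep their
//             adj0 state throughout).
// free_i/j:   0-based endpoints of the m free dyads this phase may toggle
//             (formation: dyads empty yesterday; persistence: dyads present).
// eta:        length-m dyad-independent linear predictor (all non-triangle
//             terms evaluated once; their change statistics do not depend on
//             the network state).
// theta_tri:  triangle coefficient (0 when the model has no triangle term);
//             the triangle change statistic is the current number of common
//             neighbours of the dyad's endpoints, recomputed on the fly.
// n_samples:  independent chains, each restarted from adj0.
// burnin_sweeps: full sweeps (m proposals each) before recording a sample.
//
// Uses R's RNG, so draws are reproducible under set.seed().
// Returns an n_samples x m 0/1 matrix of free-dyad states.
// [[Rcpp::export]]
IntegerMatrix mh_phase_cpp(IntegerMatrix adj0, IntegerVector free_i,
                           IntegerVector free_j, NumericVector eta,
                           double theta_tri, int n_samples,
                           int burnin_sweeps) {
  const int n = adj0.nrow();
  const int m = free_i.size();
  IntegerMatrix out(n_samples, m);
  if (m == 0) return out;
  std::vector<int> adj(n * n);
  RNGScope scope;
  for (int s = 0; s < n_samples; ++s) {
    for (int k = 0; k < n * n; ++k) adj[k] = adj0[k];
    const int steps = burnin_sweeps * m;
    for (int it = 0; it < steps; ++it) {
      const int d = (int)(unif_rand() * m);
      const int i = free_i[d], j = free_j[d];
      double lp = eta[d];
      if (theta_tri != 0.0) {
        int cn = 0;
        const int *ri = &adj[(size_t)i * n], *rj = &adj[(size_t)j * n];
        for (int k = 0; k < n; ++k) cn += ri[k] & rj[k];
        lp += theta_tri * cn;
      }
      const int cur = adj[(size_t)i * n + j];
      // log acceptance ratio of toggling: +lp if turning on, -lp if off
      const double la = cur ? -lp : lp;
      if (la >= 0.0 || unif_rand() < std::exp(la)) {
        adj[(size_t)i * n + j] = 1 - cur;
        adj[(size_t)j * n + i] = 1 - cur;
      }
    }
    for (int d = 0; d < m; ++d)
      out(s, d) = adj[(size_t)free_i[d] * n + free_j[d]];
  }
  return out;
}
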