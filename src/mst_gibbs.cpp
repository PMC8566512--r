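#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for microbial source tracking.
//
// Each read i of the sink carries a taxon t(i) and a latent source z(i) in
// {0..V-1} (known sources) or V (Unknown). The full conditional is
//
//   P(z_i = v) prop. to  (m_tv + n_tv^{-i} + alpha) / (m_.v + n_.v^{-i} + T alpha)
//                        * (n_v^{-i} + beta)
//
// where m are fixed training counts of taxon t in source v (zero for the
// Unknown source, whose distribution is learned from the current
// assignments), n are current sink assignment counts excluding read i, and
// T is the number of taxa. One draw is recorded per restart after burn_in
// full sweeps; uses R's RNG so set.seed() governs reproducibility.
//
// taxa: 0-based taxon index per read (length N)
// m_tv: T x V training count matrix (known sources only)
// returns: restarts x (V + 1) matrix of source proportions (Unknown last)
// [[Rcpp::export]]
NumericMatrix mst_gibbs(IntegerVector taxa, IntegerMatrix m_tv,
                        double alpha, double beta,
                        int burn_in, int restarts) {
  const int N = taxa.size();
  const int T = m_tv.nrow();
  const int V = m_tv.ncol();
  const int S = V + 1;  // sources incl. Unknown

  std::vector<double> m_dot(V, 0.0);
  for (int v = 0; v < V; ++v)
    for (int t = 0; t < T; ++t) m_dot[v] += m_tv(t, v);

  NumericMatrix out(restarts, S);
  std::vector<int> z(N);
  std::vector<int> n_tv(T * S);
  std::vector<double> n_v(S);
  std::vector<double> prob(S);

  for (int r = 0; r < restarts; ++r) {
    std::fill(n_tv.begin(), n_tv.end(), 0);
    std::fill(n_v.begin(), n_v.end(), 0.0);
    for (int i = 0; i < N; ++i) {
      int v = (int)(unif_rand() * S);
      if (v == S) v = S - 1;
      z[i] = v;
      n_tv[taxa[i] * S + v] += 1;
      n_v[v] += 1.0;
    }
    for (int sweep = 0; sweep < burn_in; ++sweep) {
      for (int i = 0; i < N; ++i) {
        const int t = taxa[i];
        const int old = z[i];
        n_tv[t * S + old] -= 1;
        n_v[old] -= 1.0;
        double total = 0.0;
        for (int v = 0; v < V; ++v) {
          const double lik = (m_tv(t, v) + n_tv[t * S + v] + alpha) /
                             (m_dot[v] + n_v[v] + T * alpha);
          total += lik * (n_v[v] + beta);
          prob[v] = total;
        }
        {
          const double lik = (n_tv[t * S + V] + alpha) /
                             (n_v[V] + T * alpha);
          total += lik * (n_v[V] + beta);
          prob[V] = total;
        }
        const double u = unif_rand() * total;
        int v_new = 0;
        while (v_new < V && prob[v_new] <= u) ++v_new;
        z[i] = v_new;
        n_tv[t * S + v_new] += 1;
        n_v[v_new] += 1.0;
      }
    }
    for (int v = 0; v < S; ++v) out(r, v) = n_v[v] / (double)N;
  }
  return out;
}
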