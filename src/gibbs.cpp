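#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler attributing each sink read to one of K known
// sources (fixed count profiles -> fixed per-taxon likelihoods) plus an
// optional "unknown" source modelled as a Dirichlet-multinomial over the
// taxon universe. The conditional for read i with taxon t is
//   P(z_i = v | z_-i) propto P(t|v) * (n_v^(-i) + beta)
// with P(t|v) fixed for known sources and
//   P(t|unknown) = (q_t^(-i) + alpha_u) / (q^(-i) + alpha_u * tau)
// for the unknown source. Uses R's RNG; seed via set.seed() in R.
//
// [[Rcpp::export]]
List gibbs_attribution_cpp(IntegerVector read_taxa, NumericMatrix known_lik,
                           bool include_unknown, double alpha_unknown,
                           double beta, int n_restarts, int n_burnin,
                           int n_draws, int draw_spacing) {
  const int N = read_taxa.size();
  const int tau = known_lik.nrow();
  const int K = known_lik.ncol();
  const int V = K + (include_unknown ? 1 : 0);
  const int U = K;  // index of the unknown source, if enabled

  std::vector<double> acc_n(V, 0.0);
  std::vector<double> acc_tv((size_t)tau * V, 0.0);
  std::vector<int> z(N), n_v(V), q_t(tau), c_tv((size_t)tau * V);
  std::vector<double> w(V);
  long n_recorded = 0;

  for (int r = 0; r < n_restarts; ++r) {
    std::fill(n_v.begin(), n_v.end(), 0);
    std::fill(q_t.begin(), q_t.end(), 0);
    std::fill(c_tv.begin(), c_tv.end(), 0);
    int q_tot = 0;
    for (int i = 0; i < N; ++i) {
      int v = (int)(unif_rand() * V);
      if (v >= V) v = V - 1;
      z[i] = v;
      n_v[v]++;
      c_tv[(size_t)read_taxa[i] * V + v]++;
      if (include_unknown && v == U) { q_t[read_taxa[i]]++; q_tot++; }
    }
    const int total_sweeps = n_burnin + n_draws * draw_spacing;
    for (int sweep = 1; sweep <= total_sweeps; ++sweep) {
      for (int i = 0; i < N; ++i) {
        const int t = read_taxa[i];
        const int v_old = z[i];
        n_v[v_old]--;
        c_tv[(size_t)t * V + v_old]--;
        if (include_unknown && v_old == U) { q_t[t]--; q_tot--; }
        double w_sum = 0.0;
        for (int v = 0; v < K; ++v) {
          w[v] = known_lik(t, v) * (n_v[v] + beta);
          w_sum += w[v];
        }
        if (include_unknown) {
          w[U] = (q_t[t] + alpha_unknown) / (q_tot + alpha_unknown * tau) *
                 (n_v[U] + beta);
          w_sum += w[U];
        }
        double u = unif_rand() * w_sum;
        int v_new = 0;
        for (; v_new < V - 1; ++v_new) {
          u -= w[v_new];
          if (u <= 0.0) break;
        }
        z[i] = v_new;
        n_v[v_new]++;
        c_tv[(size_t)t * V + v_new]++;
        if (include_unknown && v_new == U) { q_t[t]++; q_tot++; }
      }
      if (sweep > n_burnin && (sweep - n_burnin) % draw_spacing == 0) {
        for (int v = 0; v < V; ++v) acc_n[v] += n_v[v];
        for (size_t k = 0; k < acc_tv.size(); ++k) acc_tv[k] += c_tv[k];
        n_recorded++;
      }
    }
  }

  NumericVector proportions(V);
  for (int v = 0; v < V; ++v) {
    proportions[v] = acc_n[v] / ((double)n_recorded * N);
  }
  // per-taxon attributed fractions: mean share of taxon t's reads per source
  std::vector<double> taxon_count(tau, 0.0);
  for (int i = 0; i < N; ++i) taxon_count[read_taxa[i]] += 1.0;
  NumericMatrix attribution(tau, V);
  for (int t = 0; t < tau; ++t) {
    for (int v = 0; v < V; ++v) {
      attribution(t, v) = taxon_count[t] > 0
        ? acc_tv[(size_t)t * V + v] / (n_recorded * taxon_count[t])
        : NA_REAL;
    }
  }
  return List::create(_["proportions"] = proportions,
                      _["attribution"] = attribution,
                      _["n_recorded"] = (double)n_recorded);
}
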