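#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Hubbell-style death-replacement dynamics for one set of local
// communities. Each sample holds n_reads individuals, initialized by a
// multinomial draw from the metacommunity relative abundances. Then
// n_generations * n_reads death events are applied: a uniformly chosen
// individual dies and is replaced from the metacommunity with probability
// m, otherwise by a copy of another (uniformly chosen) local individual.
// Uses R's RNG, so set.seed() in R makes the trajectory reproducible.
// [[Rcpp::export]]
IntegerMatrix neutral_sim_cpp(NumericVector meta_p, int n_samples,
                              int n_reads, double m, int n_generations) {
  const int T = meta_p.size();
  std::vector<double> cum(T);
  double s = 0.0;
  for (int i = 0; i < T; ++i) { s += meta_p[i]; cum[i] = s; }

  IntegerMatrix out(n_samples, T);
  std::vector<int> slots(n_reads);

  for (int smp = 0; smp < n_samples; ++smp) {
    for (int r = 0; r < n_reads; ++r) {
      double u = unif_rand() * s;
      int idx = (int)(std::lower_bound(cum.begin(), cum.end(), u) -
                      cum.begin());
      if (idx >= T) idx = T - 1;
      slots[r] = idx;
    }
    const long long events = (long long)n_generations * (long long)n_reads;
    for (long long e = 0; e < events; ++e) {
      int dead = (int)(unif_rand() * n_reads);
      if (dead >= n_reads) dead = n_reads - 1;
      if (unif_rand() < m) {
        double u = unif_rand() * s;
        int idx = (int)(std::lower_bound(cum.begin(), cum.end(), u) -
                        cum.begin());
        if (idx >= T) idx = T - 1;
        slots[dead] = idx;
      } else if (n_reads > 1) {
        int src = (int)(unif_rand() * (n_reads - 1));
        if (src >= n_reads - 1) src = n_reads - 2;
        if (src >= dead) ++src;
        slots[dead] = slots[src];
      }
    }
    for (int r = 0; r < n_reads; ++r) out(smp, slots[r])++;
  }
  return out;
}
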