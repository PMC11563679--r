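#include <Rcpp.h>
using namespace Rcpp;

// Two-type Moran process, mutant-count (k-chain) reduction.
//
// One iteration = one division + one death (possibly the same cell), so the
// compartment size stays at N. With k mutants of fitness r among N cells:
//   p_up   = [r k / (r k + N - k)] * [(N - k) / N]
//   p_down = [(N - k) / (r k + N - k)] * [k / N]
// and the chain stays put otherwise. Self-replacement iterations count.

// [[Rcpp::export]]
List cpp_simulate_kchain(int N, double r, int k0, int reps) {
  IntegerVector absorbed(reps);
  NumericVector iters(reps);
  for (int rep = 0; rep < reps; ++rep) {
    int k = k0;
    double t = 0.0;
    while (k > 0 && k < N) {
      double denom = r * k + (double)(N - k);
      double p_up = (r * k / denom) * ((double)(N - k) / N);
      double p_down = ((double)(N - k) / denom) * ((double)k / N);
      // waiting time in the current state is geometric; draw it in one shot
      // (distribution of the total iteration count is unchanged)
      double p_move = p_up + p_down;
      double u = unif_rand();
      double stays = floor(log(u) / log1p(-p_move)); // geometric, support 0,1,...
      t += stays + 1.0;
      if (unif_rand() * p_move < p_up) ++k; else --k;
    }
    absorbed[rep] = k;
    iters[rep] = t;
  }
  return List::create(_["absorbed"] = absorbed, _["iterations"] = iters);
}

// Literal N-cell implementation kept as an independent oracle: an explicit
// fitness vector, divider sampled proportional to fitness by linear scan,
// dier sampled uniformly, dier replaced by a copy of the divider. No
// geometric shortcut: every iteration is simulated.

// [[Rcpp::export]]
List cpp_simulate_agentwise(int N, double r, int k0, int reps) {
  IntegerVector absorbed(reps);
  NumericVector iters(reps);
  std::vector<double> fit(N);
  std::vector<int> mut(N); // lineage identity, independent of fitness value
  for (int rep = 0; rep < reps; ++rep) {
    for (int i = 0; i < N; ++i) {
      mut[i] = (i < k0) ? 1 : 0;
      fit[i] = mut[i] ? r : 1.0;
    }
    int k = k0;
    double t = 0.0;
    while (k > 0 && k < N) {
      double total = 0.0;
      for (int i = 0; i < N; ++i) total += fit[i];
      double u = unif_rand() * total;
      int divider = N - 1;
      double acc = 0.0;
      for (int i = 0; i < N; ++i) {
        acc += fit[i];
        if (u < acc) { divider = i; break; }
      }
      int dier = (int)(unif_rand() * N);
      if (dier == N) dier = N - 1; // guard against unif_rand() == 1
      if (mut[divider] && !mut[dier]) ++k;
      if (!mut[divider] && mut[dier]) --k;
      mut[dier] = mut[divider];
      fit[dier] = fit[divider];
      t += 1.0;
    }
    absorbed[rep] = k;
    iters[rep] = t;
  }
  return List::create(_["absorbed"] = absorbed, _["iterations"] = iters);
}
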