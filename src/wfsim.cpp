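#include <Rcpp.h>
using namespace Rcpp;

// Forward-in-time Wright-Fisher haplotype simulator with recombination
// and recurrent (symmetric) mutation, used to produce genotype panels
// whose LD decay reflects a known constant effective population size.
// Haplotypes are 0/1 over n_sites loci; `rec` is the per-adjacent-site
// crossover probability per meiosis, `mu` the per-site per-generation
// flip probability.  Uses R's RNG (set.seed-reproducible).
// [[Rcpp::export(name = ".wf_sim_haps")]]
IntegerMatrix wf_sim_haps(int n_e, int n_sites, int n_gen,
                          double rec, double mu) {
  int H = 2 * n_e;
  IntegerMatrix cur(n_sites, H), nxt(n_sites, H);
  for (int s = 0; s < n_sites; ++s) {
    double p = 0.05 + 0.9 * unif_rand();
    for (int h = 0; h < H; ++h) cur(s, h) = (unif_rand() < p) ? 1 : 0;
  }
  double log1m_rec = (rec > 0 && rec < 1) ? std::log(1.0 - rec) : 0.0;
  for (int g = 0; g < n_gen; ++g) {
    for (int h = 0; h < H; ++h) {
      int parent = (int)(unif_rand() * n_e);
      if (parent >= n_e) parent = n_e - 1;
      int src = 2 * parent + (unif_rand() < 0.5 ? 1 : 0);
      int oth = 4 * parent + 1 - src;
      int pos = 0;
      while (pos < n_sites) {
        int jump = n_sites;
        if (rec > 0 && rec < 1) {
          jump = 1 + (int)(std::log(unif_rand()) / log1m_rec);
          if (jump < 1) jump = 1;
        }
        int end = pos + jump;
        if (end > n_sites) end = n_sites;
        for (int s = pos; s < end; ++s) nxt(s, h) = cur(s, src);
        pos = end;
        std::swap(src, oth);
      }
      if (mu > 0) {
        int nmut = (int)R::rbinom((double)n_sites, mu);
        for (int k = 0; k < nmut; ++k) {
          int s = (int)(unif_rand() * n_sites);
          if (s >= n_sites) s = n_sites - 1;
          nxt(s, h) ^= 1;
        }
      }
    }
    std::swap(cur, nxt);
  }
  return cur;
}
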