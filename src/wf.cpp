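// Forward Wright-Fisher simulator core: biallelic reversible mutation over a
// short sequence, fitness-proportional parent sampling, optional
// recombination, additive per-site selection with dominance, pairwise
// epistatic increments evaluated per haplotype, and an optional negative
// frequency-dependent site.  Uses R's RNG so runs are reproducible from
// set.seed() on the R side.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static int sample_cumulative(const std::vector<double> &cw) {
  double u = unif_rand() * cw.back();
  int lo = 0, hi = (int)cw.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cw[mid] < u) lo = mid + 1; else hi = mid;
  }
  return lo;
}

// Fitness of each individual.  pop is row-major (haplotype-major): hap h,
// site j at pop[h*L + j].  Diploid individuals own haplotypes 2i and 2i+1.
static void compute_fitness(const std::vector<signed char> &pop, int n_hap,
                            int L, int ploidy,
                            const std::vector<int> &sel_sites,
                            const NumericVector &s_site,
                            const NumericVector &h_site,
                            const IntegerMatrix &epi_pairs,
                            const NumericVector &epi_eps, int nfds_site,
                            double nfds_smax, double fitness_floor,
                            std::vector<double> &w) {
  int n_ind = (ploidy == 2) ? n_hap / 2 : n_hap;
  w.assign(n_ind, 1.0);
  double s_nfds = 0.0;
  if (nfds_site >= 0) {
    double p = 0.0;
    for (int h = 0; h < n_hap; ++h) p += pop.data()[(size_t)h * L + nfds_site];
    p /= n_hap;
    s_nfds = nfds_smax * (1.0 - 2.0 * p);
  }
  for (int i = 0; i < n_ind; ++i) {
    double acc = 0.0;
    if (ploidy == 1) {
      const signed char *hap = pop.data() + (size_t)i * L;
      for (size_t k = 0; k < sel_sites.size(); ++k) {
        int j = sel_sites[k];
        if (hap[j]) acc += s_site[j];
      }
      if (nfds_site >= 0 && hap[nfds_site]) acc += s_nfds;
      for (int k = 0; k < epi_pairs.nrow(); ++k) {
        if (hap[epi_pairs(k, 0)] && hap[epi_pairs(k, 1)]) acc += epi_eps[k];
      }
    } else {
      const signed char *ha = pop.data() + (size_t)(2 * i) * L;
      const signed char *hb = pop.data() + (size_t)(2 * i + 1) * L;
      for (size_t k = 0; k < sel_sites.size(); ++k) {
        int j = sel_sites[k];
        int g = ha[j] + hb[j];
        if (g == 2) acc += s_site[j];
        else if (g == 1) acc += h_site[j] * s_site[j];
      }
      if (nfds_site >= 0) {
        int g = ha[nfds_site] + hb[nfds_site];
        if (g == 2) acc += s_nfds;
        else if (g == 1) acc += h_site[nfds_site] * s_nfds;
      }
      // per-haplotype epistatic increment at half weight, so a cis double
      // mutant het and the double homozygote are both exactly compensated
      for (int k = 0; k < epi_pairs.nrow(); ++k) {
        int a = epi_pairs(k, 0), b = epi_pairs(k, 1);
        if (ha[a] && ha[b]) acc += 0.5 * epi_eps[k];
        if (hb[a] && hb[b]) acc += 0.5 * epi_eps[k];
      }
    }
    double f = 1.0 + acc;
    w[i] = (f > fitness_floor) ? f : fitness_floor;
  }
}

// [[Rcpp::export]]
IntegerMatrix wf_simulate_cpp(int n_hap, int L, int ploidy, double mu,
                              int n_gen, NumericVector s_site,
                              NumericVector h_site, IntegerMatrix epi_pairs,
                              NumericVector epi_eps, int nfds_site,
                              double nfds_smax, double recomb,
                              double fitness_floor) {
  if (ploidy == 2 && n_hap % 2 != 0) stop("diploid population needs even n_hap");
  int n_ind = (ploidy == 2) ? n_hap / 2 : n_hap;
  std::vector<signed char> cur((size_t)n_hap * L, 0), nxt((size_t)n_hap * L, 0);
  std::vector<int> sel_sites;
  for (int j = 0; j < L; ++j) if (s_site[j] != 0.0) sel_sites.push_back(j);
  std::vector<double> w, cw(n_ind);

  for (int gen = 0; gen < n_gen; ++gen) {
    compute_fitness(cur, n_hap, L, ploidy, sel_sites, s_site, h_site,
                    epi_pairs, epi_eps, nfds_site, nfds_smax, fitness_floor,
                    w);
    double acc = 0.0;
    for (int i = 0; i < n_ind; ++i) { acc += w[i]; cw[i] = acc; }
    if (ploidy == 1) {
      for (int i = 0; i < n_ind; ++i) {
        int p1 = sample_cumulative(cw);
        signed char *dst = nxt.data() + (size_t)i * L;
        if (recomb > 0.0 && unif_rand() < recomb) {
          int p2 = sample_cumulative(cw);
          int x = 1 + (int)(unif_rand() * (L - 1));
          const signed char *s1 = cur.data() + (size_t)p1 * L;
          const signed char *s2 = cur.data() + (size_t)p2 * L;
          std::copy(s1, s1 + x, dst);
          std::copy(s2 + x, s2 + L, dst + x);
        } else {
          const signed char *s1 = cur.data() + (size_t)p1 * L;
          std::copy(s1, s1 + L, dst);
        }
      }
    } else {
      for (int i = 0; i < n_ind; ++i) {
        for (int g = 0; g < 2; ++g) {
          int par = sample_cumulative(cw);
          const signed char *ha = cur.data() + (size_t)(2 * par) * L;
          const signed char *hb = cur.data() + (size_t)(2 * par + 1) * L;
          if (unif_rand() < 0.5) std::swap(ha, hb);
          signed char *dst = nxt.data() + (size_t)(2 * i + g) * L;
          if (recomb > 0.0 && unif_rand() < recomb) {
            int x = 1 + (int)(unif_rand() * (L - 1));
            std::copy(ha, ha + x, dst);
            std::copy(hb + x, hb + L, dst);
          } else {
            std::copy(ha, ha + L, dst);
          }
        }
      }
    }
    // reversible 0<->1 mutation: binomial number of flips at random cells
    int n_cells = n_hap * L;
    int nm = (int)R::rbinom((double)n_cells, mu);
    for (int k = 0; k < nm; ++k) {
      int cell = (int)(unif_rand() * n_cells);
      if (cell >= n_cells) cell = n_cells - 1;
      nxt.data()[cell] ^= 1;
    }
    cur.swap(nxt);
  }

  IntegerMatrix out(n_hap, L);
  for (int h = 0; h < n_hap; ++h)
    for (int j = 0; j < L; ++j) out(h, j) = cur.data()[(size_t)h * L + j];
  return out;
}

// [[Rcpp::export]]
NumericVector wf_fitness_cpp(IntegerMatrix pop, int ploidy,
                             NumericVector s_site, NumericVector h_site,
                             IntegerMatrix epi_pairs, NumericVector epi_eps,
                             int nfds_site, double nfds_smax,
                             double fitness_floor) {
  int n_hap = pop.nrow(), L = pop.ncol();
  std::vector<signed char> flat((size_t)n_hap * L);
  for (int h = 0; h < n_hap; ++h)
    for (int j = 0; j < L; ++j) flat[(size_t)h * L + j] = (signed char)pop(h, j);
  std::vector<int> sel_sites;
  for (int j = 0; j < L; ++j) if (s_site[j] != 0.0) sel_sites.push_back(j);
  std::vector<double> w;
  compute_fitness(flat, n_hap, L, ploidy, sel_sites, s_site, h_site,
                  epi_pairs, epi_eps, nfds_site, nfds_smax, fitness_floor, w);
  return wrap(w);
}
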