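#include <Rcpp.h>
#include <cstring>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Discrete-generation Wright-Fisher forward simulation of an island model.
// Haplotypes are columns of a sites x n_hap raw matrix so that copying a run
// of consecutive sites is a contiguous memcpy.
//
// H0:          L x n_hap0 raw matrix of 0/1 alleles (initial haplotypes)
// pos_M:       within-chromosome genetic position of each site (Morgans)
// chrom_start: 0-based offsets of each chromosome's first site, length n_chrom+1
//              (last element = L)
// deme_sizes:  s x T integer matrix, diploid individuals per deme per generation
//              (for haploid mode: haploid individuals per deme)
// deme_sizes0: initial individuals per deme (must match ncol(H0)/ploidy)
// m:           per-generation migration rate (offspring's parents come from a
//              uniformly chosen other deme with probability m)
// ploidy:      2 = diploid (2 columns per individual), 1 = haploid (1 column;
//              offspring is a recombinant of two random parent haplotypes)
// mu:          per-site per-copy symmetric flip rate per generation

static inline int sample_int(int n) {
  // uniform on 0..n-1 using R's RNG
  int k = (int)(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

// copy one recombinant gamete from parent haplotype columns a and b into dst
static void make_gamete(const Rbyte* a, const Rbyte* b, Rbyte* dst,
                        const int* chrom_start, int n_chrom,
                        const double* pos_M, const double* chrom_len_M,
                        std::vector<double>& cx) {
  for (int ch = 0; ch < n_chrom; ++ch) {
    int lo = chrom_start[ch], hi = chrom_start[ch + 1];
    int cur = (unif_rand() < 0.5) ? 0 : 1;   // independent assortment
    int ncx = (int)R::rpois(chrom_len_M[ch]);
    if (ncx == 0) {
      std::memcpy(dst + lo, (cur ? b : a) + lo, hi - lo);
      continue;
    }
    cx.resize(ncx);
    for (int k = 0; k < ncx; ++k) cx[k] = unif_rand() * chrom_len_M[ch];
    std::sort(cx.begin(), cx.end());
    int seg_lo = lo;
    for (int k = 0; k < ncx; ++k) {
      // first site strictly beyond the crossover point
      const double* first = pos_M + seg_lo;
      const double* last  = pos_M + hi;
      int seg_hi = seg_lo + (int)(std::upper_bound(first, last, cx[k]) - first);
      if (seg_hi > seg_lo)
        std::memcpy(dst + seg_lo, (cur ? b : a) + seg_lo, seg_hi - seg_lo);
      seg_lo = seg_hi;
      cur = 1 - cur;
    }
    if (hi > seg_lo)
      std::memcpy(dst + seg_lo, (cur ? b : a) + seg_lo, hi - seg_lo);
  }
}

// [[Rcpp::export]]
RawMatrix forward_wf_cpp(RawMatrix H0, NumericVector pos_M,
                         IntegerVector chrom_start, NumericVector chrom_len_M,
                         IntegerMatrix deme_sizes, IntegerVector deme_sizes0,
                         double m, int ploidy, double mu) {
  const int L = H0.nrow();
  const int s = deme_sizes.nrow();
  const int T = deme_sizes.ncol();
  const int n_chrom = chrom_len_M.size();
  RNGScope scope;

  std::vector<Rbyte> cur(H0.begin(), H0.end());
  std::vector<int> cur_n(deme_sizes0.begin(), deme_sizes0.end());
  std::vector<double> cx;

  for (int g = 0; g < T; ++g) {
    std::vector<int> nxt_n(s);
    for (int d = 0; d < s; ++d) nxt_n[d] = deme_sizes(d, g);
    int tot_next = 0, tot_cur = 0;
    for (int d = 0; d < s; ++d) { tot_next += nxt_n[d]; tot_cur += cur_n[d]; }
    std::vector<Rbyte> nxt((size_t)L * tot_next * ploidy);
    // column offset of each deme's first haplotype
    std::vector<int> off_cur(s + 1, 0), off_nxt(s + 1, 0);
    for (int d = 0; d < s; ++d) {
      off_cur[d + 1] = off_cur[d] + cur_n[d] * ploidy;
      off_nxt[d + 1] = off_nxt[d] + nxt_n[d] * ploidy;
    }
    for (int d = 0; d < s; ++d) {
      for (int i = 0; i < nxt_n[d]; ++i) {
        int src = d;
        if (s > 1 && unif_rand() < m) {
          int other = sample_int(s - 1);
          src = (other >= d) ? other + 1 : other;
        }
        int np = cur_n[src];
        for (int h = 0; h < ploidy; ++h) {
          const Rbyte *pa, *pb;
          if (ploidy == 2) {
            int par = sample_int(np);
            pa = cur.data() + (size_t)L * (off_cur[src] + 2 * par);
            pb = pa + L;
          } else {
            int p1 = sample_int(np), p2 = sample_int(np);
            pa = cur.data() + (size_t)L * (off_cur[src] + p1);
            pb = cur.data() + (size_t)L * (off_cur[src] + p2);
          }
          Rbyte* dst = nxt.data() + (size_t)L * (off_nxt[d] + ploidy * i + h);
          make_gamete(pa, pb, dst, &chrom_start[0], n_chrom, &pos_M[0],
                      &chrom_len_M[0], cx);
        }
      }
    }
    if (mu > 0) {
      double lambda = mu * (double)L * tot_next * ploidy;
      int nmut = (int)R::rpois(lambda);
      size_t sz = nxt.size();
      for (int k = 0; k < nmut; ++k) {
        size_t j = (size_t)(unif_rand() * sz);
        if (j >= sz) j = sz - 1;
        nxt[j] = 1 - nxt[j];
      }
    }
    cur.swap(nxt);
    cur_n = nxt_n;
  }

  int tot = 0;
  for (int d = 0; d < s; ++d) tot += cur_n[d];
  RawMatrix out(L, tot * ploidy);
  std::copy(cur.begin(), cur.end(), out.begin());
  return out;
}
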