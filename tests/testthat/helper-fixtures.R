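# Shared, lazily computed simulation fixtures.  Heavy runs are computed once
# per test session and reused across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, fun) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- fun()
  .fixtures[[name]]
}

# small panmictic diploid sample used by several unit tests
small_panmictic <- function() fixture("small_panmictic", function() {
  simulate_island(sim_config(s = 1, N = 300, n_sites = 3000, sample_n = 80,
                             generations = 120, seed = 11))
})

small_summary <- function() fixture("small_summary", function() {
  summarize_ld(small_panmictic()$genotypes, ld_config(seed = 1))
})

# build a synthetic ld_summary directly from observable values (noiseless
# solver inputs); weak profile is a single effective-c bin
synthetic_summary <- function(d2u, d2w, f_hat, n = 100, c_weak = 0.2,
                              ploidy = "diploid", bins = NULL) {
  wp <- tibble::tibble(bin = 25L, n_pairs = 1e5, sum_w = 1,
                       sum_c = c_weak * 1e5, sum_inv_c = 1e5 / c_weak,
                       c_harm = c_weak, c_mean = c_weak)
  if (is.null(bins)) bins <- tibble::tibble()
  structure(list(
    delta2_unlinked = d2u, delta2_weak = d2w, bins = bins, f_hat = f_hat,
    n = n, n_snps = NA_integer_, ploidy = ploidy,
    chroms = paste0("chr", 1:4), n_pairs_unlinked = 1e6, n_pairs_weak = 1e5,
    weak_profile = wp, pair_table = tibble::tibble(),
    f_by_chrom = NULL, config = ld_config()), class = "ld_summary")
}

# the ten seeded replicates of the two-deme reference scenario
# (2 demes x 1000, m = 0.001, 100 sampled individuals, >= 10k SNPs on
# 4 chromosomes); shared by the structure-recovery acceptance checks
two_deme_runs <- function() fixture("two_deme_runs", function() {
  lapply(1:10, function(r) {
    cfg <- sim_config(s = 2, N = 1000, m = 0.001, n_sites = 13000,
                      sample_n = 100, generations = 120, seed = 9100 + r)
    sim <- simulate_island(cfg)
    obs <- summarize_ld(sim$genotypes, ld_config(seed = r))
    fit <- solve_metapop(obs, solver_config(s_max = 12))
    list(truth = sim$truth, obs = obs, fit = fit)
  })
})

small_haploid <- function() fixture("small_haploid", function() {
  simulate_island(sim_config(s = 1, N = 600, n_sites = 3000, sample_n = 80,
                             generations = 120, ploidy = "haploid",
                             seed = 13))$genotypes
})

geomean <- function(x) exp(mean(log(x)))
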