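# recombination-binned Ne trajectories and the sex-chromosome helpers

make_bins_summary <- function(cs, d2s, n = 100) {
  bins <- tibble::tibble(bin = seq_along(cs), c_mean = cs, c_harm = cs,
                         delta2 = d2s, n_pairs = 1e5,
                         sum_num = d2s, sum_w = 1)
  synthetic_summary(d2s[length(d2s)], d2s[length(d2s)], 0, n = n, bins = bins)
}

test_that("the generations-ago mapping is t = 1/(2c)", {
  obs <- make_bins_summary(c(0.005, 0.05, 0.5),
                           expected_delta2_observed(c(0.005, 0.05, 0.5), 500,
                                                    n = 100))
  tr <- ne_trajectory(obs)
  expect_equal(tr$points$t, c(1, 10, 100))
  expect_equal(tidy(tr)$t, tr$points$t)
})

test_that("a single bin at c = 0.5 reproduces the contemporary panmictic
           estimate", {
  d2 <- expected_delta2_observed(0.5, 800, n = 100)
  obs <- make_bins_summary(0.5, d2)
  tr <- ne_trajectory(obs)
  est <- ne_panmictic(obs, basis = "unlinked")
  expect_equal(tr$points$Ne, est$Ne, tolerance = 1e-6)
  expect_equal(tr$points$Ne, 800, tolerance = 1e-6)
})

test_that("bins below the structural LD floor are dropped with a warning", {
  fit <- solve_metapop(synthetic_summary(
    expected_delta2_observed(0.5, 1000, 2, 0.001, 100),
    expected_delta2_observed(0.2, 1000, 2, 0.001, 100),
    takahata_fst(1000, 0.001, 2)), solver_config(s_max = 4))
  # a bin whose LD is below the between-deme component cannot be inverted
  floor_val <- 4 * expected_delta2_between(fit$F_ST, fit$s) * 0.5
  obs <- make_bins_summary(c(0.1, 0.4), c(0.02, floor_val))
  expect_warning(tr <- ne_trajectory(obs, structure = fit), "floor")
  expect_equal(nrow(tr$points), 1)
})

test_that("a recent decline shows up as lower Ne at small t", {
  cfg <- sim_config(s = 1, N = 1000, n_sites = 8000, sample_n = 100,
                    generations = 250, seed = 801)
  cfg <- demographic_event(cfg, time_ago = 10, N = 100)
  sim <- simulate_island(cfg)
  obs <- summarize_ld(sim$genotypes, ld_config(seed = 1))
  tr <- tidy(ne_trajectory(obs))
  recent <- tr$Ne[tr$t <= 5]
  older <- tr$Ne[tr$t >= 20 & tr$t <= 60]
  expect_lt(geomean(recent), 0.5 * geomean(older))
})

test_that("a recent expansion shows the opposite direction", {
  cfg <- sim_config(s = 1, N = 150, n_sites = 8000, sample_n = 100,
                    generations = 250, seed = 802)
  cfg <- demographic_event(cfg, time_ago = 10, N = 1500)
  sim <- simulate_island(cfg)
  obs <- summarize_ld(sim$genotypes, ld_config(seed = 2))
  tr <- tidy(suppressWarnings(ne_trajectory(obs)))
  expect_gt(geomean(tr$Ne[tr$t <= 5]),
            1.5 * geomean(tr$Ne[tr$t >= 20 & tr$t <= 60]))
})

test_that("X-to-autosome rescaling multiplies by 4/3 and divides by 2", {
  expect_equal(x_to_autosome_scale(300), 200)
  # round trip through the inverse scaling is the identity
  expect_equal(x_to_autosome_scale(300) * 2 / (4 / 3), 300)
  expect_error(x_to_autosome_scale(0))
  expect_error(x_to_autosome_scale(-5))
})

test_that("sex-specific map corrections scale cM by 2/3 or 1/2", {
  sites <- tibble::tibble(chrom = "chrX", position_bp = c(1e6, 2e6),
                          position_cM = c(0, 30))
  g <- genotype_matrix(matrix(c(0L, 1L, 2L, 1L), 2), sites, "diploid")
  expect_equal(sex_map_correction(g, "x_male_sample")$sites$position_cM,
               c(0, 20))
  expect_equal(sex_map_correction(g,
                                  "autosome_male_drosophila")$sites$position_cM,
               c(0, 15))
  expect_equal(sex_map_correction(g)$sites$position_cM, c(0, 30))
})
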