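# composite LD computation, sampling correction and the genome-wide summary

test_that("identical loci give D2 close to W; constant loci are skipped", {
  x <- rep(c(0L, 1L, 2L), times = c(25, 50, 25))  # HWE at p = 0.5
  p <- composite_pair_ld(x, x, "diploid")
  expect_false(p$skipped)
  expect_equal(p$D2 / p$W, 1, tolerance = 0.03)  # equal up to O(1/n) unbiasing
  expect_true(composite_pair_ld(rep(1L, 50), x[1:50], "diploid")$skipped)
})

test_that("sampling correction matches the permutation oracle", {
  set.seed(42)
  n <- 60
  x <- rbinom(n, 2, 0.4); y <- rbinom(n, 2, 0.25)
  vals <- replicate(3000, {
    p <- composite_pair_ld(x, sample(y), "diploid")
    correct_for_sampling(p$D2, p$W, n, "diploid", p$sxx, p$syy) / p$W
  })
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(length(vals)))
})

test_that("sampling correction vanishes as n grows and errors below n = 4", {
  expect_error(correct_for_sampling(0.01, 0.05, 3))
  w <- 0.04
  corr_small <- 0.01 - correct_for_sampling(0.01, w, 20)
  corr_large <- 0.01 - correct_for_sampling(0.01, w, 2e6)
  expect_gt(corr_small, 1e-3 * w)
  expect_lt(corr_large, 1e-5 * w)
})

test_that("recombination fraction follows Haldane and c = 0.5 across chromosomes", {
  expect_equal(recombination_fraction(37, same_chromosome = FALSE), 0.5)
  expect_equal(recombination_fraction(0), 0)
  expect_equal(recombination_fraction(50), (1 - exp(-1)) / 2)
  expect_error(recombination_fraction(-1))
  # matrix input keeps its shape
  m <- recombination_fraction(matrix(c(0, 10, 10, 0), 2))
  expect_equal(dim(m), c(2, 2))
})

test_that("corrected unlinked delta2 matches the drift observable for a
           panmictic simulation", {
  obs <- small_summary()
  pred <- expected_delta2_observed(0.5, 300, n = obs$n)
  expect_equal(obs$delta2_unlinked, pred, tolerance = 0.25)
})

test_that("pooling two fixed demes gives the Wahlund composite extreme", {
  # 50 individuals fixed ref, 50 fixed alt at every site: Fhat ~ 1 and the
  # composite delta2 approaches 4 * Fst^2/(s-1) = 4 (both homologs carry the
  # deme deviation)
  L <- 60
  dos <- rbind(matrix(0L, 50, L), matrix(2L, 50, L))
  sites <- tibble::tibble(chrom = rep(paste0("chr", 1:4), each = L / 4),
                          position_bp = rep(seq_len(L / 4) * 1e6, 4),
                          position_cM = rep(seq_len(L / 4), 4))
  g <- genotype_matrix(dos, sites, "diploid")
  obs <- summarize_ld(g)
  expect_equal(obs$f_hat, 1)
  expect_equal(obs$delta2_unlinked, 4, tolerance = 0.05)
})

test_that("summaries are invariant to allele relabeling and site order", {
  g <- small_panmictic()$genotypes
  obs1 <- summarize_ld(g, ld_config(seed = 5))
  # swap allele labels at a third of the sites
  d <- g$dosages
  flip <- seq(1, ncol(d), by = 3)
  d[, flip] <- 2L - d[, flip]
  g2 <- genotype_matrix(d, g$sites, "diploid")
  obs2 <- summarize_ld(g2, ld_config(seed = 5))
  expect_equal(obs2$delta2_unlinked, obs1$delta2_unlinked, tolerance = 1e-10)
  expect_equal(obs2$delta2_weak, obs1$delta2_weak, tolerance = 1e-10)
  expect_equal(abs(obs2$f_hat - obs1$f_hat), 0, tolerance = 1e-12)
})

test_that("binned delta2 decays with recombination fraction on average", {
  b <- tidy(small_summary())
  k <- nrow(b)
  expect_gt(mean(b$delta2[1:3]), mean(b$delta2[(k - 2):k]))
})

test_that("inbreeding coefficient hits the textbook extremes and is ~0 under
           Hardy-Weinberg", {
  sites <- tibble::tibble(chrom = "chr1", position_bp = 1:20 * 1000)
  all_het <- genotype_matrix(matrix(1L, 40, 20), sites, "diploid")
  expect_equal(inbreeding_coefficient(all_het), 1 - 1 / (0.5 * 80 / 79))
  all_hom <- genotype_matrix(rbind(matrix(0L, 20, 20), matrix(2L, 20, 20)),
                             sites, "diploid")
  expect_equal(inbreeding_coefficient(all_hom), 1)
  set.seed(3)
  hw <- genotype_matrix(matrix(rbinom(200 * 400, 2, 0.3), 200, 400),
                        tibble::tibble(chrom = "chr1",
                                       position_bp = 1:400 * 1000),
                        "diploid")
  expect_lt(abs(inbreeding_coefficient(hw)), 0.012)  # 3 SE at n=200, L=400
  expect_error(inbreeding_coefficient(small_haploid()))
})

test_that("single-chromosome input without a map is rejected; with a map the
           unlinked summary is flagged unavailable", {
  g <- small_panmictic()$genotypes
  one <- g$sites$chrom == "chr1"
  g1 <- genotype_matrix(g$dosages[, one], g$sites[one, ], "diploid")
  obs <- suppressWarnings(summarize_ld(g1))
  expect_true(is.na(obs$delta2_unlinked))
  expect_error(ne_panmictic(obs, basis = "unlinked"))
  g1$sites$position_cM <- NA_real_
  expect_error(summarize_ld(g1), "map")
})

test_that("missing genotypes are masked, not imputed, and pairwise-complete
           statistics remain finite", {
  g <- small_panmictic()$genotypes
  d <- g$dosages
  set.seed(8)
  d[sample(length(d), length(d) * 0.05)] <- NA_integer_
  keep <- colSums(!is.na(d)) > 0
  g2 <- genotype_matrix(d[, keep], g$sites[keep, ], "diploid")
  obs <- summarize_ld(g2, ld_config(seed = 5))
  expect_true(is.finite(obs$delta2_unlinked))
  expect_true(is.finite(obs$delta2_weak))
  expect_equal(obs$delta2_unlinked, small_summary()$delta2_unlinked,
               tolerance = 0.25)
})
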