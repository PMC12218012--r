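# genotyping-error corrections and the pseudohaploid low-depth procedure

test_that("covariance attenuation and variance inflation match their closed
           forms at the extremes", {
  expect_equal(attenuate_covariance(0.1, 0), 0.1)
  expect_equal(attenuate_covariance(0.1, 0.5), 0)
  expect_equal(inflate_variance(0.25, 0.3), 0.25)  # p = 1/2 is a fixed point
  expect_equal(inflate_variance(0, 0.05), 0.05)
  expect_error(inflate_variance(0.3, 0.05))
  expect_error(attenuate_covariance(0.1, 0.7))
})

test_that("forward error maps then inversion is the identity", {
  for (eps in c(0.01, 0.05, 0.2)) {
    D <- 0.08; V1 <- 0.12; V2 <- 0.2
    d2p <- attenuate_covariance(D, eps)^2
    v1p <- inflate_variance(V1, eps); v2p <- inflate_variance(V2, eps)
    rec <- correct_observed_ld(d2p, epsilon = eps, v1 = v1p, v2 = v2p)
    expect_equal(rec$d2, D^2, tolerance = 1e-12)
    expect_equal(rec$w, V1 * V2, tolerance = 1e-12)
  }
  expect_error(correct_observed_ld(0.01, 0.01, epsilon = 0.5), "not invertible")
})

test_that("error injection attenuates covariances as (1-2e)^2 = 1-4e(1-e)", {
  set.seed(21)
  n <- 2e5; p <- 0.3; eps <- 0.05
  x <- rbinom(n, 1, p); y <- x                       # perfectly coupled gametes
  flip <- function(v) ifelse(runif(n) < eps, 1L - v, v)
  ratio <- cov(flip(x), flip(y)) / cov(x, y)
  expect_equal(ratio, 1 - 4 * eps * (1 - eps), tolerance = 0.02)
})

test_that("error injection inflates variances as V' = V + e(1-4V) to O(e^2)", {
  set.seed(22)
  sites <- tibble::tibble(chrom = "chr1", position_bp = (1:50) * 1000)
  g <- genotype_matrix(matrix(rbinom(50 * 4000, 2, 0.1), 4000), sites,
                       "diploid")
  ge <- inject_errors(g, 0.05, seed = 5)
  p2 <- colMeans(ge$dosages) / 2
  v_obs <- mean(p2 * (1 - p2))
  expect_equal(v_obs, inflate_variance(0.09, 0.05), tolerance = 0.02)
  # monomorphic site gains frequency epsilon
  g0 <- genotype_matrix(matrix(0L, 4000, 50), sites, "diploid")
  p0 <- mean(inject_errors(g0, 0.05, seed = 6)$dosages) / 2
  expect_equal(p0, 0.05, tolerance = 0.05)
  expect_identical(inject_errors(g, 0)$dosages, g$dosages)
})

test_that("pseudohaploid draws keep homozygotes, halve alleles fairly and are
           seed-deterministic", {
  g <- small_panmictic()$genotypes
  h1 <- pseudohaploidize(g, seed = 3)
  h2 <- pseudohaploidize(g, seed = 3)
  expect_identical(h1$dosages, h2$dosages)
  expect_equal(h1$ploidy, "haploid")
  hom <- g$dosages != 1L
  expect_identical(h1$dosages[hom], as.integer(g$dosages[hom] / 2L))
  het <- which(g$dosages == 1L)
  frac <- mean(h1$dosages[het])
  expect_lt(abs(frac - 0.5), 3 * 0.5 / sqrt(length(het)))
  expect_error(pseudohaploidize(h1), "diploid")
})

test_that("pseudohaploid draws preserve per-site allele frequencies in
           expectation", {
  g <- small_panmictic()$genotypes
  set.seed(9)
  acc <- Reduce(`+`, lapply(1:30, function(i) pseudohaploidize(g)$dosages))
  p_hap <- colMeans(acc / 30)
  p_dip <- colMeans(g$dosages) / 2
  expect_equal(p_hap, p_dip, tolerance = 0.05)
})

test_that("depth corruption halves heterozygosity at rate 1/2 and the
           pseudohaploid pipeline is immune to it", {
  g <- small_panmictic()$genotypes
  expect_identical(depth_corruption(g, 0, seed = 1)$dosages, g$dosages)
  g1 <- depth_corruption(g, 1, seed = 1)
  expect_false(any(g1$dosages == 1L))
  g5 <- depth_corruption(g, 0.5, seed = 2)
  expect_equal(sum(g5$dosages == 1L) / sum(g$dosages == 1L), 0.5,
               tolerance = 0.03)
  # one pseudohaploid draw from corrupted data has the same distribution as a
  # draw from the truth: compare corrected delta2 of the two
  cfgl <- ld_config(seed = 7, max_sites_per_chrom = 800)
  s_true <- summarize_ld(pseudohaploidize(g, seed = 11), cfgl)
  s_corr <- summarize_ld(pseudohaploidize(g5, seed = 11), cfgl)
  expect_equal(s_corr$delta2_unlinked, s_true$delta2_unlinked,
               tolerance = 0.35)
  expect_equal(s_corr$delta2_weak, s_true$delta2_weak, tolerance = 0.25)
})

test_that("reps average on the log scale: one replicate is noisier than many", {
  g <- small_panmictic()$genotypes
  cfgl <- ld_config(seed = 7, max_sites_per_chrom = 600)
  est1 <- ne_pseudohaploid(g, reps = 2, config = cfgl, seed = 31)
  est2 <- ne_pseudohaploid(g, reps = 8, config = cfgl, seed = 31)
  expect_equal(nrow(est1$replicates), 2)
  expect_equal(nrow(est2$replicates), 8)
  # same estimand: geometric means agree within the replicate spread
  expect_equal(log(est1$Ne), log(est2$Ne), tolerance = 0.5)
})
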