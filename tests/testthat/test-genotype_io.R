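# readers, writers and coordinate handling

write_tiny_vcf <- function(path, extra_site = NULL) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "a", "b", "c", sep = "\t"),
    paste("chr1", 100, "s1", "A", "C", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("chr1", 200, "s2", "G", "T", ".", "PASS", ".", "GT",
          "0/1", "0/1", "1/0", sep = "\t"),
    extra_site)
  writeLines(lines, path)
  path
}

test_that("VCF genotypes are encoded as alt-allele dosages", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_tiny_vcf(f)
  g <- read_vcf(f, min_maf = 0)
  expect_equal(dim(g$dosages), c(3, 2))
  expect_equal(unname(g$dosages[, 1]), c(0L, 1L, 2L))
  expect_equal(g$sites$position_bp, c(100L, 200L))
})

test_that("multiallelic sites are dropped with a count", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_tiny_vcf(f, paste("chr1", 300, "s3", "A", "C,G", ".", "PASS", ".",
                          "GT", "0/1", "0/2", "1/2", sep = "\t"))
  expect_message(g <- read_vcf(f, min_maf = 0, verbose = TRUE),
                 "non-biallelic")
  expect_equal(ncol(g$dosages), 2)
})

test_that("haploid read of diploid calls fails loudly", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_tiny_vcf(f)
  expect_error(read_vcf(f, ploidy = "haploid", min_maf = 0), "haploid")
})

test_that("simulator VCF round trip preserves dosages, missingness and map", {
  g <- small_panmictic()$genotypes
  d <- g$dosages
  d[3, 7] <- NA_integer_
  g <- genotype_matrix(d, g$sites, "diploid")
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(g, f)
  g2 <- read_vcf(f, min_call_rate = 0, min_maf = 0)
  expect_identical(unname(g2$dosages), unname(g$dosages))
  expect_equal(g2$sites$position_cM, g$sites$position_cM, tolerance = 1e-6)
  expect_equal(g2$sites$chrom, g$sites$chrom)
})

test_that("TPED round trip preserves dosages up to allele orientation", {
  g <- small_panmictic()$genotypes
  pre <- withr::local_tempfile()
  write_tped(g, pre)
  g2 <- read_plink(paste0(pre, ".tped"), min_maf = 0)
  expect_equal(dim(g2$dosages), dim(g$dosages))
  # read_plink counts the minor allele, so sites may be flipped as a block
  same <- colSums(g2$dosages == g$dosages) == nrow(g$dosages)
  flip <- colSums(g2$dosages == 2L - g$dosages) == nrow(g$dosages)
  expect_true(all(same | flip))
  expect_equal(g2$sites$position_cM, g$sites$position_cM, tolerance = 1e-6)
})

test_that("toy PED+MAP reads, and an all-zero cM column means no map", {
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  writeLines(c("F1 i1 0 0 0 -9 A A A C",
               "F2 i2 0 0 0 -9 A C C C"), ped)
  writeLines(c("chr1 s1 0 1000", "chr1 s2 0 2000"), map)
  g <- read_plink(ped, map, min_maf = 0)
  expect_equal(dim(g$dosages), c(2, 2))
  expect_true(all(is.na(g$sites$position_cM)))
  # dosages count the minor allele at each site
  expect_equal(sort(as.vector(g$dosages[, 1])), c(0L, 1L))
})

test_that("PED/MAP row mismatch is an error", {
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  writeLines("F1 i1 0 0 0 -9 A A A C", ped)
  writeLines("chr1 s1 0 1000", map)
  expect_error(read_plink(ped, map), "MAP")
})

test_that("physical-to-genetic conversion uses cM/Mb and respects existing maps", {
  sites <- tibble::tibble(chrom = "chr1", position_bp = c(1e6, 1e7),
                          position_cM = NA_real_)
  g <- genotype_matrix(matrix(c(0L, 1L, 2L, 1L), 2), sites, "diploid")
  g1 <- assign_genetic_positions(g, 1)
  expect_equal(g1$sites$position_cM, c(1, 10))
  g2 <- assign_genetic_positions(g, 2.47)
  expect_equal(g2$sites$position_cM[2], 24.7)
  expect_error(assign_genetic_positions(g, 0))
  # existing positions kept unless overwrite = TRUE
  g3 <- assign_genetic_positions(g1, 5)
  expect_equal(g3$sites$position_cM, c(1, 10))
  g4 <- assign_genetic_positions(g1, 5, overwrite = TRUE)
  expect_equal(g4$sites$position_cM, c(5, 50))
})

test_that("call-rate and MAF filters drop the right sites", {
  d <- cbind(c(0L, 1L, 2L, 1L, NA, NA, NA, NA),   # call rate 0.5
             c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L),   # maf 1/16
             c(0L, 1L, 2L, 1L, 0L, 1L, 2L, 1L))   # clean
  g <- genotype_matrix(d, tibble::tibble(chrom = "chr1",
                                         position_bp = c(1e3, 2e3, 3e3)),
                       "diploid")
  out <- filter_sites(g, min_call_rate = 0.9, min_maf = 0.1)
  expect_equal(ncol(out$dosages), 1)
  expect_equal(out$sites$position_bp, 3000L)
})

test_that("dosage bounds and ploidy are validated", {
  sites <- tibble::tibble(chrom = "chr1", position_bp = c(1e3, 2e3))
  expect_error(genotype_matrix(matrix(c(0L, 3L, 1L, 1L), 2), sites, "diploid"),
               "dosages")
  expect_error(genotype_matrix(matrix(c(0L, 2L, 1L, 1L), 2), sites, "haploid"),
               "dosages")
})
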