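#' Genotype matrix container
#'
#' Bundles an individuals-by-sites allele-dosage matrix with per-site metadata
#' and a ploidy flag.  Dosages are counts of the alternate allele: 0/1/2 for
#' diploids, 0/1 for haploids; missing genotypes are `NA` and are never
#' imputed.  Site metadata is a tibble with columns `chrom`, `id`,
#' `position_bp` (1-based) and `position_cM` (`NA` when no genetic map is
#' available), plus `ref`/`alt` allele labels.
#'
#' @param dosages integer matrix, individuals in rows, sites in columns.
#' @param sites tibble of site metadata (one row per column of `dosages`).
#' @param ploidy `"diploid"` or `"haploid"`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, sites, ploidy = c("diploid", "haploid")) {
  ploidy <- match.arg(ploidy)
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  sites <- as_tibble(sites)
  stopifnot(ncol(dosages) == nrow(sites))
  needed <- c("chrom", "position_bp")
  if (!all(needed %in% names(sites)))
    abort("`sites` must contain columns 'chrom' and 'position_bp'")
  if (!"id" %in% names(sites))
    sites$id <- paste0(sites$chrom, "_", sites$position_bp)
  if (!"position_cM" %in% names(sites)) sites$position_cM <- NA_real_
  if (!"ref" %in% names(sites)) sites$ref <- "A"
  if (!"alt" %in% names(sites)) sites$alt <- "C"
  pmax_allowed <- if (ploidy == "diploid") 2L else 1L
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0L || rng[2] > pmax_allowed)
    abort(sprintf("dosages outside 0..%d for %s data", pmax_allowed, ploidy))
  if (any(colSums(!is.na(dosages)) == 0L))
    abort("every site must have at least one non-missing genotype")
  # enforce strictly increasing positions within chromosome
  ord <- order(factor(sites$chrom, levels = unique(sites$chrom)), sites$position_bp)
  if (is.unsorted(ord)) {
    sites <- sites[ord, ]
    dosages <- dosages[, ord, drop = FALSE]
  }
  structure(list(dosages = dosages, sites = sites, ploidy = ploidy),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d %s individuals x %d biallelic SNPs on %d chromosome(s)\n",
              nrow(x$dosages), x$ploidy, ncol(x$dosages),
              length(unique(x$sites$chrom))))
  cm <- !all(is.na(x$sites$position_cM))
  cat(sprintf("  genetic map: %s; missing genotypes: %d\n",
              if (cm) "present (cM)" else "absent",
              sum(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

n_individuals <- function(g) nrow(g$dosages)
n_sites <- function(g) ncol(g$dosages)

#' Per-site summary of a genotype matrix
#'
#' @param x a [genotype_matrix()].
#' @param ... unused.
#' @return A tibble with one row per site: allele frequency, minor allele
#'   frequency, call rate and observed heterozygosity (diploid only).
#' @method tidy genotype_matrix
#' @export
tidy.genotype_matrix <- function(x, ...) {
  d <- x$dosages
  p <- colMeans(d, na.rm = TRUE) / if (x$ploidy == "diploid") 2 else 1
  out <- x$sites
  out$freq_alt <- p
  out$maf <- pmin(p, 1 - p)
  out$call_rate <- colMeans(!is.na(d))
  out$het_obs <- if (x$ploidy == "diploid") colMeans(d == 1L, na.rm = TRUE) else NA_real_
  out
}

#' Filter sites on call rate, minor allele frequency and chromosome length
#'
#' Sites failing any criterion are dropped.  Defaults mirror common SNP-panel
#' hygiene: complete-ish genotyping (call rate >= 0.9) and MAF >= 0.01; the
#' chromosome length filter is off by default.
#'
#' @param g a [genotype_matrix()].
#' @param min_call_rate minimum fraction of non-missing genotypes per site.
#' @param min_maf minimum sample minor allele frequency.
#' @param min_chrom_mb drop whole chromosomes/scaffolds spanning less than
#'   this many Mb (0 = keep all).
#' @param verbose log counts of dropped sites.
#' @return A filtered [genotype_matrix()].
#' @export
filter_sites <- function(g, min_call_rate = 0.9, min_maf = 0.01,
                         min_chrom_mb = 0, verbose = FALSE) {
  d <- g$dosages
  cr <- colMeans(!is.na(d))
  p <- colMeans(d, na.rm = TRUE) / if (g$ploidy == "diploid") 2 else 1
  maf <- pmin(p, 1 - p)
  keep <- cr >= min_call_rate & maf >= min_maf
  if (min_chrom_mb > 0) {
    span <- tapply(g$sites$position_bp, g$sites$chrom, function(x) diff(range(x)))
    short <- names(span)[span < min_chrom_mb * 1e6]
    keep <- keep & !(g$sites$chrom %in% short)
  }
  if (verbose)
    message(sprintf("filter_sites: kept %d / %d sites (%d call-rate, %d MAF)",
                    sum(keep), length(keep), sum(cr < min_call_rate),
                    sum(maf < min_maf, na.rm = TRUE)))
  if (!any(keep)) abort("no sites left after filtering")
  genotype_matrix(d[, keep, drop = FALSE], g$sites[keep, ], g$ploidy)
}

#' Convert physical positions to genetic positions
#'
#' Approximates a genetic map from physical coordinates using a genome-wide
#' recombination rate: `position_cM = position_bp * rate / 1e6`.  Sites that
#' already carry a genetic position keep it unless `overwrite = TRUE`.
#'
#' @param g a [genotype_matrix()].
#' @param rate_cM_per_Mb recombination rate in cM/Mb (> 0).
#' @param overwrite replace existing cM positions too.
#' @return The genotype matrix with `position_cM` filled in.
#' @export
assign_genetic_positions <- function(g, rate_cM_per_Mb, overwrite = FALSE) {
  if (!is.numeric(rate_cM_per_Mb) || length(rate_cM_per_Mb) != 1 ||
      rate_cM_per_Mb <= 0)
    abort("`rate_cM_per_Mb` must be a single positive number")
  cm <- g$sites$position_cM
  fill <- if (overwrite) rep(TRUE, length(cm)) else is.na(cm)
  cm[fill] <- g$sites$position_bp[fill] * rate_cM_per_Mb / 1e6
  g$sites$position_cM <- cm
  g
}
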