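#' LD engine configuration
#'
#' Controls the pairwise composite-LD summary.  Pair enumeration is bounded by
#' per-chromosome site caps (uniform random subsamples beyond the cap) so the
#' cost stays quadratic in the cap, not in the SNP count.
#'
#' @param weak_c_min,weak_c_max recombination-fraction bounds of the "weakly
#'   linked" window on the same chromosome.  The lower bound keeps out pairs
#'   whose LD reflects older demography; the upper bound concentrates the
#'   window where the drift component still varies with c, which carries the
#'   N_T signal.
#' @param n_bins number of logarithmic recombination-fraction bins.
#' @param c_min lower edge of the smallest bin.
#' @param min_pairs bins with fewer pairs are merged upward.
#' @param max_sites_per_chrom cap on sites per chromosome for same-chromosome
#'   pairs.
#' @param max_cross_sites genome-wide cap on sites used for cross-chromosome
#'   (unlinked) pairs.
#' @param error_rate per-base genotyping error probability `epsilon`; when
#'   positive, covariances are deflated by `(1-4e(1-e))^2` and per-site
#'   variances inverted through `V' = V + e(1-4V)` before forming `W`.
#' @param seed RNG seed for site subsampling (NULL = leave RNG state alone).
#' @return A list of class `ld_config`.
#' @export
ld_config <- function(weak_c_min = 0.05, weak_c_max = 0.2, n_bins = 30,
                      c_min = 0.001, min_pairs = 100,
                      max_sites_per_chrom = 3000, max_cross_sites = Inf,
                      error_rate = 0, seed = NULL) {
  stopifnot(weak_c_min > 0, weak_c_min < weak_c_max, weak_c_max <= 0.5,
            error_rate >= 0, error_rate < 0.5)
  structure(list(weak_c_min = weak_c_min, weak_c_max = weak_c_max,
                 n_bins = n_bins, c_min = c_min,
                 min_pairs = min_pairs, max_sites_per_chrom = max_sites_per_chrom,
                 max_cross_sites = max_cross_sites, error_rate = error_rate,
                 seed = seed), class = "ld_config")
}

#' Map genetic distance to recombination fraction
#'
#' Uses Haldane's map function (no interference) within chromosomes,
#' `c = (1 - exp(-2 d_Morgans)) / 2`; pairs on different chromosomes recombine
#' freely at `c = 0.5`.
#'
#' @param d_cM genetic distance in centiMorgans (>= 0).
#' @param same_chromosome logical; FALSE forces c = 0.5.
#' @return Recombination fraction in `[0, 0.5]`.
#' @export
recombination_fraction <- function(d_cM, same_chromosome = TRUE) {
  if (any(d_cM < 0)) abort("negative genetic distance")
  cc <- (1 - exp(-2 * d_cM / 100)) / 2
  if (length(same_chromosome) == 1) {
    if (!same_chromosome) cc[] <- 0.5
    return(cc)
  }
  ifelse(same_chromosome, cc, 0.5)
}

# genotyping-error attenuation of covariances (see data_quality.R for the
# exported forward maps); factor applied to squared covariances
err_d2_factor <- function(epsilon) (1 - 4 * epsilon * (1 - epsilon))^2

# per-site gametic variance from sample frequency, unbiased, with optional
# inversion of the genotyping-error inflation V' = V + e(1 - 4V)
site_variance <- function(p_hat, n_obs, ploidy, epsilon = 0) {
  copies <- if (ploidy == "diploid") 2 * n_obs else n_obs
  v <- p_hat * (1 - p_hat) * copies / (copies - 1)
  if (epsilon > 0) v <- pmin(pmax((v - epsilon) / (1 - 4 * epsilon), 1e-9), 0.25)
  v
}

#' Composite (Burrows) pairwise LD for one pair of loci
#'
#' Computes the squared composite covariance of allele dosages on the
#' per-gamete scale (`D = cov(x, y)/2` for diploids, `cov(x, y)` for haploids)
#' and the product of per-locus gametic variances `W = V_i V_j` with
#' `V = p(1-p)`, from shared non-missing individuals.  Works on unphased data;
#' no phase information is used.
#'
#' @param x,y integer dosage vectors of equal length (NA = missing).
#' @param ploidy `"diploid"` or `"haploid"`.
#' @return A list with `D2`, `W`, `n` (shared individuals) and the observed
#'   genotype variances `sxx`, `syy` used by [correct_for_sampling()].
#' @export
composite_pair_ld <- function(x, y, ploidy = c("diploid", "haploid")) {
  ploidy <- match.arg(ploidy)
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 2) abort("need >= 2 shared non-missing individuals")
  x <- x[ok]; y <- y[ok]
  if (var(x) == 0 || var(y) == 0)
    return(list(D2 = NA_real_, W = NA_real_, n = n, sxx = NA_real_,
                syy = NA_real_, skipped = TRUE))
  k <- if (ploidy == "diploid") 2 else 1
  xc <- x - mean(x); yc <- y - mean(y)
  sxy <- sum(xc * yc) / n
  sxx <- sum(xc^2) / n; syy <- sum(yc^2) / n
  p1 <- mean(x) / k; p2 <- mean(y) / k
  V1 <- site_variance(p1, n, ploidy); V2 <- site_variance(p2, n, ploidy)
  list(D2 = (n / (n - 1))^2 * sxy^2 / k^2, W = V1 * V2, n = n,
       sxx = sxx, syy = syy, skipped = FALSE)
}

#' Finite-sample correction of a squared composite covariance
#'
#' Removes the expected pure-sampling inflation of `D^2` under sampling
#' individuals with replacement, so that truly independent loci have corrected
#' contribution 0 in expectation.  The subtraction equals the exact permutation
#' null `E[Sxy^2] = Sxx Syy / (n-1)` for centered vectors; genotype variances
#' default to their Hardy-Weinberg values `k V` when not supplied.
#'
#' @param d2_raw raw squared per-gamete covariance (as from
#'   [composite_pair_ld()]`$D2`).
#' @param w product of gametic variances `V_i V_j`.
#' @param n number of individuals (>= 4).
#' @param ploidy `"diploid"` or `"haploid"`.
#' @param sxx,syy observed genotype variances (denominator `n`); default
#'   `k^2 V` under Hardy-Weinberg with `k = ploidy`.
#' @return Corrected numerator contribution (same scale as `d2_raw`); divide
#'   summed numerators by summed `w` to get corrected delta-squared.
#' @export
correct_for_sampling <- function(d2_raw, w, n, ploidy = c("diploid", "haploid"),
                                 sxx = NULL, syy = NULL) {
  ploidy <- match.arg(ploidy)
  if (any(n < 4)) abort("need sample size n >= 4")
  k <- if (ploidy == "diploid") 2 else 1
  # HWE default: var(dosage) = k p(1-p), so sxx*syy = k^2 W
  if (is.null(sxx)) sxx <- k * sqrt(w)
  if (is.null(syy)) syy <- k * sqrt(w)
  d2_raw - (n / (n - 1))^2 * sxx * syy / ((n - 1) * k^2)
}

# block computation of corrected numerators and W for site sets A x B
# X: n x L dosage matrix (NA allowed); returns matrices over A x B
block_stats <- function(X, A, B, ploidy, epsilon = 0) {
  k <- if (ploidy == "diploid") 2 else 1
  XA <- X[, A, drop = FALSE]; XB <- X[, B, drop = FALSE]
  MA <- !is.na(XA); MB <- !is.na(XB)
  any_na <- !(all(MA) && all(MB))
  muA <- colMeans(XA, na.rm = TRUE); muB <- colMeans(XB, na.rm = TRUE)
  CA <- sweep(XA, 2, muA); CB <- sweep(XB, 2, muB)
  if (any_na) {
    CA[!MA] <- 0; CB[!MB] <- 0
    npair <- crossprod(MA + 0, MB + 0)
    Sxy <- crossprod(CA, CB) / npair
    Sxx <- crossprod(CA^2, MB + 0) / npair
    Syy <- crossprod(MA + 0, CB^2) / npair
  } else {
    n <- nrow(X)
    npair <- n
    Sxy <- crossprod(CA, CB) / n
    Sxx <- matrix(colSums(CA^2) / n, length(A), length(B))
    Syy <- matrix(colSums(CB^2) / n, length(A), length(B), byrow = TRUE)
  }
  num <- (npair / (npair - 1))^2 * (Sxy^2 - Sxx * Syy / (npair - 1)) / k^2
  if (epsilon > 0) num <- num / err_d2_factor(epsilon)
  nA <- colSums(MA); nB <- colSums(MB)
  VA <- site_variance(muA / k, nA, ploidy, epsilon)
  VB <- site_variance(muB / k, nB, ploidy, epsilon)
  W <- outer(VA, VB)
  if (any_na && any(npair < 4)) {
    # too few shared individuals: drop the pair from both sums
    num[npair < 4] <- 0
    W[npair < 4] <- 0
  }
  list(num = num, W = W)
}

#' Sample inbreeding coefficient
#'
#' Aggregate deficit of observed relative to expected heterozygosity,
#' `F = 1 - sum(H_obs) / sum(H_exp)`, over all polymorphic sites.  Under
#' internally panmictic subpopulations this approximates FST of the
#' metapopulation the sample was drawn from.
#'
#' @param g a diploid [genotype_matrix()].
#' @return A single numeric value in `[-1, 1]`.
#' @export
inbreeding_coefficient <- function(g) {
  if (g$ploidy != "diploid")
    abort("inbreeding coefficient is undefined for haploid data")
  f <- fhat_sums(g)
  1 - sum(f$h_obs) / sum(f$h_exp)
}

# per-chromosome heterozygosity sums (for jackknife)
fhat_sums <- function(g) {
  d <- g$dosages
  n_obs <- colSums(!is.na(d))
  p <- colMeans(d, na.rm = TRUE) / 2
  h_obs <- colMeans(d == 1L, na.rm = TRUE)
  h_exp <- 2 * p * (1 - p) * (2 * n_obs) / (2 * n_obs - 1)
  tibble(chrom = g$sites$chrom, h_obs = h_obs, h_exp = h_exp) %>%
    group_by(.data$chrom) %>%
    summarise(h_obs = sum(.data$h_obs), h_exp = sum(.data$h_exp),
              .groups = "drop")
}

bin_edges <- function(config) {
  e <- exp(seq(log(config$c_min), log(0.5), length.out = config$n_bins + 1))
  # snap the nearest interior edges to the weak-window boundaries so the weak
  # set is exactly a union of bins
  for (b in c(config$weak_c_min, config$weak_c_max)) {
    if (b >= 0.5) next
    i <- which.min(abs(e - b))
    i <- min(max(i, 2L), length(e) - 1L)
    e[i] <- b
  }
  e
}

#' Genome-wide composite-LD summary
#'
#' Computes sampling-corrected composite delta-squared for unlinked pairs
#' (different chromosomes, c = 0.5), for weakly linked pairs (same chromosome,
#' `weak_c_min < c < 0.5`) and per recombination-fraction bin, plus the sample
#' inbreeding coefficient.  All summaries are ratios of summed corrected
#' numerators to summed `W` (ratio of expectations, not mean of ratios).
#' Per-chromosome(-pair) partial sums are retained for chromosome jackknifing.
#'
#' @param g a [genotype_matrix()]; genetic positions (cM) are required for
#'   same-chromosome statistics (see [assign_genetic_positions()]).
#' @param config an [ld_config()].
#' @return An object of class `ld_summary`: observables `delta2_unlinked`,
#'   `delta2_weak`, `f_hat`, the bin table, and bookkeeping (`n`, `n_snps`,
#'   `ploidy`, pair tables).
#' @export
summarize_ld <- function(g, config = ld_config()) {
  if (!is.null(config$seed)) {
    old <- get0(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(config$seed)
  }
  d <- g$dosages
  n <- nrow(d)
  if (n < 4) abort("need at least 4 individuals")
  chroms <- unique(g$sites$chrom)
  has_map <- !all(is.na(g$sites$position_cM))
  if (length(chroms) < 2 && !has_map)
    abort("single chromosome without a genetic map: no LD summary possible")
  if (length(chroms) < 2)
    warn("single chromosome: unlinked (c = 0.5) summary unavailable")
  idx_by_chrom <- split(seq_len(ncol(d)), g$sites$chrom)[chroms]

  # site subsamples under the pair budget; cross-chromosome sites are a nested
  # subset of the linked-site subsample so that the shared between-deme LD
  # component cancels exactly in weak-vs-unlinked contrasts
  linked_idx <- lapply(idx_by_chrom, function(ii) {
    if (length(ii) > config$max_sites_per_chrom)
      sort(sample(ii, config$max_sites_per_chrom)) else ii
  })
  cross_cap <- max(2, config$max_cross_sites / length(chroms))
  cross_idx <- lapply(linked_idx, function(ii) {
    if (length(ii) > cross_cap) sort(sample(ii, round(cross_cap))) else ii
  })

  eps <- config$error_rate
  rows <- list()
  # cross-chromosome (unlinked) pairs
  if (length(chroms) >= 2) {
    for (a in seq_along(chroms)[-length(chroms)]) {
      for (b in seq((a + 1), length(chroms))) {
        bs <- block_stats(d, cross_idx[[a]], cross_idx[[b]], g$ploidy, eps)
        rows[[length(rows) + 1]] <- tibble(
          chr_a = chroms[a], chr_b = chroms[b], bin = 0L,
          sum_num = sum(bs$num), sum_w = sum(bs$W),
          n_pairs = length(bs$num), sum_c = 0.5 * length(bs$num),
          sum_inv_c = 2 * length(bs$num))
      }
    }
  }
  # same-chromosome pairs, binned by recombination fraction
  edges <- bin_edges(config)
  if (has_map) {
    for (a in seq_along(chroms)) {
      ii <- linked_idx[[a]]
      cm <- g$sites$position_cM[ii]
      ok <- !is.na(cm)
      ii <- ii[ok]; cm <- cm[ok]
      if (length(ii) < 2) next
      bs <- block_stats(d, ii, ii, g$ploidy, eps)
      cc <- recombination_fraction(abs(outer(cm, cm, "-")))
      ut <- upper.tri(cc)
      cv <- cc[ut]; numv <- bs$num[ut]; wv <- bs$W[ut]
      bi <- findInterval(cv, edges, rightmost.closed = TRUE)
      keep <- bi >= 1 & bi <= config$n_bins & cv > 0
      if (!any(keep)) next
      agg <- rowsum(cbind(numv, wv, 1, cv, 1 / cv)[keep, , drop = FALSE],
                    bi[keep])
      rows[[length(rows) + 1]] <- tibble(
        chr_a = chroms[a], chr_b = chroms[a],
        bin = as.integer(rownames(agg)),
        sum_num = agg[, 1], sum_w = agg[, 2], n_pairs = agg[, 3],
        sum_c = agg[, 4], sum_inv_c = agg[, 5])
    }
  }
  pair_table <- bind_rows(rows)
  if (nrow(pair_table) == 0) abort("no usable site pairs")
  f_by_chrom <- if (g$ploidy == "diploid") fhat_sums(g) else NULL
  out <- build_ld_summary(pair_table, f_by_chrom, n = n,
                          n_snps = ncol(d), ploidy = g$ploidy,
                          chroms = chroms, config = config)
  out
}

# assemble an ld_summary from the pair accumulator (shared with jackknife)
build_ld_summary <- function(pair_table, f_by_chrom, n, n_snps, ploidy,
                             chroms, config) {
  edges <- bin_edges(config)
  u <- dplyr::filter(pair_table, .data$bin == 0L)
  delta2_unlinked <- if (nrow(u)) sum(u$sum_num) / sum(u$sum_w) else NA_real_
  lk <- dplyr::filter(pair_table, .data$bin > 0L)
  first_weak_bin <- which(edges >= config$weak_c_min - 1e-12)[1]
  last_weak_bin <- which(edges >= config$weak_c_max - 1e-12)[1] - 1L
  if (is.na(last_weak_bin) || config$weak_c_max >= 0.5)
    last_weak_bin <- config$n_bins
  wk <- dplyr::filter(lk, .data$bin >= first_weak_bin,
                      .data$bin <= last_weak_bin)
  delta2_weak <- if (nrow(wk)) sum(wk$sum_num) / sum(wk$sum_w) else NA_real_
  bins <- if (nrow(lk)) {
    b <- lk %>% group_by(.data$bin) %>%
      summarise(sum_num = sum(.data$sum_num), sum_w = sum(.data$sum_w),
                n_pairs = sum(.data$n_pairs), sum_c = sum(.data$sum_c),
                sum_inv_c = sum(.data$sum_inv_c), .groups = "drop") %>%
      arrange(.data$bin)
    merge_small_bins(b, config$min_pairs)
  } else tibble()
  if (nrow(bins)) {
    bins <- bins %>% mutate(
      c_mean = .data$sum_c / .data$n_pairs,
      c_harm = .data$n_pairs / .data$sum_inv_c,
      delta2 = .data$sum_num / .data$sum_w) %>%
      select("bin", "c_mean", "c_harm", "delta2", "n_pairs", "sum_num", "sum_w")
  }
  f_hat <- if (!is.null(f_by_chrom)) 1 - sum(f_by_chrom$h_obs) / sum(f_by_chrom$h_exp)
           else NA_real_
  structure(list(
    delta2_unlinked = delta2_unlinked,
    delta2_weak = delta2_weak,
    bins = bins,
    f_hat = f_hat,
    n = n, n_snps = n_snps, ploidy = ploidy, chroms = chroms,
    n_pairs_unlinked = sum(u$n_pairs), n_pairs_weak = sum(wk$n_pairs),
    weak_profile = if (nrow(wk)) wk %>% group_by(.data$bin) %>%
      summarise(n_pairs = sum(.data$n_pairs), sum_w = sum(.data$sum_w),
                sum_c = sum(.data$sum_c), sum_inv_c = sum(.data$sum_inv_c),
                .groups = "drop") %>%
      mutate(c_harm = .data$n_pairs / .data$sum_inv_c,
             c_mean = .data$sum_c / .data$n_pairs) else tibble(),
    pair_table = pair_table,
    f_by_chrom = f_by_chrom,
    config = config), class = "ld_summary")
}

merge_small_bins <- function(b, min_pairs) {
  # merge bins with too few pairs into the next (larger-c) bin
  if (!nrow(b)) return(b)
  repeat {
    small <- which(b$n_pairs < min_pairs)
    if (!length(small) || nrow(b) == 1) break
    i <- small[1]
    j <- if (i < nrow(b)) i + 1L else i - 1L
    b[j, c("sum_num", "sum_w", "n_pairs", "sum_c", "sum_inv_c")] <-
      b[j, c("sum_num", "sum_w", "n_pairs", "sum_c", "sum_inv_c")] +
      b[i, c("sum_num", "sum_w", "n_pairs", "sum_c", "sum_inv_c")]
    b <- b[-i, ]
  }
  b
}

#' @export
print.ld_summary <- function(x, ...) {
  cat(sprintf("<ld_summary> n = %d %s individuals, %d SNPs, %d chromosome(s)\n",
              x$n, x$ploidy, x$n_snps, length(x$chroms)))
  cat(sprintf("  delta2 unlinked (c=0.5): %.6g   [%g pairs]\n",
              x$delta2_unlinked, x$n_pairs_unlinked))
  cat(sprintf("  delta2 weak (c>%g):      %.6g   [%g pairs]\n",
              x$config$weak_c_min, x$delta2_weak, x$n_pairs_weak))
  cat(sprintf("  inbreeding F-hat:        %.4g\n", x$f_hat))
  if (nrow(x$bins)) cat(sprintf("  %d recombination bins over c in [%.4g, 0.5]\n",
                                nrow(x$bins), min(x$bins$c_mean)))
  invisible(x)
}

#' Tidy the recombination-bin table of an LD summary
#'
#' @param x an `ld_summary`.
#' @param ... unused.
#' @return A tibble with one row per bin: mean and harmonic-mean recombination
#'   fraction, corrected delta-squared and pair count.
#' @method tidy ld_summary
#' @export
tidy.ld_summary <- function(x, ...) {
  if (!nrow(x$bins)) return(tibble())
  select(x$bins, "c_mean", "c_harm", "delta2", "n_pairs")
}

#' One-row overview of an LD summary
#'
#' @param x an `ld_summary`.
#' @param ... unused.
#' @return A one-row tibble of the three solver observables and sample sizes.
#' @method glance ld_summary
#' @export
glance.ld_summary <- function(x, ...) {
  tibble(delta2_unlinked = x$delta2_unlinked, delta2_weak = x$delta2_weak,
         f_hat = x$f_hat, n = x$n, n_snps = x$n_snps,
         n_chrom = length(x$chroms), ploidy = x$ploidy)
}

#' Plot the LD decay of an LD summary
#'
#' Corrected composite delta-squared per recombination bin on log-log axes,
#' with the unlinked (c = 0.5) point highlighted.
#'
#' @param object an `ld_summary`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot ld_summary
#' @export
autoplot.ld_summary <- function(object, ...) {
  b <- tidy(object)
  gg <- ggplot2::ggplot(b, ggplot2::aes(x = .data$c_mean, y = .data$delta2)) +
    ggplot2::geom_point() + ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "recombination fraction c",
                  y = expression(delta^2), title = "Composite LD decay")
  if (!is.na(object$delta2_unlinked) && object$delta2_unlinked > 0)
    gg <- gg + ggplot2::annotate("point", x = 0.5, y = object$delta2_unlinked,
                                 colour = "red", size = 2)
  gg
}

# jackknife: rebuild summaries with one chromosome deleted
delete_one_chrom_summaries <- function(obs) {
  lapply(obs$chroms, function(ch) {
    pt <- dplyr::filter(obs$pair_table, .data$chr_a != ch, .data$chr_b != ch)
    fb <- if (!is.null(obs$f_by_chrom))
      dplyr::filter(obs$f_by_chrom, .data$chrom != ch) else NULL
    build_ld_summary(pt, fb, n = obs$n, n_snps = obs$n_snps,
                     ploidy = obs$ploidy, chroms = setdiff(obs$chroms, ch),
                     config = obs$config)
  })
}
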