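#' Island-model simulation configuration
#'
#' Desk-scale defaults: 4 chromosomes of 100 cM (mapped to physical positions
#' at 1 cM/Mb), ~5000 segregating sites, per-deme size in the hundreds.  The
#' simulation runs in two phases: an allele-frequency-only island burn-in
#' (binomial drift + symmetric migration, run to migration-drift equilibrium)
#' followed by a genotype-phase Wright-Fisher forward simulation with
#' recombination that builds the linkage disequilibrium.  `generations` is the
#' genotype-phase length; the frequency burn-in length is chosen automatically
#' (about six relaxation times of FST) unless `freq_burnin` is given.
#'
#' @param s number of demes (1 = panmictic).
#' @param N per-deme diploid size (scalar, or vector of length `s` for unequal
#'   demes); for haploid simulations the number of haploid individuals.
#' @param m symmetric migration rate, `0 <= m <= (s-1)/s`.
#' @param chromosomes number of chromosomes.
#' @param chrom_length_cM genetic length of each chromosome.
#' @param n_sites target number of segregating sites available for sampling
#'   (the burn-in starts with a surplus; fixed/lost sites are discarded at the
#'   end of the frequency phase only).
#' @param mu per-site per-copy symmetric mutation rate during the genotype
#'   phase (0: standing variation only).
#' @param generations genotype-phase length; LD at recombination fraction c
#'   equilibrates within a few multiples of `1/(2c)` generations.
#' @param sample_n individuals sampled at the end.
#' @param sampling_weights per-deme sampling proportions (default: deme
#'   sizes).
#' @param ploidy `"diploid"` or `"haploid"`.
#' @param init_sfs initial allele-frequency distribution: `"uniform"` on
#'   (0.05, 0.95) or U-shaped `"beta"` (shape `4 N_T mu` when `mu > 0`,
#'   else 0.2).
#' @param freq_burnin frequency-phase generations (NULL = automatic).
#' @param schedule optional demographic schedule, see [demographic_event()].
#' @param maf_sample minimum sample MAF of emitted sites.
#' @param seed RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(s = 1, N = 500, m = 0, chromosomes = 4,
                       chrom_length_cM = 100, n_sites = 5000, mu = 0,
                       generations = 150, sample_n = 100,
                       sampling_weights = NULL,
                       ploidy = c("diploid", "haploid"),
                       init_sfs = c("uniform", "beta"), freq_burnin = NULL,
                       schedule = NULL, maf_sample = 0.01, seed = NULL) {
  ploidy <- match.arg(ploidy)
  init_sfs <- match.arg(init_sfs)
  N <- rep(as.integer(N), length.out = s)
  if (s > 1 && (m < 0 || m > (s - 1) / s)) abort("m outside [0, (s-1)/s]")
  if (!is.null(sampling_weights) && length(sampling_weights) != s)
    abort("sampling_weights must have one entry per deme")
  if (sample_n > sum(N)) abort("sample_n exceeds the number of individuals")
  structure(list(s = s, N = N, m = m, chromosomes = chromosomes,
                 chrom_length_cM = chrom_length_cM, n_sites = n_sites,
                 mu = mu, generations = generations, sample_n = sample_n,
                 sampling_weights = sampling_weights, ploidy = ploidy,
                 init_sfs = init_sfs, freq_burnin = freq_burnin,
                 schedule = schedule, maf_sample = maf_sample, seed = seed,
                 return_haplotypes = FALSE),
            class = "sim_config")
}

#' Add a demographic step change to a simulation configuration
#'
#' Deme sizes switch to `N` for all generations from `time_ago` generations
#' before sampling up to the present (later events override earlier ones in
#' the affected window).  The four canonical profiles -- constant, recent
#' decline, recent expansion, bottleneck -- are all expressible as one or two
#' events.
#'
#' @param config a [sim_config()].
#' @param time_ago generations before sampling at which the new size takes
#'   effect (must be within the genotype phase).
#' @param N new per-deme size (scalar or per-deme vector).
#' @return The updated configuration.
#' @export
demographic_event <- function(config, time_ago, N) {
  stopifnot(inherits(config, "sim_config"))
  if (time_ago < 0 || time_ago >= config$generations)
    abort("event time outside the simulated generations")
  sched <- config$schedule
  if (!is.null(sched) && any(sched$time_ago <= time_ago))
    abort("schedule must be added in decreasing time_ago order")
  config$schedule <- bind_rows(sched,
    tibble(time_ago = time_ago, N = list(rep(as.integer(N),
                                             length.out = config$s))))
  config
}

# per-generation deme-size matrix for the genotype phase
deme_size_matrix <- function(config) {
  Tg <- config$generations
  sz <- matrix(rep(config$N, Tg), nrow = config$s)
  if (!is.null(config$schedule)) {
    for (i in seq_len(nrow(config$schedule))) {
      ta <- config$schedule$time_ago[i]
      newN <- config$schedule$N[[i]]
      # forward generation j has time_ago = Tg - j
      sz[, (Tg - ta):Tg] <- newN
    }
  }
  sz
}

#' Simulate genotypes under the island model
#'
#' Discrete-generation Wright-Fisher forward simulation with random mating
#' within demes (selfing allowed), symmetric island migration, Haldane
#' (interference-free) recombination and optional symmetric mutation;
#' equilibrium allele-frequency structure is produced by a frequency-phase
#' burn-in (see [sim_config()]).  Returns the sampled genotypes and the
#' ground truth needed by oracle tests.
#'
#' @param config a [sim_config()].
#' @return A list with `genotypes` (a [genotype_matrix()]) and `truth` (class
#'   `sim_truth`): realized FST from full-population deme frequencies, `N_T`,
#'   per-deme allele frequencies, deme of origin of each sampled individual
#'   and the configuration echo.
#' @export
simulate_island <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  s <- config$s; m <- config$m
  ploidy_k <- if (config$ploidy == "diploid") 2L else 1L
  copies <- config$N * ploidy_k          # haplotypes per deme
  L0 <- ceiling(config$n_sites * 1.6)
  # initial allele frequencies
  p0 <- switch(config$init_sfs,
    uniform = runif(L0, 0.05, 0.95),
    beta = {
      sh <- if (config$mu > 0) 4 * sum(config$N) * config$mu else 0.2
      pmin(pmax(rbeta(L0, sh, sh), 0.01), 0.99)
    })
  p <- matrix(rep(p0, each = s), s, L0)
  # frequency-phase burn-in to migration-drift equilibrium
  Tf <- config$freq_burnin
  if (is.null(Tf)) {
    Tf <- if (s == 1) 0L else {
      rate <- 2 * m * s / (s - 1) + 1 / mean(copies)
      as.integer(min(10000, ceiling(6 / rate)))
    }
  }
  if (Tf > 0) {
    for (g in seq_len(Tf)) {
      if (s > 1) {
        pbar_other <- (matrix(colSums(p), s, L0, byrow = TRUE) - p) / (s - 1)
        pm <- (1 - m) * p + m * pbar_other
      } else pm <- p
      p <- matrix(rbinom(s * L0, rep(copies, L0), as.vector(pm)), s, L0) /
        rep(copies, L0)
    }
  }
  pbar <- colSums(p * copies) / sum(copies)
  keep <- which(pbar > 0 & pbar < 1)
  if (length(keep) > config$n_sites) keep <- sort(sample(keep, config$n_sites))
  if (length(keep) < 50) abort("too few segregating sites after burn-in")
  p <- p[, keep, drop = FALSE]
  L <- ncol(p)
  # site coordinates: chromosomes of chrom_length_cM, physical map at 1 cM/Mb
  per <- diff(floor(seq(0, L, length.out = config$chromosomes + 1)))
  chrom <- rep(seq_len(config$chromosomes), per)
  bp <- unlist(lapply(per, function(k)
    sort(sample.int(round(config$chrom_length_cM * 1e6), k))))
  pos_M <- bp / 1e8          # 1 cM/Mb: Morgans = bp / 1e8
  chrom_start <- c(0L, cumsum(per))
  # initial haplotypes: linkage equilibrium within demes
  H0 <- matrix(as.raw(0), L, sum(copies))
  off <- c(0L, cumsum(copies))
  for (d in seq_len(s)) {
    cols <- (off[d] + 1):off[d + 1]
    H0[, cols] <- as.raw(rbinom(L * copies[d], 1, rep(p[d, ], times = copies[d])))
  }
  sz <- deme_size_matrix(config)
  H <- forward_wf_cpp(H0, pos_M, as.integer(chrom_start),
                      rep(config$chrom_length_cM / 100, config$chromosomes),
                      matrix(as.integer(sz), nrow = s), as.integer(config$N),
                      m, ploidy_k, config$mu)
  final_N <- sz[, ncol(sz)]
  final_copies <- final_N * ploidy_k
  # truth: deme frequencies and realized FST from the full final population
  offc <- c(0L, cumsum(final_copies))
  deme_freq <- t(vapply(seq_len(s), function(d)
    rowMeans(matrix(as.integer(H[, (offc[d] + 1):offc[d + 1]]), nrow = L)),
    numeric(L)))
  pb <- colSums(deme_freq * final_copies) / sum(final_copies)
  poly <- pb > 0 & pb < 1
  fst_real <- if (s > 1) {
    num <- colSums((deme_freq[, poly, drop = FALSE] -
                      matrix(pb[poly], s, sum(poly), byrow = TRUE))^2) / s
    sum(num) / sum(pb[poly] * (1 - pb[poly]))
  } else 0
  # sample individuals
  deme_of_ind <- rep(seq_len(s), final_N)
  wts <- config$sampling_weights
  if (is.null(wts)) wts <- final_N / sum(final_N)
  wts <- wts / sum(wts)
  n_d <- floor(config$sample_n * wts)
  rem <- config$sample_n - sum(n_d)
  if (rem > 0) {
    extra <- order(config$sample_n * wts - n_d, decreasing = TRUE)[seq_len(rem)]
    n_d[extra] <- n_d[extra] + 1L
  }
  n_d <- pmin(n_d, final_N)
  ids <- unlist(lapply(seq_len(s), function(d)
    sample(which(deme_of_ind == d), n_d[d])))
  dos <- matrix(0L, length(ids), L)
  for (k in seq_along(ids)) {
    i <- ids[k]
    cols <- ((i - 1) * ploidy_k + 1):(i * ploidy_k)
    dos[k, ] <- as.integer(rowSums(matrix(as.integer(H[, cols]), nrow = L)))
  }
  sites <- tibble(chrom = paste0("chr", chrom),
                  id = paste0("snp", seq_len(L)),
                  position_bp = as.integer(bp), position_cM = pos_M * 100,
                  ref = "A", alt = "C")
  g <- genotype_matrix(dos, sites, config$ploidy)
  # drop sites rare or monomorphic in the sample
  keep2 <- {
    pf <- colMeans(g$dosages) / ploidy_k
    pmin(pf, 1 - pf) >= config$maf_sample
  }
  g <- genotype_matrix(g$dosages[, keep2, drop = FALSE], g$sites[keep2, ],
                       config$ploidy)
  truth <- structure(list(
    F_ST = fst_real, N_T = sum(final_N), deme_freq = deme_freq[, keep2,
                                                               drop = FALSE],
    deme_of_sample = deme_of_ind[ids], config = config,
    sites_kept = which(keep2)), class = "sim_truth")
  if (isTRUE(config$return_haplotypes)) {
    truth$haplotypes <- H[keep2, , drop = FALSE]
    truth$hap_copies_per_deme <- final_copies
  }
  list(genotypes = g, truth = truth)
}

#' Inject symmetric genotyping errors
#'
#' Every allele copy flips to the other allele independently with probability
#' `epsilon` (the simulator-side counterpart of the corrections in
#' [attenuate_covariance()] and [inflate_variance()]).
#'
#' @param g a [genotype_matrix()].
#' @param epsilon per-base error probability.
#' @param seed optional seed (caller's RNG state restored).
#' @return The corrupted genotype matrix.
#' @export
inject_errors <- function(g, epsilon, seed = NULL) {
  check_epsilon(epsilon)
  if (epsilon == 0) return(g)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  k <- if (g$ploidy == "diploid") 2L else 1L
  d <- g$dosages
  ok <- !is.na(d)
  d[ok] <- rbinom(sum(ok), d[ok], 1 - epsilon) +
    rbinom(sum(ok), k - d[ok], epsilon)
  genotype_matrix(d, g$sites, g$ploidy)
}

#' Convert heterozygotes to homozygotes (low-depth corruption)
#'
#' Each heterozygote independently becomes `0` or `2` (equal probability)
#' with probability `rate`; `rate = 1/2` roughly emulates 2x sequencing
#' depth.
#'
#' @param g a diploid [genotype_matrix()].
#' @param rate corruption probability per heterozygous call.
#' @param seed optional seed (caller's RNG state restored).
#' @return The corrupted genotype matrix.
#' @export
depth_corruption <- function(g, rate = 0.5, seed = NULL) {
  if (g$ploidy != "diploid") abort("depth corruption applies to diploid data")
  if (rate < 0 || rate > 1) abort("rate must be in [0, 1]")
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  d <- g$dosages
  het <- which(d == 1L)
  hit <- het[runif(length(het)) < rate]
  d[hit] <- 2L * rbinom(length(hit), 1L, 0.5)
  genotype_matrix(d, g$sites, g$ploidy)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> s = %d deme(s), N_T = %d, realized F_ST = %.4g\n",
              nrow(x$deme_freq), x$N_T, x$F_ST))
  invisible(x)
}
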