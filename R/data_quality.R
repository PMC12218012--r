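#' Expected covariance attenuation under genotyping error
#'
#' A symmetric per-read error `epsilon` replaces one allele by the other,
#' creating a covariance of opposite sign; the net expectation is
#' `D' = D (1 - 4 epsilon (1 - epsilon))`.
#'
#' @param D true covariance.
#' @param epsilon per-base genotyping error probability in `[0, 0.5]`.
#' @return Expected post-genotyping covariance.
#' @export
attenuate_covariance <- function(D, epsilon) {
  check_epsilon(epsilon)
  D * (1 - 4 * epsilon * (1 - epsilon))
}

#' Expected variance inflation under genotyping error
#'
#' `V' = V + epsilon (1 - 4V)`; the maximal variance `V = 1/4` (p = 1/2) is a
#' fixed point of the error process.
#'
#' @param V true gametic variance `p(1-p)` in `[0, 0.25]`.
#' @param epsilon per-base genotyping error probability.
#' @return Expected post-genotyping variance.
#' @export
inflate_variance <- function(V, epsilon) {
  check_epsilon(epsilon)
  if (any(V < 0) || any(V > 0.25)) abort("V must be in [0, 0.25]")
  V + epsilon * (1 - 4 * V)
}

check_epsilon <- function(epsilon) {
  if (any(epsilon < 0) || any(epsilon > 0.5))
    abort("epsilon must be in [0, 0.5]")
}

#' Invert the genotyping-error maps on observed LD components
#'
#' Exact algebraic inverse of [attenuate_covariance()] and
#' [inflate_variance()]: `D^2 = D'^2 / (1 - 4e(1-e))^2` and
#' `V = (V' - e) / (1 - 4e)`.  When only the product `w_obs = V'_i V'_j` is
#' available the two variances are taken equal (`sqrt(w_obs)` each); supply
#' `v1`/`v2` for the exact asymmetric inversion.
#'
#' @param d2_obs observed squared covariance.
#' @param w_obs observed product of variances (used when `v1`/`v2` absent).
#' @param epsilon error probability, strictly below 0.5.
#' @param v1,v2 optional observed per-locus variances.
#' @return A list with corrected `d2` and `w`.
#' @export
correct_observed_ld <- function(d2_obs, w_obs = NULL, epsilon,
                                v1 = NULL, v2 = NULL) {
  check_epsilon(epsilon)
  if (any(epsilon >= 0.5)) abort("epsilon = 0.5 destroys all signal; not invertible")
  d2 <- d2_obs / (1 - 4 * epsilon * (1 - epsilon))^2
  if (is.null(v1) || is.null(v2)) {
    if (is.null(w_obs)) abort("supply w_obs or both v1 and v2")
    v1 <- v2 <- sqrt(w_obs)
  }
  inv_v <- function(v) (v - epsilon) / (1 - 4 * epsilon)
  r1 <- inv_v(v1); r2 <- inv_v(v2)
  clip <- r1 < 0 | r1 > 0.25 | r2 < 0 | r2 > 0.25
  if (any(clip)) {
    warn("recovered variance outside [0, 0.25]; clipped")
    r1 <- pmin(pmax(r1, 0), 0.25); r2 <- pmin(pmax(r2, 0), 0.25)
  }
  list(d2 = d2, w = r1 * r2)
}

#' Draw pseudohaploid genomes from diploid genotypes
#'
#' Picks one allele at random at every heterozygous site of every individual
#' (homozygotes map deterministically 0 -> 0, 2 -> 1).  Because a depth-limited
#' sequencer that miscalls a heterozygote as a homozygote picks one allele at
#' random too, a pseudohaploid draw from depth-corrupted data has the same
#' distribution as a draw from the truth, which is what makes the low-depth
#' correction work.
#'
#' @param g a diploid [genotype_matrix()].
#' @param seed optional integer seed (bit-identical output for a fixed seed;
#'   the caller's RNG state is restored).
#' @return A haploid [genotype_matrix()] with the same sites.
#' @export
pseudohaploidize <- function(g, seed = NULL) {
  if (g$ploidy != "diploid") abort("pseudohaploidization needs diploid input")
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  d <- g$dosages
  h <- d
  h[d == 2L] <- 1L
  het <- which(d == 1L)
  h[het] <- rbinom(length(het), 1L, 0.5)
  genotype_matrix(h, g$sites, "haploid")
}

#' Contemporary Ne from repeated pseudohaploid draws
#'
#' Runs a haploid-scale estimator on `reps` independent pseudohaploid copies
#' of the sample and combines the replicate estimates by geometric mean
#' (Ne is a log-scale quantity).  The default estimator inverts the
#' pseudohaploid observable model (the diploid composite observable divided
#' by 4, see [expected_delta2_observed()]) for the unlinked and weak
#' observables, so the returned value is on the diploid Ne scale.  Robust to
#' depth-dependent heterozygote miscalls, see [pseudohaploidize()].
#'
#' @param g a diploid [genotype_matrix()].
#' @param reps number of pseudohaploid replicates (default 50).
#' @param estimator function mapping a haploid `ld_summary` to a named or
#'   unnamed numeric vector; default: pseudohaploid-scale [ne_panmictic()].
#' @param config an [ld_config()] (a fixed subsampling seed is set so that
#'   replicates share site subsets).
#' @param seed seed for the allele draws.
#' @return An `ne_estimate` whose `Ne` is the geometric mean (first element
#'   when the estimator returns a vector); replicate values in `$replicates`.
#' @export
ne_pseudohaploid <- function(g, reps = 50, estimator = NULL,
                             config = ld_config(seed = 1), seed = NULL) {
  if (g$ploidy != "diploid") abort("pseudohaploid correction needs diploid input")
  if (is.null(estimator))
    estimator <- function(o) ne_panmictic(o, model = "pseudohaploid")$Ne
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  vals <- lapply(seq_len(reps), function(r) {
    h <- pseudohaploidize(g)
    estimator(summarize_ld(h, config))
  })
  mat <- do.call(rbind, vals)
  gm <- exp(colMeans(log(mat)))
  structure(list(Ne = gm[[1]], estimates = gm, replicates = mat,
                 ci = c(NA_real_, NA_real_), level = NA_real_,
                 basis = "pseudohaploid", model = "pseudohaploid",
                 n = nrow(g$dosages), n_snps = ncol(g$dosages), reps = reps),
            class = "ne_estimate")
}
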