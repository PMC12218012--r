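#' Expected within-subpopulation LD component
#'
#' Equilibrium expectation of the within-deme component of delta-squared for a
#' metapopulation with total size `N_T` and differentiation `F_ST`:
#' `(1-F_ST)^2 (1+c^2) / (2 N_T (1-(1-c)^2) + 2.2 (1-c)^2)`.
#' With `F_ST = 0` this is the panmictic drift-LD expectation.
#'
#' @param c recombination fraction, `0 < c <= 0.5`.
#' @param N_T summed effective size of all subpopulations (> 0).
#' @param F_ST differentiation index in `[0, 1)` (or 1, giving 0).
#' @return Expected gametic-scale delta-squared.
#' @export
expected_delta2_within <- function(c, N_T, F_ST = 0) {
  stopifnot(all(c > 0), all(c <= 0.5), all(N_T > 0),
            all(F_ST >= 0), all(F_ST <= 1))
  (1 - F_ST)^2 * (1 + c^2) / (2 * N_T * (1 - (1 - c)^2) + 2.2 * (1 - c)^2)
}

#' Expected between-subpopulation LD component
#'
#' `F_ST^2 / (s - 1)`: the Wahlund-type LD created by pooling `s`
#' differentiated demes, independent of recombination.
#'
#' @param F_ST differentiation index in `[0, 1]`.
#' @param s number of subpopulations (>= 2).
#' @return Expected gametic-scale between component.
#' @export
expected_delta2_between <- function(F_ST, s) {
  if (any(s < 2)) abort("between component requires s >= 2")
  F_ST^2 / (s - 1)
}

#' Expected between-within LD cross component
#'
#' `(s/(s-1))^2 d2_b m / (1 - (1 - (s/(s-1)) m)^2 (1-c))` with
#' `d2_b = F_ST^2/(s-1)`; enters the total with a factor 2.
#'
#' @param c recombination fraction, `0 < c <= 0.5`.
#' @param F_ST differentiation index.
#' @param s number of subpopulations (>= 2).
#' @param m migration rate in `[0, (s-1)/s]`.
#' @return Expected gametic-scale cross component.
#' @export
expected_delta2_between_within <- function(c, F_ST, s, m) {
  if (any(s < 2)) abort("between-within component requires s >= 2")
  if (any(m < 0) || any(m > (s - 1) / s)) abort("m outside [0, (s-1)/s]")
  stopifnot(all(c > 0), all(c <= 0.5))
  d2b <- F_ST^2 / (s - 1)
  denom <- 1 - (1 - s / (s - 1) * m)^2 * (1 - c)
  if (any(denom <= 0)) abort("non-positive denominator in between-within component")
  (s / (s - 1))^2 * d2b * m / denom
}

#' Equilibrium island-model FST
#'
#' Finite-island closed form `F_ST = 1 / (1 + 4 N m alpha)` with
#' `alpha = (s/(s-1))^2`, monotone decreasing in `N` and `m`; `m = 0` gives 1
#' (complete isolation), `N m -> Inf` gives 0 (effective panmixia).
#'
#' @param N subpopulation (deme) effective size (> 0).
#' @param m migration rate in `[0, (s-1)/s]`.
#' @param s number of subpopulations (>= 2).
#' @return Equilibrium `F_ST` in `[0, 1]`.
#' @export
takahata_fst <- function(N, m, s) {
  if (any(s < 2)) abort("island-model FST requires s >= 2")
  if (any(m < 0) || any(m > (s - 1) / s)) abort("m outside [0, (s-1)/s]")
  stopifnot(all(N > 0))
  alpha <- (s / (s - 1))^2
  1 / (1 + 4 * N * m * alpha)
}

#' Total expected LD in the island model
#'
#' Sum of the three components, `d2_w + d2_b + 2 d2_bw`, with `F_ST` computed
#' internally from [takahata_fst()] and `N_T = s N`.  With `s = 1` this reduces
#' to the panmictic within component.
#'
#' @param c recombination fraction, `0 < c <= 0.5`.
#' @param N deme effective size.
#' @param s number of subpopulations (>= 1).
#' @param m migration rate (ignored when `s = 1`).
#' @return Expected gametic-scale total delta-squared.
#' @export
expected_delta2_total <- function(c, N, s, m = 0) {
  if (any(s < 1)) abort("s must be >= 1")
  if (all(s == 1)) return(expected_delta2_within(c, N, 0))
  F_ST <- takahata_fst(N, m, s)
  expected_delta2_within(c, s * N, F_ST) +
    expected_delta2_between(F_ST, s) +
    2 * expected_delta2_between_within(c, F_ST, s, m)
}

#' Metapopulation effective size from total size and FST
#'
#' `N_e = N_T / (1 - F_ST)`: differentiation slows drift for the pooled
#' metapopulation, so `N_e >= N_T` with equality only under panmixia.
#'
#' @param N_T summed effective size of subpopulations.
#' @param F_ST differentiation index in `[0, 1)`.
#' @return Metapopulation effective size.
#' @export
metapop_ne <- function(N_T, F_ST) {
  if (any(F_ST >= 1) || any(F_ST < 0)) abort("F_ST must be in [0, 1)")
  N_T / (1 - F_ST)
}

#' Expected composite delta-squared as observed from a finite sample
#'
#' The sampling-corrected composite (Burrows) delta-squared computed from
#' unphased genotypes differs from the gametic-scale expectations of
#' [expected_delta2_total()] in three documented ways: (i) both homologs of an
#' individual carry the deme-of-origin deviation, so the between and
#' between-within components enter with weight 4 rather than 1 and 2;
#' (ii) random pairing of gametes into individuals adds
#' `(1-F_ST)^2 / (2 N_c)` where `N_c` is the census number of individuals;
#' (iii) a sample of `n` individuals drawn without replacement makes the
#' with-replacement sampling correction over-subtract by
#' `(n / N_c) (1+F_ST)^2 / (n-1)`.  This function returns the full observable
#' model used by the estimators.  For haploid data there is no pairing term
#' and the drift expectation is `1 / (N_h (1-(1-c)^2) + 2.2 (1-c)^2)` on the
#' haploid scale `N_h`, calibrated against haploid Wright-Fisher simulation.
#' Pseudohaploid data (one allele drawn per site per individual) halve the
#' composite covariance, so their observable is the diploid model over 4.
#'
#' @param c recombination fraction.
#' @param N deme effective size (haploid count for `model = "haploid"`).
#' @param s number of subpopulations.
#' @param m migration rate.
#' @param n number of sampled individuals (haplotypes for haploid data).
#' @param model `"diploid"` (composite genotypes), `"haploid"` (true haploid
#'   population) or `"pseudohaploid"` (per-site random allele draws from a
#'   diploid sample; the observable is the diploid one divided by 4).
#' @param census census number of individuals; defaults to `s * N` (ideal
#'   Wright-Fisher, Ne = census).
#' @return Expected value of the sampling-corrected observable.
#' @export
expected_delta2_observed <- function(c, N, s = 1, m = 0, n,
                                     model = c("diploid", "haploid",
                                               "pseudohaploid"),
                                     census = NULL) {
  model <- match.arg(model)
  F_ST <- if (s >= 2) takahata_fst(N, m, s) else 0
  N_T <- s * N
  if (model == "haploid") {
    # N is the haploid population size here
    drift <- 1 / (N_T * (1 - (1 - c)^2) + 2.2 * (1 - c)^2)
    if (s >= 2) drift <- drift * (1 - F_ST)^2 +
        expected_delta2_between(F_ST, s) +
        2 * expected_delta2_between_within(c, F_ST, s, m)
    return(drift - min(n / N_T, 1) / (n - 1))
  }
  if (model == "pseudohaploid") {
    # independent per-site allele draws halve the composite covariance, so
    # the pseudohaploid observable is the diploid composite observable / 4
    # (including its pairing and without-replacement terms)
    return(expected_delta2_observed(c, N, s, m, n, "diploid", census) / 4)
  }
  if (is.null(census)) census <- N_T
  base <- expected_delta2_within(c, N_T, F_ST)
  if (s >= 2) base <- base + 4 * expected_delta2_between(F_ST, s) +
      4 * expected_delta2_between_within(c, F_ST, s, m)
  base + (1 - F_ST)^2 / (2 * census) -
    min(n / census, 1) * (1 + F_ST)^2 / (n - 1)
}
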