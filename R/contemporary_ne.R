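# inversion of the observable model for a panmictic population -------------

# predicted observable at one c for panmictic N (model-dependent scale)
predict_pan_point <- function(N, c, n, model, census = NULL,
                              sampling_bias = TRUE) {
  if (!sampling_bias) {
    if (model == "haploid")
      return(1 / (N * (1 - (1 - c)^2) + 2.2 * (1 - c)^2))
    return(expected_delta2_within(c, N, 0))
  }
  expected_delta2_observed(c, N, s = 1, m = 0, n = n, model = model,
                           census = census)
}

# predicted weak-window observable: pair-weighted average over the weak bins
predict_pan_weak <- function(N, profile, n, model, census = NULL,
                             sampling_bias = TRUE) {
  w <- profile$sum_w
  p <- vapply(profile$c_harm, function(cc)
    predict_pan_point(N, cc, n, model, census, sampling_bias), numeric(1))
  sum(w * p) / sum(w)
}

# invert a monotone-decreasing prediction for N on a log grid
invert_for_n <- function(target, pred_fun, lo = 2, hi = 1e9) {
  f <- function(x) pred_fun(exp(x)) - target
  flo <- f(log(lo)); fhi <- f(log(hi))
  if (flo <= 0) return(lo)          # more LD than N = lo predicts
  if (fhi >= 0) return(Inf)         # at/below the sampling floor
  exp(uniroot(f, c(log(lo), log(hi)), tol = 1e-12)$root)
}

#' Contemporary Ne assuming panmixia
#'
#' Inverts the drift-LD expectation for the corrected delta-squared of
#' unlinked site pairs (c = 0.5), of weakly linked pairs, or both (geometric
#' mean on the log scale).  With `sampling_bias = TRUE` (default) the
#' observable model of [expected_delta2_observed()] is inverted, accounting
#' for gamete pairing and without-replacement sampling; with
#' `sampling_bias = FALSE` and the `"pseudohaploid"` model the inversion is the
#' exact algebraic inverse of [expected_delta2_within()] at `F_ST = 0`.
#'
#' @param obs an `ld_summary` from [summarize_ld()].
#' @param basis which observable(s) to invert.
#' @param model observable scale; `"auto"` picks `"diploid"` for diploid
#'   summaries and `"haploid"` for haploid ones (see
#'   [expected_delta2_observed()]).
#' @param census census population size for the pairing/sampling terms
#'   (default: equal to the estimated Ne, solved self-consistently).
#' @param sampling_bias include the O(1/N) observable bias terms.
#' @param ci compute a delete-one-chromosome jackknife confidence interval.
#' @param level confidence level for the interval.
#' @return An object of class `ne_estimate` with elements `Ne`, `ci`, `basis`.
#' @export
ne_panmictic <- function(obs, basis = c("combined", "unlinked", "weak"),
                         model = c("auto", "diploid", "haploid",
                                   "pseudohaploid"),
                         census = NULL, sampling_bias = TRUE,
                         ci = FALSE, level = 0.90) {
  basis <- match.arg(basis)
  model <- match.arg(model)
  if (model == "auto")
    model <- if (obs$ploidy == "diploid") "diploid" else "haploid"
  est_fun <- function(o) {
    vals <- c()
    if (basis %in% c("combined", "unlinked")) {
      d2u <- o$delta2_unlinked
      if (is.na(d2u)) abort("no unlinked (cross-chromosome) pairs in summary")
      vals <- c(vals, invert_for_n(d2u, function(N)
        predict_pan_point(N, 0.5, o$n, model, census, sampling_bias)))
    }
    if (basis %in% c("combined", "weak")) {
      if (is.na(o$delta2_weak) || !nrow(o$weak_profile))
        abort("no weakly linked pairs in summary (genetic map required)")
      vals <- c(vals, invert_for_n(o$delta2_weak, function(N)
        predict_pan_weak(N, o$weak_profile, o$n, model, census, sampling_bias)))
    }
    if (any(is.infinite(vals))) return(Inf)
    exp(mean(log(vals)))
  }
  ne <- est_fun(obs)
  if (is.infinite(ne))
    warn("corrected delta-squared at or below the sampling floor: Ne unbounded above")
  interval <- c(NA_real_, NA_real_)
  if (ci && is.finite(ne))
    interval <- confidence_interval(obs, est_fun, level = level)
  structure(list(Ne = ne, ci = interval, level = level, basis = basis,
                 model = model, n = obs$n, n_snps = obs$n_snps),
            class = "ne_estimate")
}

#' Delete-one-chromosome jackknife confidence interval
#'
#' Recomputes a statistic of an LD summary with each chromosome left out in
#' turn and forms a jackknife interval on the log scale.  Chromosome deletion
#' respects the LD correlation structure (pairs involving the deleted
#' chromosome disappear from every summary component).
#'
#' @param obs an `ld_summary` built by [summarize_ld()] (its per-chromosome
#'   pair tables are reused, nothing is recomputed from genotypes).
#' @param statistic function mapping an `ld_summary` to a positive scalar.
#' @param level confidence level (default 0.90).
#' @return Numeric vector `c(low, high)`.
#' @export
confidence_interval <- function(obs, statistic, level = 0.90) {
  K <- length(obs$chroms)
  if (K < 4) abort("chromosome jackknife needs at least 4 chromosomes")
  full <- statistic(obs)
  subs <- delete_one_chrom_summaries(obs)
  thetas <- vapply(subs, function(o) log(statistic(o)), numeric(1))
  if (any(!is.finite(thetas))) abort("statistic not finite on a jackknife replicate")
  se <- sqrt((K - 1) / K * sum((thetas - mean(thetas))^2))
  z <- qnorm(1 - (1 - level) / 2)
  exp(log(full) + c(-1, 1) * z * se)
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat(sprintf("<ne_estimate> Ne = %.4g (%s basis, %s model)\n",
              x$Ne, x$basis, x$model))
  if (!all(is.na(x$ci)))
    cat(sprintf("  %d%% CI: [%.4g, %.4g]\n", round(100 * x$level),
                x$ci[1], x$ci[2]))
  invisible(x)
}

#' @method tidy ne_estimate
#' @export
tidy.ne_estimate <- function(x, ...) {
  tibble(term = "Ne", estimate = x$Ne, conf.low = x$ci[1], conf.high = x$ci[2])
}

#' @method glance ne_estimate
#' @export
glance.ne_estimate <- function(x, ...) {
  tibble(Ne = x$Ne, conf.low = x$ci[1], conf.high = x$ci[2],
         basis = x$basis, model = x$model, n = x$n, n_snps = x$n_snps)
}
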