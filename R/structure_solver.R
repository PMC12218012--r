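#' Structure-solver configuration
#'
#' @param s_max largest subpopulation count searched (integers `2..s_max`,
#'   plus the panmictic model `s = 1`).
#' @param n_starts optimizer starts per `s` on a log-size grid.
#' @param weight_f relative weight of the inbreeding-coefficient residual.
#' @param census census metapopulation size for the observable bias terms
#'   (NULL = assume census equals the fitted `N_T`, the ideal Wright-Fisher
#'   case).
#' @param f_floor scale floor of the F residual (F-hat values below this are
#'   effectively "zero differentiation").
#' @param d2_floor floor applied to non-positive corrected delta-squared
#'   observables, with a warning.
#' @param rel_tol relative objective tolerance for parsimony ties: the
#'   smallest `s` whose objective is within this factor of the best is
#'   reported.
#' @return A list of class `solver_config`.
#' @export
solver_config <- function(s_max = 50, n_starts = 5, weight_f = 1,
                          census = NULL, f_floor = 0.02, d2_floor = 1e-6,
                          rel_tol = 1e-3) {
  structure(list(s_max = s_max, n_starts = n_starts, weight_f = weight_f,
                 census = census, f_floor = f_floor, d2_floor = d2_floor,
                 rel_tol = rel_tol), class = "solver_config")
}

# predicted observables for given (N, s, m); obs supplies n and weak profile
predict_observables <- function(N, s, m, obs, model, census = NULL) {
  n <- obs$n
  u <- expected_delta2_observed(0.5, N, s, m, n, model, census)
  wp <- obs$weak_profile
  if (is.null(wp) || !nrow(wp)) abort("no weak-set profile in summary")
  pw <- vapply(wp$c_harm, function(cc)
    expected_delta2_observed(cc, N, s, m, n, model, census), numeric(1))
  w <- sum(wp$sum_w * pw) / sum(wp$sum_w)
  f <- if (s >= 2) takahata_fst(N, m, s) else 0
  c(u = u, w = w, f = f)
}

#' Jointly estimate deme size, subpopulation number and migration rate
#'
#' The structure-aware ('-x') analysis: for each candidate number of
#' subpopulations `s`, minimizes the weighted sum of squared relative
#' differences between three observables -- corrected delta-squared of
#' unlinked pairs, of weakly linked pairs, and the sample inbreeding
#' coefficient -- and their island-model expectations, over deme size `N` and
#' migration rate `m` (with `F_ST` tied to them by [takahata_fst()]).  The
#' best `s` (smallest, among ties within `rel_tol`) is reported, together with
#' `N_T = s N`, `N_e = N_T / (1 - F_ST)` and the panmictic estimate for
#' comparison.
#'
#' @param obs an `ld_summary` from [summarize_ld()] on data with a genetic map
#'   and at least two chromosomes.  Haploid summaries (no inbreeding
#'   coefficient) are fitted on the two LD observables only.
#' @param config a [solver_config()].
#' @return An object of class `metapop_fit`.
#' @export
solve_metapop <- function(obs, config = solver_config()) {
  stopifnot(inherits(obs, "ld_summary"))
  model <- if (obs$ploidy == "diploid") "diploid" else "haploid"
  d2u <- obs$delta2_unlinked
  d2w <- obs$delta2_weak
  if (is.na(d2u)) abort("unlinked delta-squared unavailable (need >= 2 chromosomes)")
  if (is.na(d2w) || !nrow(obs$weak_profile))
    abort("weakly linked delta-squared unavailable (need a genetic map)")
  if (d2u <= 0) {
    warn("corrected unlinked delta-squared <= 0; floored at sampling noise level")
    d2u <- config$d2_floor
  }
  if (d2w <= 0) {
    warn("corrected weak delta-squared <= 0; floored at sampling noise level")
    d2w <- config$d2_floor
  }
  fhat <- obs$f_hat
  use_f <- model == "diploid" && !is.na(fhat)
  scale_u <- max(d2u, 5e-4)
  scale_w <- max(d2w, 5e-4)
  scale_f <- max(abs(fhat), config$f_floor)

  objective <- function(N, s, m) {
    pr <- predict_observables(N, s, m, obs, model, config$census)
    r <- c((d2u - pr["u"]) / scale_u, (d2w - pr["w"]) / scale_w)
    if (use_f) r <- c(r, config$weight_f * (fhat - pr["f"]) / scale_f)
    sum(r^2)
  }

  fit_one_s <- function(s) {
    if (s == 1) {
      o <- optim(log(1000), function(ln) objective(exp(ln), 1, 0),
                 method = "Brent", lower = log(2), upper = log(1e9))
      return(list(s = 1, N = exp(o$par), m = 0, obj = o$value,
                  convergence = o$convergence))
    }
    m_max <- (s - 1) / s
    alpha <- (s / (s - 1))^2
    m_from_f <- function(N) {
      f0 <- if (use_f) max(fhat, 1e-3) else sqrt(max(d2u, 1e-6) / 4 * (s - 1))
      f0 <- min(max(f0, 1e-4), 0.999)
      min(max((1 - f0) / (4 * N * alpha * f0), 1e-8), 0.99 * m_max)
    }
    N_grid <- c(50, 500, 5000, 5e4, 200)
    starts <- lapply(N_grid[seq_len(min(config$n_starts, length(N_grid)))],
                     function(N0) c(log(N0), stats::qlogis(m_from_f(N0) / m_max)))
    best <- NULL
    for (st in starts) {
      o <- tryCatch(
        nlminb(st, function(p) objective(exp(p[1]), s,
                                         m_max * stats::plogis(p[2])),
               lower = c(log(2), -30), upper = c(log(1e9), 30),
               control = list(rel.tol = 1e-14, iter.max = 500)),
        error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$objective < best$objective)) best <- o
    }
    if (is.null(best)) return(list(s = s, N = NA, m = NA, obj = Inf,
                                   convergence = 1L))
    # polish with Nelder-Mead
    p <- optim(best$par, function(p) objective(exp(p[1]), s,
                                               m_max * stats::plogis(p[2])),
               method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 2000))
    use <- if (p$value < best$objective) list(par = p$par, objective = p$value)
           else list(par = best$par, objective = best$objective)
    list(s = s, N = exp(use$par[1]), m = m_max * stats::plogis(use$par[2]),
         obj = use$objective, convergence = 0L)
  }

  fits <- lapply(c(1, 2:config$s_max), fit_one_s)
  profile <- bind_rows(lapply(fits, function(f)
    tibble(s = f$s, N = f$N, m = f$m, objective = f$obj)))
  objs <- vapply(fits, `[[`, numeric(1), "obj")
  best_obj <- min(objs[is.finite(objs)])
  # parsimony: smallest s within rel_tol of the best objective
  ok <- which(objs <= best_obj * (1 + config$rel_tol) + 1e-14)
  pick <- fits[[ok[1]]]
  if (!is.finite(pick$obj)) abort("structure solver failed to converge")
  s <- pick$s; N <- pick$N; m <- pick$m
  F_ST <- if (s >= 2) takahata_fst(N, m, s) else 0
  N_T <- s * N
  N_e <- metapop_ne(N_T, F_ST)
  ne_pan <- tryCatch(ne_panmictic(obs)$Ne, error = function(e) NA_real_)
  pr <- predict_observables(N, s, m, obs, model, config$census)
  structure(list(
    N = N, s = s, m = m, F_ST = F_ST, N_T = N_T, N_e = N_e,
    Ne_panmixia = ne_pan, residual = pick$obj,
    observed = c(u = d2u, w = d2w, f = fhat), fitted = pr,
    profile = profile, n = obs$n, n_snps = obs$n_snps, model = model,
    config = config), class = "metapop_fit")
}

#' @export
print.metapop_fit <- function(x, ...) {
  cat("<metapop_fit> island-model joint estimate\n")
  cat(sprintf("  s = %d subpopulation(s), deme size N = %.4g\n", x$s, x$N))
  cat(sprintf("  m = %.4g, F_ST = %.4g\n", x$m, x$F_ST))
  cat(sprintf("  N_T = %.4g, N_e = %.4g (panmictic estimate: %.4g)\n",
              x$N_T, x$N_e, x$Ne_panmixia))
  cat(sprintf("  fit residual = %.3g on observables (u, w%s)\n", x$residual,
              if (x$model == "diploid") ", F" else ""))
  invisible(x)
}

#' Parameter estimates of a metapopulation fit
#'
#' @param x a `metapop_fit` from [solve_metapop()].
#' @param ... unused.
#' @return A tibble with one row per estimated parameter.
#' @method tidy metapop_fit
#' @export
tidy.metapop_fit <- function(x, ...) {
  tibble(term = c("N", "s", "m", "F_ST", "N_T", "N_e", "Ne_panmixia"),
         estimate = c(x$N, x$s, x$m, x$F_ST, x$N_T, x$N_e, x$Ne_panmixia))
}

#' One-row fit summary of a metapopulation fit
#'
#' @param x a `metapop_fit`.
#' @param ... unused.
#' @return A one-row tibble with the headline estimates and the residual.
#' @method glance metapop_fit
#' @export
glance.metapop_fit <- function(x, ...) {
  tibble(N_e = x$N_e, N_T = x$N_T, s = x$s, m = x$m, F_ST = x$F_ST,
         Ne_panmixia = x$Ne_panmixia, residual = x$residual,
         n = x$n, n_snps = x$n_snps)
}
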