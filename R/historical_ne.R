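#' Recent-historical Ne trajectory from recombination bins
#'
#' LD at recombination fraction `c` reflects the effective size roughly
#' `t = 1/(2c)` generations ago (assuming near-linear change in Ne).  For each
#' recombination bin the corrected delta-squared is substituted into the
#' island-model LD partition with the contemporary estimates of `(s, m, F_ST)`
#' held fixed (or panmixia when `structure = NULL`), and solved for `N_T`;
#' `Ne(t) = N_T / (1 - F_ST)`.  Bins whose LD falls below the structural floor
#' (the between-deme components) are dropped with a warning.  The method gives
#' an approximate demographic trend, not a full demographic-history fit.
#'
#' @param obs an `ld_summary` with recombination bins (genetic map required).
#' @param structure optional `metapop_fit` from [solve_metapop()]; NULL
#'   assumes a single panmictic population.
#' @param model observable scale as in [ne_panmictic()].
#' @param census census size for the bias terms (default: fitted `N_T`).
#' @param smooth apply a 3-point moving geometric mean over bins.
#' @return An object of class `ne_trajectory`; its `points` tibble has columns
#'   `t` (generations ago), `Ne`, `c_bin` and `n_pairs`.
#' @export
ne_trajectory <- function(obs, structure = NULL,
                          model = c("auto", "diploid", "haploid",
                                    "pseudohaploid"),
                          census = NULL, smooth = FALSE) {
  model <- match.arg(model)
  if (model == "auto")
    model <- if (obs$ploidy == "diploid") "diploid" else "haploid"
  if (!nrow(obs$bins)) abort("no recombination bins: a genetic map is required")
  s <- if (is.null(structure)) 1L else structure$s
  m <- if (is.null(structure)) 0 else structure$m
  F_ST <- if (is.null(structure)) 0 else structure$F_ST
  pts <- lapply(seq_len(nrow(obs$bins)), function(i) {
    b <- obs$bins[i, ]
    cc <- b$c_harm
    # (s, m, F_ST) held at the contemporary estimates; N_T is free per bin
    nt <- invert_for_n(b$delta2, function(N_T)
      pt_expected_fixed_f(cc, N_T, s, m, F_ST, obs$n, model, census))
    tibble(t = 1 / (2 * b$c_mean), Ne = nt / (1 - F_ST), c_bin = b$c_mean,
           n_pairs = b$n_pairs, N_T = nt)
  })
  pts <- bind_rows(pts)
  dropped <- !is.finite(pts$Ne)
  if (any(dropped))
    warn(sprintf("%d bin(s) below the structural LD floor were dropped",
                 sum(dropped)))
  pts <- pts[!dropped, ]
  pts <- arrange(pts, .data$t)
  if (smooth && nrow(pts) >= 3) {
    lg <- log(pts$Ne)
    sm <- stats::filter(lg, rep(1 / 3, 3), sides = 2)
    pts$Ne_smooth <- exp(ifelse(is.na(sm), lg, sm))
  }
  structure(list(points = pts, s = s, m = m, F_ST = F_ST, model = model,
                 n = obs$n), class = "ne_trajectory")
}

# expected observable at fixed F_ST (trajectory inversion: s, m, F_ST from the
# contemporary fit; N_T is the free parameter)
pt_expected_fixed_f <- function(c, N_T, s, m, F_ST, n, model, census = NULL) {
  if (model == "haploid") {
    drift <- (1 - F_ST)^2 / (N_T * (1 - (1 - c)^2) + 2.2 * (1 - c)^2)
    extra <- if (s >= 2) expected_delta2_between(F_ST, s) +
      2 * expected_delta2_between_within(c, F_ST, s, m) else 0
    return(drift + extra - min(n / N_T, 1) / (n - 1))
  }
  if (model == "pseudohaploid") {
    # diploid composite observable / 4 (see expected_delta2_observed())
    return(pt_expected_fixed_f(c, N_T, s, m, F_ST, n, "diploid", census) / 4)
  }
  if (is.null(census)) census <- N_T
  base <- expected_delta2_within(c, N_T, F_ST)
  extra <- if (s >= 2) 4 * expected_delta2_between(F_ST, s) +
    4 * expected_delta2_between_within(c, F_ST, s, m) else 0
  base + extra + (1 - F_ST)^2 / (2 * census) -
    min(n / census, 1) * (1 + F_ST)^2 / (n - 1)
}

#' @export
print.ne_trajectory <- function(x, ...) {
  cat(sprintf("<ne_trajectory> %d points, t in [%.3g, %.3g] generations ago\n",
              nrow(x$points), min(x$points$t), max(x$points$t)))
  cat(sprintf("  structure: s = %d, m = %.4g, F_ST = %.4g (%s model)\n",
              x$s, x$m, x$F_ST, x$model))
  invisible(x)
}

#' Trajectory points as a tibble
#'
#' @param x an `ne_trajectory`.
#' @param ... unused.
#' @return The points tibble (`t`, `Ne`, `c_bin`, `n_pairs`).
#' @method tidy ne_trajectory
#' @export
tidy.ne_trajectory <- function(x, ...) x$points

#' Plot an Ne trajectory
#'
#' @param object an `ne_trajectory`.
#' @param ... unused.
#' @return A ggplot object (generations ago on x, Ne on log y).
#' @method autoplot ne_trajectory
#' @export
autoplot.ne_trajectory <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$t, y = .data$Ne)) +
    ggplot2::geom_step() + ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "generations ago (1/2c)", y = "Ne",
                  title = "Recent historical Ne")
}

#' Rescale a haploid X-chromosome Ne to the autosomal diploid scale
#'
#' Multiplies by 4/3 (haploid X pool to the autosome-equivalent haploid pool
#' with equal sex numbers) and divides by 2 (haploid to diploid numbers):
#' `ne * (4/3) / 2`.
#'
#' @param ne_haploid_x positive haploid-scale Ne estimated from X data.
#' @return Diploid autosome-equivalent Ne.
#' @export
x_to_autosome_scale <- function(ne_haploid_x) {
  if (any(!is.finite(ne_haploid_x)) || any(ne_haploid_x <= 0))
    abort("Ne must be positive")
  ne_haploid_x * (4 / 3) / 2
}

#' Sex-specific genetic-map corrections
#'
#' Adjusts genetic distances for chromosomes whose transmission skips
#' recombination in one sex: X chromosomes sampled in males use 2/3 of the
#' female-map distances (1/3 of copies are in males and do not recombine);
#' autosomes of male Drosophila use 1/2 (achiasmatic male meiosis).
#'
#' @param g a [genotype_matrix()] with cM positions.
#' @param mode `"none"` (unchanged), `"x_male_sample"` (x 2/3) or
#'   `"autosome_male_drosophila"` (x 1/2).
#' @return The genotype matrix with scaled `position_cM`.
#' @export
sex_map_correction <- function(g, mode = c("none", "x_male_sample",
                                           "autosome_male_drosophila")) {
  mode <- match.arg(mode)
  fac <- switch(mode, none = 1, x_male_sample = 2 / 3,
                autosome_male_drosophila = 1 / 2)
  if (fac != 1) {
    if (all(is.na(g$sites$position_cM)))
      abort("genetic positions (cM) required for map correction")
    g$sites$position_cM <- g$sites$position_cM * fac
  }
  g
}
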