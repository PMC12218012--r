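---
title: "Effective population size and metapopulation structure from composite LD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effective population size and metapopulation structure from composite LD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(islandne)
```

# The model

`islandne` estimates contemporary and recent-historical effective population
size ($N_e$) from a single sample of unphased SNP genotypes, allowing for
metapopulation structure under the finite island model: $s$ subpopulations
(demes) of effective size $N$ exchanging migrants at a symmetric
per-generation rate $m$.

The information source is linkage disequilibrium measured as
$$\delta^2 = \frac{E[D^2]}{E[W]},$$
the ratio of expectations of squared two-locus covariances $D$ (gametic
scale) to products of single-locus variances $W = p_i(1-p_i)\,p_j(1-p_j)$.
Pooling individuals from differentiated demes creates LD even between
unlinked loci — a two-locus analogue of the Wahlund effect — and the total
LD partitions into within-, between- and between-within-subpopulation
components:
$$\delta^2 = \delta^2_w + \delta^2_b + 2\,\delta^2_{bw},$$
with migration–drift-equilibrium expectations
$$E[\delta^2_w] = (1-F_{ST})^2\,\frac{1+c^2}{2N_T\!\left(1-(1-c)^2\right)+2.2(1-c)^2},
\qquad
E[\delta^2_b] \approx \frac{F_{ST}^2}{s-1},$$
$$E[\delta^2_{bw}] \approx
\frac{\left(\tfrac{s}{s-1}\right)^2 \delta^2_b\, m}
     {1-\left(1-\tfrac{s}{s-1}m\right)^2 (1-c)},$$
where $c$ is the recombination fraction between the two loci,
$N_T = sN$ is the summed effective size of the demes, and $F_{ST}$ is
Wright's differentiation index.  At equilibrium $F_{ST}$, $N$, $m$ and $s$
are linked by the finite-island closed form
$F_{ST} = 1/(1 + 4Nm\alpha)$ with $\alpha = (s/(s-1))^2$, and the
metapopulation effective size follows $N_e = N_T/(1-F_{ST})$, so $N_e \ge
N_T$ always.  These closed forms are exported as `expected_delta2_within()`,
`expected_delta2_between()`, `expected_delta2_between_within()`,
`takahata_fst()` and `metapop_ne()`.

Three observables are measured from the sample by `summarize_ld()`:

* $\hat\delta^2_u$: corrected composite $\delta^2$ of pairs on *different
  chromosomes* ($c = 0.5$);
* $\hat\delta^2_{weak}$: the same for *weakly linked* pairs on the same
  chromosome (recombination window described below);
* $\hat F$: the sample inbreeding coefficient
  $1 - \sum H_{obs}/\sum H_{exp}$, which approximates $F_{ST}$ when demes
  are internally panmictic.

`solve_metapop()` minimizes, over $(N, m)$ for each integer $s$, the sum of
squared relative differences between these observables and their model
expectations, and reports the best $s$ (ties resolved towards smaller $s$).
`ne_panmictic()` is the one-population special case, and `ne_trajectory()`
substitutes per-recombination-bin $\delta^2$ values into the partition with
the contemporary $(s, m, F_{ST})$ held fixed, using the mapping that LD at
recombination fraction $c$ reflects $N_e$ roughly $t = 1/(2c)$ generations
ago.

# What the sample actually measures: the composite observable

With unphased diploid genotypes, $D$ is estimated by the Burrows composite
covariance (half the dosage covariance), which requires no phase
information.  Three corrections connect this observable to the
gametic-scale theory above; all three were derived analytically and
verified against the package's own forward simulator (they are collected in
`expected_delta2_observed()`):

1. **Finite sampling.**  For each pair, the exact permutation-null
   expectation $E_{perm}[S_{xy}^2] = S_{xx}S_{yy}/(n-1)$ is subtracted from
   the squared dosage covariance, so truly independent loci contribute zero
   on average (`correct_for_sampling()`).  This is an
   individuals-resampled (with-replacement) correction.
2. **Homolog doubling under structure.**  Both homologous chromosomes of an
   individual carry its deme-of-origin allele-frequency deviation, so the
   between and between-within components appear in the composite observable
   with weights 4 and 4 rather than 1 and 2.  This is a property of
   unphased data, not an estimator choice: in the fully differentiated
   two-deme extreme the composite $\delta^2$ of unlinked pairs approaches
   4, not 1.
3. **$O(1/N)$ terms.**  Random pairing of gametes into individuals adds
   $(1-F_{ST})^2/(2N_c)$ to the observable ($N_c$ the census size), while
   sampling $n$ individuals *without* replacement makes correction (1)
   over-subtract by $\min(n/N_c, 1)(1+F_{ST})^2/(n-1)$.  The estimators
   invert the full observable model, taking $N_c = N_T$ (the ideal
   Wright–Fisher case, exact for the simulator; an approximation for real
   data, where both terms are $O(1/N)$ and small at typical sampling
   fractions).

For haploid data there is no pairing term and the drift expectation fits
$1/\!\left(N_h(1-(1-c)^2)+2.2(1-c)^2\right)$ on the haploid scale $N_h$
(simulation-calibrated; note the numerator 1 rather than $1+c^2$).
Pseudohaploid data are a different case again: because one allele is drawn
independently at each site, the pseudo-alleles do not form coherent gametes
— their cross-locus covariance is half the composite covariance — so the
pseudohaploid observable equals the diploid composite observable divided by
4 (verified against simulation to three digits), and the low-depth pipeline
inverts exactly that.  Its robustness to depth corruption comes from the
pseudo-allele variance being Bernoulli $p(1-p)$ regardless of how many
heterozygotes were miscalled, which keeps the finite-sampling correction
honest where the direct diploid pipeline over-subtracts.

# Tunable parameters

* **Site hygiene** (`filter_sites()`, reader defaults): call rate
  $\ge 0.9$, minor allele frequency $\ge 0.01$.  $\delta^2$ ratios are
  unstable at extreme frequencies; the MAF floor removes that instability
  at negligible information cost.  Both are configurable; a minimum
  chromosome length filter is available but off by default.
* **Weakly linked window** (`ld_config()`): $0.05 < c < 0.2$ by default.
  The lower bound keeps out strongly linked pairs whose LD reflects older
  demography; the upper bound is the package's choice.  Between $c = 0.2$
  and $c = 0.5$ the within-component expectation is nearly flat in $c$, so
  those pairs dilute the $N_T$ contrast between the weak and unlinked
  observables while amplifying the influence of the approximate
  $\delta^2_{bw}$ term (see *Numerical behaviour* below); narrowing the
  window materially reduces the replicate scatter of $\hat N_T$ in two-deme
  simulations.
* **Pair budget** (`ld_config()`): at most 3000 sites per chromosome enter
  same-chromosome pair enumeration (uniform random subsample beyond that);
  cross-chromosome pairs use a *nested subset* of the same sites.  Nesting
  matters: the between-deme component is a property of the chosen sites,
  and using different subsets for the unlinked and weak observables breaks
  its cancellation in their contrast, which is the $N_T$ signal.
* **Bins**: 30 logarithmic recombination bins on $[0.001, 0.5]$, at least
  100 pairs per bin (smaller bins merged upward), with edges snapped to the
  weak-window bounds.
* **Solver** (`solver_config()`): $s$ searched over $1..50$; five
  optimizer starts per $s$ on a log-size grid with migration initialized
  from $\hat F$; equal relative weights on the three residuals (the
  relative weighting is not externally prescribed; equal weighting is the
  package default and configurable).  The $\hat F$ residual uses a scale
  floor of 0.02 so that near-zero differentiation does not produce
  divide-by-zero relative errors.
* **Confidence intervals**: delete-one-chromosome jackknife on the log
  scale (`confidence_interval()`), 90% by default; chromosome deletion
  respects the LD correlation structure.  At least 4 chromosomes are
  required.
* **Pseudohaploid replicates** (`ne_pseudohaploid()`): 50 by default,
  combined by geometric mean, since $N_e$ is a log-scale quantity.

# The simulator and what it emulates

`simulate_island()` is a discrete-generation Wright–Fisher forward
simulator: random mating within demes (selfing allowed), symmetric island
migration of individuals, Haldane (interference-free) crossovers, biallelic
sites on a fixed grid (4 chromosomes of 100 cM by default, physical
coordinates at 1 cM/Mb).  It runs in two phases:

1. a **frequency phase** — allele-frequency-only binomial drift plus
   migration, run for about six relaxation times of $F_{ST}$
   ($1/(2m\,s/(s-1) + 1/2N)$ each) so deme frequencies reach
   migration–drift equilibrium cheaply; sites fixed or lost are discarded
   at the end of this phase only;
2. a **genotype phase** — the full recombining forward simulation
   (compiled code), which builds the linkage disequilibrium.  LD at
   recombination fraction $c$ relaxes towards equilibrium at rate
   $\approx (1-c)^2$ per generation, so 150 generations equilibrate
   everything with $c \gtrsim 0.02$.

One slower process matters for very precise equilibrium checks: the
coupling between LD and the allele-frequency distribution equilibrates on
the drift timescale ($\sim N$ generations), not $1/(2c)$.  Equilibrium
validation runs therefore use a mutation–drift stationary recipe
($4N\mu = 0.2$, a U-shaped starting frequency distribution and $7.5N$
generations), under which the simulated $\delta^2$ matches the closed form
to within Monte-Carlo error at all tested $c$.

The simulator emulates drift, migration, recombination and the sampling
process.  It does not emulate selection, gene conversion, crossover
interference, overlapping generations, uneven recombination maps or
SNP-array ascertainment, so passing tests demonstrate correctness of the
estimators under the island model's assumptions, not robustness to every
feature of real data.  Corruption operators (`inject_errors()`,
`depth_corruption()`) emulate symmetric base-calling error and
depth-limited heterozygote loss; `demographic_event()` expresses step
changes of deme size (decline, expansion, bottleneck).

Reference problem sizes used throughout the package's validation: two
demes of 1000 with $m = 0.001$, 100 sampled individuals and
$\ge$ 10,000 SNPs on 4 chromosomes for structure recovery (10 replicates);
$N = 200$ with $n = 100$ for equilibrium checks; $N = 500$ for the
data-quality pipelines.  These are deliberate desk-scale reductions of
genome-scale designs (20 chromosomes, $\sim$ 50k SNPs) and were chosen so
the full validation suite runs in minutes on one core.

# Numerical behaviour and known limitations

* **The $\delta^2_{bw}$ approximation.**  Deme-labeled decomposition of
  simulated data reproduces $E[\delta^2_w]$ and $E[\delta^2_b]$ closely,
  but the closed-form $E[\delta^2_{bw}]$ approximation *underestimates*
  the simulated between-within component, increasingly so at large $c$.
  The term is small (a few percent of the unlinked observable), but its
  error leaks into the weak-vs-unlinked contrast; the default weak window
  caps $c$ at 0.2 mainly to bound this leakage.  The residual effect is a
  mild downward bias of $\hat N_T$, concentrated where $N m \approx 1$
  and well inside the scatter of single replicates.
* **Degenerate inputs.**  Non-positive corrected $\delta^2$ observables
  (pure sampling noise; very large $N_e$) are floored at a small positive
  value with a warning in the solver, and reported as an unbounded
  estimate ($N_e = \infty$, upper confidence limit $\infty$) by
  `ne_panmictic()`.  Monomorphic loci are skipped pair-wise.  Trajectory
  bins whose $\delta^2$ falls below the structural floor (the between-deme
  components) are dropped with a warning.
* **Inversion.**  All $N$ inversions are monotone root-findings on
  $\log N$ over $[2, 10^9]$ with tolerance $10^{-12}$; with the sampling
  bias terms disabled the unlinked inversion is the exact algebraic
  inverse of $E[\delta^2_w]$.
* **Ties and identifiability.**  When $Nm \gg 1$ the metapopulation is
  effectively panmictic: $F_{ST}\to 0$, $s$ becomes weakly identified and
  migration rates are underestimated — the solver then reports structure
  parameters with large uncertainty, but $\hat N_e$ remains accurate and
  close to the panmictic estimate.  Agreement between the structure-aware
  and panmictic estimates is itself the diagnostic for panmixia.
* **Haploid structure analysis** uses only the two LD observables (no
  inbreeding coefficient), so subpopulation parameters are less well
  identified than in the diploid case.
* **Depth robustness of the default pipeline.**  Because $W$ is built from
  allele frequencies ($p(1-p)$, unchanged by heterozygote miscalls) and the
  finite-sampling subtraction uses observed genotype variances (which
  inflate with the corruption exactly as the real sampling noise does), the
  *uncorrected* diploid pipeline is already essentially unbiased under
  mean-preserving het-to-hom corruption in simulations; the upward bias
  reported for genotype-variance-normalized LD estimators does not occur
  here.  The pseudohaploid mode remains the recommended route for real
  low-depth data, where corruption is not exactly mean-preserving and
  depth varies across sites and individuals.
* **Trajectories** are per-bin substitutions, not a demographic-history
  fit: they indicate trends over roughly the last $1/(2c_{min})$
  generations and inherit the equal-$(s,m,F_{ST})$-across-time assumption.

# Design choices made where the design was open

* Burrows composite covariance with per-gamete scaling for unphased data;
  phase is never required.
* Haldane's map function (no interference) converts genetic distances to
  recombination fractions; different chromosomes are fixed at $c = 0.5$.
* The weak-set model prediction averages $E[\delta^2](c)$ over the
  empirical pair-count distribution of $c$ within the window (the
  observable is a ratio of sums, i.e. a pair-weighted mean), rather than
  evaluating at a single effective $c$.
* The error corrections (`-b`) and the pseudohaploid mode (`-g 3`) are
  available only under panmixia; combining them with the structure option
  is rejected, since genotyping noise overwhelms the small between-deme LD
  signals.
* Genotyping-error correction inverts
  $D' = D\,[1-4\varepsilon(1-\varepsilon)]$ and
  $V' = V + \varepsilon(1-4V)$ exactly; the pseudohaploid route needs no
  error model at all because a random draw from a depth-corrupted
  heterozygote has the same distribution as a draw from the true
  heterozygote.
* X-chromosome helpers implement the male-sample map correction (2/3),
  the Drosophila male-autosome correction (1/2) and the
  $\times\tfrac{4}{3}\,/\,2$ rescaling of haploid X estimates to the
  diploid autosomal scale.

# A worked example

```{r example, eval = FALSE}
library(islandne)

# simulate a two-deme metapopulation and estimate its parameters
sim <- simulate_island(sim_config(s = 2, N = 1000, m = 0.001,
                                  n_sites = 13000, sample_n = 100,
                                  generations = 150, seed = 1))
obs <- summarize_ld(sim$genotypes, ld_config(seed = 1))
fit <- solve_metapop(obs, solver_config(s_max = 12))
tidy(fit)

# recent-historical trajectory, structure-aware
tr <- ne_trajectory(obs, structure = fit)
autoplot(tr)
```
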