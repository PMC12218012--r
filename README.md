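# islandne

Effective population size (Ne) and metapopulation structure from the linkage
disequilibrium (LD) of a single sample of unphased SNP genotypes.

## The problem and who this is for

Contemporary Ne is a core quantity in conservation and population genetics,
and LD-based estimators can extract it from one sample of a few dozen
individuals.  But almost all of them assume one panmictic population.  When
the sampled individuals actually come from a structured metapopulation,
pooling differentiated subpopulations creates LD even between unlinked loci
(a two-locus Wahlund effect), and panmictic estimators can underestimate Ne
by an order of magnitude — populations can look critically small when they
are not.  `islandne` is for population and conservation geneticists who have
a SNP panel (VCF or PLINK PED/TPED, diploid unphased or haploid) from a
single sample and want structure-aware estimates of contemporary Ne, plus
the structure parameters themselves, plus a recent-historical Ne trajectory.

## The model

Under a finite island model (`s` demes of size `N`, symmetric migration
`m`), LD measured as `delta2 = E[D^2]/E[W]` partitions as

    delta2 = delta2_w + delta2_b + 2 delta2_bw

with equilibrium expectations

    E[delta2_w]  = (1-Fst)^2 (1+c^2) / (2 N_T (1-(1-c)^2) + 2.2 (1-c)^2)
    E[delta2_b]  = Fst^2 / (s-1)
    E[delta2_bw] = (s/(s-1))^2 delta2_b m / (1 - (1-(s/(s-1))m)^2 (1-c))

where `c` is the recombination fraction, `N_T = sN` the summed deme size and
`Fst = 1/(1 + 4Nm(s/(s-1))^2)` at migration-drift equilibrium; the
metapopulation effective size is `Ne = N_T/(1-Fst)`.  Three observables from
the sample — corrected composite delta2 of unlinked pairs (different
chromosomes, c = 0.5), of weakly linked pairs (same chromosome), and the
inbreeding coefficient — identify `(N, s, m)` by least squares; per-bin
delta2 values mapped through `t = 1/(2c)` give the recent Ne trajectory.
Corrections for genotyping error (`D' = D[1-4e(1-e)]`, `V' = V + e(1-4V)`)
and for low sequencing depth (50 pseudohaploid resamples) are built in, as
is a Wright-Fisher island-model simulator that serves as the test bed for
every estimator.

## A worked example

Simulate a two-deme metapopulation (1000 individuals per deme, one migrant
per thousand per generation), sample 100 individuals, and estimate its
parameters:

```r
library(islandne)

sim <- simulate_island(sim_config(s = 2, N = 1000, m = 0.001,
                                  n_sites = 13000, sample_n = 100,
                                  generations = 150, seed = 1))
obs <- summarize_ld(sim$genotypes, ld_config(seed = 1))
obs
#> <ld_summary> n = 100 diploid individuals, 12351 SNPs, 4 chromosome(s)
#>   delta2 unlinked (c=0.5): 0.0185275   [5.4e+07 pairs]
#>   delta2 weak (c>0.05):      0.0203013   [6.19666e+06 pairs]
#>   inbreeding F-hat:        0.06844

fit <- solve_metapop(obs, solver_config(s_max = 12))
fit
#> <metapop_fit> island-model joint estimate
#>   s = 2 subpopulation(s), deme size N = 664.8
#>   m = 0.001291, F_ST = 0.06786
#>   N_T = 1330, N_e = 1426 (panmictic estimate: 65.49)
#>   fit residual = 9.44e-05 on observables (u, w, F)
```

Reading this: the unlinked delta2 (0.019) is dominated by the between-deme
component, and the inbreeding coefficient (0.068) matches the realized
differentiation; the solver correctly finds two demes and a migration rate
near 0.001.  The single-replicate `N_T` (1330 here, truth 2000) is noisy —
across ten seeded replicates its geometric mean is within ~10% of the truth
— while the panmictic estimate (65!) shows the order-of-magnitude
underestimation that ignoring structure produces.  Agreement between the
panmictic and structure-aware estimates, conversely, indicates panmixia.

The recent-historical trajectory, with the structure estimates held fixed:

```r
tr <- ne_trajectory(obs, structure = fit)
autoplot(tr)           # Ne against generations ago (t = 1/(2c))
tidy(tr)               # t, Ne, c_bin, n_pairs
```

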