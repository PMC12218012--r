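Package: islandne
Title: Effective Population Size and Metapopulation Structure from
    Linkage Disequilibrium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates contemporary and recent-historical effective
    population size (Ne) from a single sample of unphased SNP genotypes,
    accounting for metapopulation structure under the finite island model.
    Partitions composite linkage disequilibrium into within-, between- and
    between-within-subpopulation components, and jointly estimates deme
    size, subpopulation number, migration rate and FST from the LD of
    unlinked and weakly linked sites together with the sample inbreeding
    coefficient.  Includes corrections for genotyping error and for low
    sequencing depth (pseudohaploid resampling), haploid-data support,
    recombination-binned Ne trajectories, readers and writers for VCF and
    PLINK PED/TPED formats, and a Wright-Fisher island-model simulator used
    as the test bed for every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
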