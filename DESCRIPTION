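Package: ystrtrace
Title: Y-STR Haplotype Diversity, Distance, Network and TMRCA Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical toolkit for Y-chromosome short tandem repeat (Y-STR)
    haplotype surveys of paternal lineages: panel normalization under Yfiler
    conventions (DYS389II adjustment, DYS385 exclusion), per-population
    diversity summaries (haplogroup frequency, Nei average gene diversity,
    mean microsatellite variance), pairwise Rst distances with permutation
    significance testing and Bonferroni correction, classical multidimensional
    scaling of distance matrices, median-joining haplotype networks with loci
    weighted inversely to repeat variance, and founder-based TMRCA estimation
    (rho statistic, mutation-rate-weighted rho, and second-moment average
    squared distance dating). Includes a stepwise-mutation-model simulator on
    star and Kingman coalescent genealogies for calibration and testing.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    igraph,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
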