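Package: scafmap
Title: Scaffold Ordering, Recombination Maps and Structural Variant
    Detection from Low-Coverage Mapping Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Orders and orients genomic scaffolds into pseudo-chromosomes
    from sparse, low-depth genotyping of experimental mapping populations
    (F2, F3 and recombinant inbred line designs). Read counts at
    parent-diagnostic SNPs are aggregated into window markers, a
    three-state hidden Markov model with per-individual genotyping error
    rates yields the likelihood of any candidate scaffold order, and a
    genetic algorithm searches order/orientation space for the maximum
    likelihood map. Cross-map likelihood comparisons detect chromosomal
    inversions and translocations through recombination suppression and
    marker-order reversals. A mapping-population simulator with known
    ground truth (multiplexed shotgun genotyping style sparse tags,
    stochastic read depth, optional achiasmatic male meiosis) makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
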