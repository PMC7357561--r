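Package: msatdemog
Title: Microsatellite Diversity, Differentiation and Effective-Size History
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the evolutionary-history analysis of diploid
    microsatellite genotype data: GENEPOP and delimited-table input/output,
    per-locus diversity statistics (heterozygosities, polymorphism
    information content, identity and parentage-exclusion probabilities,
    null-allele estimators, Monte-Carlo exact Hardy-Weinberg tests, Weir and
    Cockerham F-statistics), population differentiation and migrant
    detection (pairwise FST with permutation tests, private-allele gene
    flow, assignment indices and sex-biased dispersal, isolation by
    distance), heterozygosity-excess bottleneck tests under the stepwise
    mutation model, and coalescent Markov chain Monte Carlo inference of a
    piecewise-constant effective-population-size trajectory and the
    pairwise TMRCA distribution from allele-size difference spectra. A
    seeded coalescent simulator of microsatellite genotypes under stepwise
    mutation and piecewise-constant demography provides synthetic data for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    pracma,
    vegan,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
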