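Package: cgpsim
Title: Sweepstakes Reproduction, Collective Dispersal and Multiple-Merger
    Coalescent Analysis of Chaotic Genetic Patchiness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying chaotic genetic patchiness in broadcast
    spawners. Provides a forward genetic simulator of sweepstakes
    reproductive success in spawning aggregations ("stacks"), collective
    larval dispersal into a five-deme stepping-stone metapopulation, and
    the multi-generation decay of sweepstake signatures; pairwise genomic
    kinship estimation (method-of-moments IBD coefficients Z0/Z1/Z2 and
    PI_HAT, and the robust within-pair kinship coefficient) with
    relatedness-category classification; cohort-level population-genetic
    statistics (nucleotide diversity, linkage-disequilibrium r-squared,
    Weir-Cockerham Fst with bootstrap significance, folded site-frequency
    spectra); and model comparison of empirical folded spectra against the
    Kingman coalescent and the Xi-Beta(2-alpha, alpha) simultaneous
    multiple-merger coalescent by the l2 metric. A synthetic-data module
    generates cohort-structured SNP datasets with known pedigrees so the
    whole pipeline is testable without empirical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
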