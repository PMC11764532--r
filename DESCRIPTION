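Package: wolfdogpop
Title: Population Genomics of Hybrid Wolfdog Breeds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to characterize SNP-array data from hybrid dog breeds and
    their wild and domestic ancestor populations. Reads, harmonizes and merges
    PLINK text and binary genotype panels; computes per-population observed
    and expected heterozygosity, polymorphic-site counts and pairwise
    Weir-Cockerham fixation indices; detects runs of homozygosity with a
    sliding-window scan and derives the genomic inbreeding coefficient F_ROH;
    reconstructs historical effective population size from the decay of
    linkage disequilibrium with genetic distance (Sved equation); and ships a
    forward-in-time diploid Wright-Fisher simulator of wolf x dog breed
    formation (founder crosses, scheduled wild infusions, popular-sire mating
    bias) with pedigree-based ground truth, so every stage is verifiable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
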