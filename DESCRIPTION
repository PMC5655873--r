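Package: haploCover
Title: Budget-Constrained Allocation of Low-Coverage Sequencing Across
    Population Haplotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decides which individuals of a genotyped population to sequence,
    and at what coverage, so that the largest possible proportion of the
    population's marker-defined haplotypes accumulates a target sequencing
    depth under a fixed budget. Builds a core-based haplotype library from
    phased marker-array genotypes, selects an initial sequencing set with a
    greedy coverage-balancing score, refines it through rounds of slot
    exchanges, and compares against inverse-weight and random allocation
    strategies. Includes a flanking-context filter that keeps only those rare
    haplotypes likely to be recombinant mosaics of common haplotypes, a
    pedigree gene-dropping simulator for generating test populations with
    realistic haplotype frequency spectra, and evaluation summaries of the
    coverage distribution achieved by a sequencing set.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
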