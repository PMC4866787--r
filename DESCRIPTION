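Package: mtcontinuity
Title: Maternal Genetic Continuity Analysis from mtDNA Control-Region Haplotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing maternal genetic continuity between ancient and
    modern human populations from mitochondrial DNA control-region data.
    Parses and compares rCRS-relative haplotype motifs with partial sequencing
    coverage, assigns haplogroups from control-region motifs and minisequenced
    coding-region diagnostics, computes Arlequin-style diversity parameters,
    AMOVA-based pairwise FST with permutation significance, chi-square tests
    and PCA on haplogroup frequencies, and performs approximate Bayesian
    computation model choice between competing demographic scenarios using a
    serial-sampling (heterochronous) coalescent simulator with HKY sequence
    evolution. Includes a synthetic-data generator that emulates the
    statistical structure of ancient/modern control-region study designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
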