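Package: hapga
Title: Haplotype Assembly by Genetic-Algorithm Weighted Minimum Error
    Correction
Version: 0.1.0
Authors@R:
    person("hapga", "developers", email = "hapga@example.org",
           role = c("aut", "cre"))
Description: Single-individual haplotype assembly from aligned sequencing
    reads under the weighted Minimum Error Correction (wMEC) model.  Reads
    covering heterozygous SNP sites are bipartitioned into the two
    chromosome copies by a genetic algorithm; large fragment matrices are
    decomposed into haplotype blocks and coverage-sized sub-problems that
    are solved independently and merged.  Includes a WIF (WhatsHap Input
    Format) reader/writer, a planted-haplotype long-read simulator with
    Roche/454-like and PacBio-RS-II-like profiles, and evaluation metrics
    (haplotype error rate, block agreement, average-best-fitness curves).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    parallel,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
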