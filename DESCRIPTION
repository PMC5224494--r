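Package: splicearch
Title: Branch Point, Polypyrimidine Tract and RNA Accessibility Analysis of 3' Splice Sites
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the 3' splice site architecture of
    alternatively spliced exons, in particular tandem duplicated exons under
    U2AF control. Computes AG-exclusion-zone (AGEZ) and polypyrimidine-tract
    (PPT) annotations, scores candidate branch points against the U2 snRNA
    guide sequence across shifted base-pairing registers, profiles RNA
    single-strandedness (probability of unpaired, PU) with an exact
    partition-function engine, evaluates stem-loop (ESL) stability for
    mutation panels and correlates it with exon inclusion, detects
    lariat-junction-spanning reads by mismatch-tolerant k-mer search and calls
    branch-point adenines, and computes splicing-regulatory motif densities.
    Includes seeded synthetic-data generators with exact planted ground truth
    for every pipeline input.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
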