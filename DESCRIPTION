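Package: serialcoal
Title: Serial Coalescent Simulation and Tests of Population Continuity
    from Heterochronous mtDNA Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates genealogies of heterochronously sampled mitochondrial
    lineages under constant-size, exponential-growth and isolation-admixture
    demographies; computes the largest ancient-exclusive clade statistic on a
    genealogy; runs Monte-Carlo rejection tests of population continuity,
    effective-size threshold scans and admixture upper-limit curves; and
    estimates the female effective population size from control-region
    nucleotide diversity. A synthetic sequence generator (finite-sites,
    equal-rates substitution on simulated genealogies) makes the whole
    pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    Matrix,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
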