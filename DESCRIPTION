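Package: proxiscaf
Title: Probabilistic Genome Scaffolding from Chromosome Contact Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scaffolds and curates genome assemblies from proximity-ligation
    (3C/Hi-C) contact data. Genomic bins built from restriction fragments are
    iteratively reordered, reoriented, duplicated or removed by a multiple-try
    Metropolis sampler that scores one-dimensional genome structures under a
    Poisson likelihood, with cis contact intensities following a power law in
    genomic distance up to a plateau and trans contacts occurring at a uniform
    rate. Includes contact-matrix construction from fragment-level read pairs,
    a contact simulator with misassembly signatures (translocations,
    inversions, collapsed duplications), and assembly-quality metrics against
    a reference structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    methods,
    stats,
    graphics,
    utils,
    jsonlite,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
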