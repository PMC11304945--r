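Package: tripar
Title: Parentage Assignment for Triploid Offspring of Diploid Parents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Likelihood and exclusion parentage assignment of triploid
    offspring (two maternal and one paternal chromosome sets, as induced by
    second-polar-body retention in finfish) against candidate diploid parent
    pairs genotyped with co-dominant markers. Implements per-marker Mendelian
    transmission probability and exclusion tables that account for the double
    maternal contribution and marker-centromere recombination, an
    error-rate-controlled likelihood threshold, an automated mismatch
    allowance for exclusion, a single-parent exclusion comparator, a
    breeding-design simulator (factorial matings, genotyping error, masked
    parents), and assignment-quality metrics (sensitivity, false discovery
    rate, specificity).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
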