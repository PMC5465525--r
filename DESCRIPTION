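Package: clklink
Title: Privacy-Preserving Record Linkage with Cryptographic Long-Term Keys
    and Multibit Trees
Version: 0.1.0
Authors@R:
    person("clklink", "developers", email = "clklink@example.org",
           role = c("aut", "cre"))
Description: Tools for privacy-preserving record linkage (PPRL) of person
    records. Personal identifiers are q-gram decomposed and hashed with a
    keyed digest into a single composite Bloom filter per record, the
    cryptographic long-term key (CLK). Similar record pairs are retrieved
    exactly under a Tanimoto (Jaccard) threshold using a popcount-binned
    forest of split-half multibit trees with provable upper-bound pruning.
    Includes a de-duplication and two-file linkage engine with optional
    external blocking, pairwise precision/recall/F-measure evaluation
    against a truth set, a synthetic person-population generator with
    configurable missingness and typographical corruption, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    openssl,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
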