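Package: adaptmsa
Title: Adaptive Guide Trees for Progressive Multiple Sequence Alignment
Version: 0.1.0
Authors@R:
    person("Quentin", "Marle", email = "qmarle@example.org", role = c("aut", "cre"))
Description: Progressive multiple sequence alignment of protein families with
    pluggable guide-tree construction.  Guide trees can be built by an adaptive
    percent-identity scheme (global alignment distances for highly similar
    families, local for moderately similar ones, and a global/local consensus
    in the twilight zone), drawn uniformly at random, or taken from a supplied
    reference phylogeny.  The package also provides optimal pairwise alignment
    with affine gaps, sum-of-pairs and total-column accuracy scoring against a
    reference alignment with similarity-binned reporting, a sequence-evolution
    simulator with indels that tracks the true alignment, and a benchmark
    harness for comparing guide-tree strategies on simulated families.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
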