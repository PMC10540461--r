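Package: ffdcj
Title: Family-Free Gene Orthology Inference via DCJ-Indel Genome Rearrangements
Version: 0.1.0
Authors@R: person("Orthology", "Tools", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers gene orthologies and gene families directly from gene
    orders and pairwise sequence similarities, without precomputed gene
    families.  For each genome pair a weighted DCJ-indel rearrangement
    distance is minimised over all candidate ortholog matchings of a gene
    similarity graph, using a family-free relational graph whose linear
    segment ends are closed ("capped") either optimally or by a heuristic
    driven by a shared-content graph on segments.  Pairwise ortholog sets
    are integrated into an n-partite family graph, classified, optionally
    refined by Markov clustering, and scored against reference families
    with pair-based precision and recall.  Includes a seeded synthetic
    genome evolution generator and exhaustive/breadth-first oracles used
    to validate the combinatorial machinery on small instances.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
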