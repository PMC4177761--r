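Package: ancenz
Title: Ancestral Enzyme Repertoires from Phylogenetic Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the enzyme repertoire of the last common ancestor (LCA)
    of Bacteria, Archaea and Eukarya from profile-based enzyme annotations
    across genomes. Implements hit-level filtering of RPS-BLAST-style
    profile searches (best hit, E-value, profile coverage), genome
    inclusion rules against taxonomic sampling bias, two-step
    genus-to-clade presence/absence normalization, wide/partial/sparse
    distribution classification, LCA attribution for enzymes widely
    distributed in all three cellular domains, subunit (AND) and analog
    (OR) resolution of multi-profile enzymatic steps, and projection of
    ancestry verdicts onto purine and pyrimidine pathway graphs. A seeded
    synthetic-data generator produces taxonomies, evolved presence/absence
    matrices with ground truth, and hit tables, so the whole pipeline is
    testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
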