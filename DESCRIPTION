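Package: flagdiv
Title: Dual-Level Diversity Analysis of Prokaryotic Flagellins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Curation, clustering and diversity analysis of bacterial and
    archaeal flagellin sequences. Filters candidate proteins by conserved
    N- and C-terminal domain profiles, discriminates flagellins from the
    hook-junction protein FlgL, deduplicates observations into unique
    proteins, groups them by greedy identity clustering, links clusters
    through bit-score-ratio distances into a minimum spanning forest, types
    hypervariable regions into forms and isoforms, quantifies per-taxon
    diversity by the unique-sequence-ratio regression, and computes
    cumulative synonymous/nonsynonymous mutation curves along codon
    alignments. Ships a synthetic panel generator with ground truth so the
    whole pipeline runs and is testable without any sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
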