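Package: hostshiftr
Title: Detecting Endosymbiont Host Shifts from Ortholog Similarity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomic detection of endosymbiont host shifts.
    Reads per-gene multiple sequence alignments for symbiont strains and
    their host species, concatenates them into partitioned supermatrices,
    computes pairwise identity matrices under explicit gap conventions,
    collapses identical sequences and clusters strains into lineages below
    a divergence threshold, classifies host pairs as host-shift versus
    codivergence by contrasting symbiont and host per-gene similarity under
    a proportional molecular clock, and quantifies symbiont-host tree
    incongruence with neighbor-joining trees and Robinson-Foulds distances.
    Includes a seeded host-symbiont coevolution simulator (Yule host trees,
    Poisson host-switching, Jukes-Cantor sequence evolution) that produces
    ground-truth-labelled datasets for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    phangorn,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
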