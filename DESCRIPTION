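Package: anicode
Title: Genome Similarity Codes from Average Nucleotide Identity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fragment-based average nucleotide identity (ANI) between genome
    sequences and a hierarchical, similarity-based code nomenclature built on
    top of it. Genomes are tiled into fixed-length fragments, each fragment is
    locally aligned to a subject genome, and fragments passing coverage and
    identity filters are averaged into an ANI value together with the
    percentage of aligned fragments. New genomes are registered sequentially:
    each receives a 24-position hierarchical code derived from its ANI to the
    most similar previously coded genome, so that the depth of the shared code
    prefix between two organisms reflects their genome similarity. Includes an
    optional core-genome (median-centred) fragment filter to suppress
    horizontally transferred regions, a clade simulator with a mutation ledger
    for validation, and a permutation study quantifying how the order of
    registration affects code similarity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    ape,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
SystemRequirements: Optional BLAST+ (blastn) for the external alignment
    backend.
Config/testthat/edition: 3
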