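Package: cryptgap
Title: Barcoding-Gap Delimitation of Cryptic Species from Multi-Locus DNA Barcodes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for detecting cryptic species in multi-locus DNA-barcoding
    surveys. Computes Kimura two-parameter (K2P) and p-distances from aligned
    COI and 16S sequences with pairwise deletion of gapped and ambiguous
    sites, partitions morphospecies into candidate clades by distance
    clustering or from externally inferred trees with node support, applies
    barcoding-gap and inter/intra divergence-ratio tests, reconciles
    per-locus results into four evidence scenarios, assigns study-style
    species labels (MB numbers, letters for unresolved species complexes),
    and maintains a before/after species-richness ledger. Includes a seeded
    two-locus K2P sequence simulator with planted cryptic structure so the
    whole pipeline can be validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
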