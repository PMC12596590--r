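Package: pseudoscan
Title: Detection and Phylogenetic Dating of Gene-Inactivating Mutations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and classifies gene-inactivating mutations (nonsense
    substitutions, stop-introducing insertions, frameshift indels) in exon-wise
    coding-sequence alignments against one or more reference species, reports
    them in reference-anchored per-exon coordinates, calls pseudogene status per
    gene and functional status of heterodimeric receptors, maps shared lesions
    onto a time-calibrated phylogeny under Dollo parsimony, and brackets
    gene-loss events in time. Includes a coding-sequence decay simulator
    (purifying constraint before a planted loss event, neutral decay after it)
    and deterministic fixture builders, so the whole inference chain can be
    exercised and validated without external data.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
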