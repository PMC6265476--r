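Package: operondetect
Title: Detection of Conserved Gene Arrays in Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Screens assembled bacterial genomes for operon-like gene arrays
    built around one conserved "hit" gene. Candidate coding sequences are
    produced by six-frame translation (with prokaryotic start-codon priority)
    optionally merged with GFF3 annotation, matched against a profile-HMM
    library with HMMER3, and filtered by rule-defined structural requirements
    on the neighbouring "partner" gene (orientation, lengths, maximum distance
    and overlap). Accepted hits, partners and discarded hits are grouped by
    sequence similarity networks (BLAST+ all-vs-all, connected components)
    and reported as per-genome copy-number matrices, detailed operon tables
    and iTOL-ready heatmap datasets. Built-in presets mirror published
    parameterisations for type II toxin-antitoxin systems and RND efflux
    pumps, and a deterministic synthetic-genome generator with planted arrays
    supports end-to-end testing without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
SystemRequirements: HMMER3 (hmmsearch, hmmbuild), NCBI BLAST+ (blastp,
    makeblastdb)
Config/testthat/edition: 3
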