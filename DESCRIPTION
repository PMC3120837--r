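Package: pearlscreen
Title: Screening Shell-Formation Gene Candidates from 3'-Tag EST Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for screening biomineralization gene
    candidates from 3'-tag expressed-sequence-tag (EST) libraries of the
    three shell-forming tissues of the pearl oyster (mantle edge, pallium,
    pearl sac). Covers read simulation with planted tissue archetypes,
    quality trimming, greedy identity clustering of tags into gene
    clusters, transcripts-per-million (TPM) normalization, a
    nacre-dominance fold-change screen, marker-guided hierarchical
    co-clustering, and a Smith-Waterman homology/isoform search against
    panels of known nacreous and prismatic genes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    S4Vectors,
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
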