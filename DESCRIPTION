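Package: vnarpan
Title: Deep-Sequencing Analysis and Simulation of VNAR Display Biopanning
Version: 0.1.0
Authors@R:
    person("Repertoire", "Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing deep-sequencing data from phage- and
    yeast-display biopanning campaigns of VNAR (shark single-domain
    antibody) libraries. Extracts CDR3 clonotypes from amplicon reads via
    configurable framework anchor motifs in all six frames, builds
    per-round clonotype abundance tables, tracks enrichment trajectories,
    computes CDR3 length statistics and cross-library shared-clonotype
    abundance correlations, clusters top clones by pairwise global-alignment
    identity with neighbor-joining trees, and scores rare-codon content of
    CDR3 coding sequences against bundled host codon-usage tables. Includes
    a stochastic biopanning simulator with affinity-driven, avidity-aware
    and codon-usage-penalised selection that emits round-by-round FASTQ
    read sets with ground truth, so every pipeline stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
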