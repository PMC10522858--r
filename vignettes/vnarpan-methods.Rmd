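---
title: "Models and methods behind vnarpan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vnarpan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vnarpan)
```

# The scientific problem

Display biopanning selects antigen binders from a large antibody
library by iterating capture, wash and amplification. When the same
VNAR (shark single-domain antibody) repertoire is cloned into both an
M13 phage display and a yeast surface display format, deep sequencing
of each round shows that the two systems enrich *different* clones from
the *same* starting material. Two mechanistic explanations stand out:

* **Avidity.** A phage particle carries roughly five pIII-fused copies
  of the antibody, so even a weak monomeric binder can be retained
  through multivalent contacts; yeast capture events are effectively
  monovalent per interaction in comparison.
* **Translation bias.** Phage are produced in *E. coli*, where codons
  that are rare for the host depress expression; a CDR3 coding sequence
  heavy in bacterial rare codons displays poorly and is selected
  against regardless of its affinity.

`vnarpan` provides the analysis pipeline for such experiments (CDR3
clonotype extraction, abundance and enrichment statistics, homology
clustering, rare-codon scoring) together with a generative simulator
that encodes exactly these two mechanisms, so the whole pipeline is
testable without sequencing data.

# Clonotype extraction

Reads longer than 400 bp (strictly: a 400 bp read is dropped; the
`strict` flag switches to inclusive) are scanned on both strands in all
three frames. A CDR3 is the translation segment between the end of the
leftmost 5' anchor match (default `[YF][YF]C`, the conserved
framework-3 cysteine block) and the start of the nearest following 3'
anchor match (default `[DN]G[AG]GT`, the framework-4 start) that yields
a stop-free, `N`-free segment of 3–35 residues. When several
frame/strand combinations qualify, the longest anchored span wins, with
ties resolved to the plus strand and the lowest frame — a deterministic
rule that makes extraction independent of read order. Every non-
matching read is tallied under the reason code of the frame that
progressed furthest (`no_5p_anchor`, `no_3p_anchor`, `bad_length`,
`ambiguous_base`, `stop_in_cdr3`), so extracted + rejected always
equals input.

The anchor motifs are configuration, not constants: published studies
rarely state their extraction rule, so the rule here is explicit and
overridable (`anchor_config()`), and the simulator embeds the same
defaults so end-to-end tests are self-consistent.

# Repertoire statistics

The clonotype is the exact CDR3 amino-acid sequence; nucleotide
variants are retained only through the representative (most frequent,
ties lexicographic) coding sequence, which downstream codon analysis
uses. Abundance is `100 * count / total` per round table, always
derived from counts and never stored. Length statistics are computed
over *unique* clonotypes with the lower median for even-sized sets
(the convention is stated because published medians rarely say).
Cross-library comparison is a Pearson correlation of raw abundances
over clonotypes detected in both libraries — raw rather than
log-transformed because the corresponding scatter plots put raw
abundance on both axes; a `log` option exists. Enrichment per clonotype
is the least-squares slope of `ln(abundance)` over rounds with positive
abundance.

# Homology clustering

Pairwise distances are `1 - identity` under Needleman–Wunsch global
alignment with match +1, mismatch 0, linear gap −1 — a deliberately
simple scheme, exposed in configuration, standing in for the web
alignment services often used for this step. Because several
alignments can share the optimal score while differing in identity,
the implementation optimises the lexicographic objective
(score, matches, −length), which is additive and therefore a valid
dynamic program; tests verify it against exhaustive alignment
enumeration. Trees are classical neighbor joining (Saitou–Nei Q
criterion) implemented in-package and returned as `ape::phylo`
objects; negative branch estimates are clamped to zero with a warning.
Cluster membership, qualitative in most figures of this literature, is
made operational as single-linkage connected components at a
configurable distance threshold (default 0.5).

# Rare-codon scoring

Codon usage tables (bundled for *E. coli* K-12 and *S. cerevisiae*,
approximate per-thousand values; headers state provenance) feed the
relative adaptiveness `w = freq / max(synonymous freq)`. Codons are
classed rare (`w < 1/3`), common (`w >= 2/3`) or intermediate —
tertile-style cutoffs, configurable, since the underlying three-group
classifications in the literature never state theirs. All statistics
depend only on within-family frequency ratios, so modest absolute
inaccuracies in the bundled tables cannot change conclusions, and
every test computes its expectations from the bundled table rather
than from published numbers. Cohort statistics score the
representative coding sequence of the top 10 clonotypes (mean and
sample SD); the weighted all-variants alternative was considered and
rejected as the default because the majority variant is the least
ambiguous single choice.

# The biopanning simulator

The simulator is a stated world, not a fitting device. Its defaults:

* **Library.** 200 clones; CDR3 lengths from a discrete mixture over
  8–31 residues with a main peak at 16 and secondary peaks at 22 and
  24 (the multimodal shape reported for immunised VNAR repertoires);
  residues uniform over the 20 amino acids, redrawn if a CDR3 happens
  to contain an anchor motif so ground truth stays unambiguous; codons
  uniform over the synonymous family — the library is cloned from
  shark cDNA and is adapted to *neither* display host, and in paired
  mode one physical library serves both, so no host usage is "the"
  source (a usage table can be supplied to bias codons). Affinities
  are log-uniform over 1 nM – 100 µM, bracketing reported VNAR binder
  constants. Naive counts follow a symmetric Dirichlet(1)-multinomial
  over a pool of 1e5 — a typically skewed immune library.
* **Capture.** `q = exp(-lambda * r/100) * (1 - (1 - b)^valence)` with
  `b = [Ag]/([Ag] + K_D)` at 100 nM antigen: single-site occupancy,
  avidity rescue across the displayed copies (valence 5 for phage's
  five pIII fusions, 1 for yeast), and a codon display penalty driven
  by the clone's rare-codon percentage `r` in the producing host.
  `lambda_phage = 2` makes a clone at the library-average rare content
  (~16%) display at ~72% efficiency and a rare-codon-heavy clone
  (~35%) at ~50% — strong enough for translation bias to reshape the
  selected cohort over four rounds, weak enough to be invisible in a
  single round. Yeast mode sets `lambda = 0`.
* **Rounds.** Four rounds of per-clone binomial capture followed by
  noiseless multinomial re-amplification to the fixed pool size;
  extinction is absorbing, and an all-washout round is redrawn with a
  logged guard. Amplification bias (PCR, growth) is out of scope.
* **Reads.** Per round, `read_depth` (2e4) reads are drawn
  multinomially; each is the full fixed cassette (flanks + frameworks
  embedding the anchors + the clone's CDR3, always > 400 bp) with
  independent per-base substitution errors at 0.001 and uniform
  qualities. Indels, quality decay, chimeras and paired-end structure
  are *not* modelled: a green end-to-end test establishes correctness
  of the pipeline's logic on this idealised read model, not robustness
  to every real-world artefact.

`campaign_round_table()` provides a count-level shortcut (multinomial
read sampling tallied from ground truth, equivalent to error-free
sequencing plus perfect extraction); the equivalence is itself tested,
and the acceptance suite uses the full read-level path where sequencing
error matters.

# Numerical and design choices

* Ties everywhere are broken deterministically (lexicographic CDR3,
  plus strand, lowest frame, smallest matrix index in NJ) so identical
  inputs give byte-identical outputs.
* All randomness flows from one integer seed through small derived
  seeds per stage; campaigns are reproducible end to end.
* The paired-design decorrelation (round-0 shared-abundance
  correlation near 1, round-4 much lower) and the codon-content drop
  in phage-selected top clones are *emergent* from the capture model —
  the tests assert their direction and magnitude class, not figures
  from any particular dataset.
* Degenerate inputs fail loudly: empty tables, fewer than 3 shared
  clonotypes, zero-variance abundance vectors, fewer than 2 positive
  rounds for a slope, and non-finite distances all raise
  undefined-statistic errors rather than returning NA.

# Known limitations

Anchor motifs must match the construct actually sequenced; the
defaults fit the simulator's cassette and common VNAR frameworks but
real amplicon designs may need overrides. The aligner's scoring scheme
is intentionally simple and is not a substitute for substitution-
matrix-based protein alignment when distant homology matters. Bundled
codon usage tables are approximate; for exact reproduction of a
published rare-codon percentage, load the exact table used there via
`load_codon_usage(path)`.
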