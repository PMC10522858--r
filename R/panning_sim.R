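# Fixed synthetic VNAR cassette scaffolding. The frameworks embed the
# default anchor motifs exactly once, so error-free extraction is
# unambiguous: framework-3 ends in YYC (5' anchor) and framework-4
# starts with DGAGT (3' anchor). The 5' nucleotide flank has length
# 32, placing the open reading frame in frame 2 of the read.
FW_PRE_AA <- paste0("MAEVQLVESGGGLVQPGGSL",
                    "ARVDQTPQTITKETGESLTINCVLRDASNTLHSTSWVRKNPGSSNQERI",
                    "SISGRVTVTDDPSKESVSLRIRDLRVEDSGT")
ANCHOR5_AA <- "YYC"
FW_POST_AA <- "DGAGTVLTVNPGH"
FLANK5_NT <- "GGCTGCAGGTCGACTCTAGAGGATCCCCGGGA"
FLANK3_NT <- "TAAGGATCCGAGCTCGAATTCACTGGCCGTCGTTTT"

CODON_OF_AA <- c(A = "GCA", C = "TGC", D = "GAT", E = "GAA", F = "TTC",
                 G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "TTG",
                 M = "ATG", N = "AAC", P = "CCA", Q = "CAA", R = "CGT",
                 S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAC")

encode_aa <- function(aa) {
  paste0(CODON_OF_AA[strsplit(aa, "", fixed = TRUE)[[1]]], collapse = "")
}

#' Assemble a full VNAR cassette read from a CDR3 coding sequence
#'
#' @param cdr3_nt CDR3 coding nucleotides (length a multiple of 3).
#' @return The full-length nucleotide cassette (flanks + frameworks +
#'   CDR3), always longer than 400 bp for CDR3s of 3+ residues.
#' @export
vnar_cassette <- function(cdr3_nt) {
  paste0(FLANK5_NT, encode_aa(FW_PRE_AA), encode_aa(ANCHOR5_AA),
         cdr3_nt, encode_aa(FW_POST_AA), FLANK3_NT)
}

#' Default CDR3 length mixture
#'
#' A discrete mixture over 8-31 residues emulating the observed
#' repertoire shape: a main peak at 16 aa plus secondary peaks at 22
#' and 24 aa, hard maximum 31 aa.
#'
#' @return Data frame with `length` and `weight` (weights sum to 1).
#' @export
default_length_mixture <- function() {
  len <- 8:31
  w <- 0.65 * stats::dnorm(len, 16, 2.5) +
       0.20 * stats::dnorm(len, 22, 1.2) +
       0.15 * stats::dnorm(len, 24, 1.2)
  data.frame(length = len, weight = w / sum(w))
}

#' Simulation configuration
#'
#' Campaign settings for the biopanning simulator. Mode-dependent
#' defaults: phage display presents ~5 VNAR-pIII fusions per particle
#' (`valence = 5`) and is produced in E. coli, where rare-codon content
#' penalises display (`lambda_codon > 0`); yeast display is monovalent
#' per binding event (`valence = 1`) with no codon penalty.
#'
#' @param n_clones Number of distinct clones in the naive library.
#' @param length_mixture Data frame `length`/`weight` for CDR3 lengths.
#' @param rounds Number of selection rounds (default 4).
#' @param pool_size Particles amplified per round (default 1e5).
#' @param read_depth Sequencing reads per round (default 2e4).
#' @param antigen_conc Antigen concentration, molar (default 1e-7).
#' @param kd_range Log-uniform sampling range for clone dissociation
#'   constants, molar (default 1e-9 to 1e-4).
#' @param valence_phage,valence_yeast Displayed copies per particle.
#' @param lambda_phage,lambda_yeast Codon display-penalty rates: the
#'   display efficiency of a clone with rare-codon percentage `r` is
#'   `exp(-lambda * r / 100)`. The phage default of 2 means a clone at
#'   the typical library rare-codon content (~16%) displays at ~72%
#'   efficiency and a rare-codon-heavy clone (35%) at ~50%, a penalty
#'   strong enough for E. coli translation bias to reshape the selected
#'   cohort over four rounds while leaving weak single-round effects.
#' @param dirichlet_alpha Symmetric Dirichlet concentration for the
#'   naive-library clone proportions (1 = a typical skewed library).
#' @param error_rate Per-base substitution probability in sequencing
#'   reads (default 0.001).
#' @param seed Integer seed; all campaign randomness derives from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_clones = 200L,
                       length_mixture = default_length_mixture(),
                       rounds = 4L, pool_size = 1e5L, read_depth = 2e4L,
                       antigen_conc = 1e-7, kd_range = c(1e-9, 1e-4),
                       valence_phage = 5L, valence_yeast = 1L,
                       lambda_phage = 2, lambda_yeast = 0,
                       dirichlet_alpha = 1, error_rate = 0.001,
                       seed = 1L) {
  stopifnot(n_clones >= 1L, rounds >= 1L, pool_size >= 1L,
            read_depth >= 1L, all(length_mixture$weight > 0),
            error_rate >= 0, error_rate < 1, antigen_conc >= 0,
            valence_phage >= 1L, valence_yeast >= 1L,
            lambda_phage >= 0, lambda_yeast >= 0)
  if (any(length_mixture$length > 31L)) {
    warning("length mixture includes CDR3s above the 31 aa cap; ",
            "raise max_cdr3_len accordingly when annotating")
  }
  structure(as.list(environment()), class = "sim_config")
}

mode_params <- function(cfg, mode) {
  switch(mode,
         phage = list(valence = cfg$valence_phage,
                      lambda = cfg$lambda_phage, organism = "bacteria"),
         yeast = list(valence = cfg$valence_yeast,
                      lambda = cfg$lambda_yeast, organism = "yeast"),
         stop("mode must be 'phage' or 'yeast'"))
}

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 10007 + k) %% 2147483647)
}

#' Generate a naive clone library
#'
#' CDR3 lengths are drawn from the length mixture, residues uniformly
#' over the 20 amino acids (sequences that happen to contain an anchor
#' motif are redrawn so ground truth stays unambiguous), and codons per
#' residue from `usage` frequencies (uniform over the synonymous family
#' when `usage` is `NULL`, the neutral default for a library cloned
#' from shark cDNA that is adapted to neither display host). Affinities
#' are log-uniform over `kd_range`, and naive counts follow a symmetric
#' Dirichlet-multinomial over `pool_size`.
#'
#' @param cfg A [sim_config()].
#' @param usage Optional `codon_usage` table biasing codon choice.
#' @param anchors The [anchor_config()] whose motifs are excluded from
#'   CDR3s.
#' @return List with `clones` (data frame `id`, `cdr3_aa`, `cdr3_nt`,
#'   `kd`) and `counts0` (integer vector of naive counts summing to
#'   `pool_size`). Reproducible from `cfg$seed`.
#' @export
generate_library <- function(cfg, usage = NULL, anchors = anchor_config()) {
  set.seed(derive_seed(cfg$seed, 1L))
  n <- cfg$n_clones
  aas <- strsplit(AA20, "", fixed = TRUE)[[1]]
  lens <- sample(cfg$length_mixture$length, n, replace = TRUE,
                 prob = cfg$length_mixture$weight)
  draw_aa <- function(l) {
    repeat {
      s <- paste0(sample(aas, l, replace = TRUE), collapse = "")
      if (!grepl(anchors$five_prime, s, perl = TRUE) &&
          !grepl(anchors$three_prime, s, perl = TRUE)) return(s)
    }
  }
  cdr3_aa <- vapply(lens, draw_aa, character(1))
  fam <- split(SENSE_CODONS, Biostrings::GENETIC_CODE[SENSE_CODONS])
  draw_nt <- function(aa) {
    res <- strsplit(aa, "", fixed = TRUE)[[1]]
    cods <- vapply(res, function(a) {
      f <- fam[[a]]
      p <- if (is.null(usage)) NULL else usage$freq[f]
      if (length(f) == 1L) f else sample(f, 1L, prob = p)
    }, character(1))
    paste0(cods, collapse = "")
  }
  cdr3_nt <- vapply(cdr3_aa, draw_nt, character(1), USE.NAMES = FALSE)
  kd <- 10^stats::runif(n, log10(cfg$kd_range[1]), log10(cfg$kd_range[2]))
  weights <- stats::rgamma(n, shape = cfg$dirichlet_alpha)
  counts0 <- as.integer(stats::rmultinom(1L, cfg$pool_size,
                                         weights / sum(weights)))
  list(clones = data.frame(id = sprintf("clone%04d", seq_len(n)),
                           cdr3_aa = cdr3_aa, cdr3_nt = cdr3_nt, kd = kd,
                           stringsAsFactors = FALSE),
       counts0 = counts0)
}

#' Per-round capture probability of a displayed clone
#'
#' Occupancy times avidity times codon-penalised display:
#' `b = antigen_conc / (antigen_conc + kd)` is the single-site bound
#' fraction, `1 - (1 - b)^valence` the chance that at least one of the
#' displayed copies engages (multivalent rescue of weak binders), and
#' `exp(-lambda_codon * r / 100)` the display efficiency of a clone
#' whose CDR3 coding sequence has `r` percent host-rare codons.
#'
#' @param kd Dissociation constant(s), molar.
#' @param antigen_conc Antigen concentration, molar.
#' @param r Rare-codon percentage(s) in `[0, 100]`.
#' @param lambda_codon Display-penalty rate (0 disables the penalty).
#' @param valence Displayed copies per particle (>= 1).
#' @return Capture probability/ies `q` in `[0, 1]`.
#' @export
capture_probability <- function(kd, antigen_conc, r = 0,
                                lambda_codon = 0, valence = 1L) {
  stopifnot(all(kd > 0), antigen_conc >= 0, all(r >= 0), all(r <= 100),
            lambda_codon >= 0, valence >= 1)
  b <- antigen_conc / (antigen_conc + kd)
  exp(-lambda_codon * r / 100) * (1 - (1 - b)^valence)
}

#' One round of capture-wash-amplify selection
#'
#' Capture is per-clone binomial thinning at probability `q`;
#' amplification redistributes `pool_size` particles multinomially over
#' the captured proportions. If every particle washes out the capture
#' is redrawn (logged), falling back to a single survivor proportional
#' to `counts * q` after 100 attempts.
#'
#' @param counts Integer vector of per-clone particle counts.
#' @param q Per-clone capture probabilities.
#' @param pool_size Post-amplification pool size.
#' @return Integer vector of post-round counts summing to `pool_size`.
#' @export
simulate_round <- function(counts, q, pool_size) {
  stopifnot(length(counts) == length(q), sum(counts) > 0)
  for (attempt in seq_len(100L)) {
    captured <- stats::rbinom(length(counts), counts, q)
    if (sum(captured) > 0L) break
  }
  if (sum(captured) == 0L) {
    message("wash-out guard: no particle captured in 100 draws; ",
            "keeping a single weighted survivor")
    w <- counts * if (sum(q) > 0) q else rep(1, length(q))
    captured[sample.int(length(counts), 1L, prob = w)] <- 1L
  }
  as.integer(stats::rmultinom(1L, pool_size, captured / sum(captured)))
}

#' Simulate a full biopanning campaign
#'
#' Runs `cfg$rounds` rounds of selection on a (generated or supplied)
#' naive library under one display mode. Clone rare-codon percentages
#' are scored against the mode's host usage table (bacteria for phage,
#' yeast for yeast).
#'
#' @param cfg A [sim_config()].
#' @param mode `"phage"` or `"yeast"`.
#' @param library Optional library from [generate_library()] (shared
#'   across modes in paired designs); generated from `cfg` if `NULL`.
#' @return A `panning_campaign`: list with `clones` (library columns
#'   plus `r` and `q`), `counts` (matrix clones x rounds, columns
#'   `R0..R<rounds>`, each summing to `pool_size`), `cfg`, `mode`.
#' @export
simulate_campaign <- function(cfg, mode = c("phage", "yeast"),
                              library = NULL) {
  mode <- match.arg(mode)
  if (is.null(library)) library <- generate_library(cfg)
  mp <- mode_params(cfg, mode)
  usage <- load_codon_usage(mp$organism)
  clones <- library$clones
  clones$r <- vapply(clones$cdr3_nt, rare_codon_fraction, numeric(1),
                     t = usage, USE.NAMES = FALSE)
  clones$q <- capture_probability(clones$kd, cfg$antigen_conc, clones$r,
                                  mp$lambda, mp$valence)
  counts <- matrix(0L, nrow(clones), cfg$rounds + 1L,
                   dimnames = list(clones$id, paste0("R", 0:cfg$rounds)))
  counts[, 1L] <- library$counts0
  set.seed(derive_seed(cfg$seed, 2L + match(mode, c("phage", "yeast"))))
  for (rd in seq_len(cfg$rounds)) {
    counts[, rd + 1L] <- simulate_round(counts[, rd], clones$q,
                                        cfg$pool_size)
  }
  structure(list(clones = clones, counts = counts, cfg = cfg,
                 mode = mode),
            class = "panning_campaign")
}

#' Simulate a paired phage + yeast campaign from one library
#'
#' Both campaigns start from the same generated library and naive
#' counts (one immune repertoire cloned into two display formats) and
#' differ only in mode parameters.
#'
#' @param cfg A [sim_config()].
#' @return List with elements `phage` and `yeast`, each a
#'   `panning_campaign` over the identical clone set.
#' @export
simulate_paired <- function(cfg) {
  library <- generate_library(cfg)
  list(phage = simulate_campaign(cfg, "phage", library),
       yeast = simulate_campaign(cfg, "yeast", library))
}

# Multinomial read counts per clone for one round.
sample_read_counts <- function(campaign, round, seed_offset = 100L) {
  cfg <- campaign$cfg
  cnt <- campaign$counts[, round + 1L]
  if (sum(cnt) == 0L) stop("round ", round, " has no particles")
  set.seed(derive_seed(cfg$seed,
                       seed_offset + round * 10L +
                         match(campaign$mode, c("phage", "yeast"))))
  as.integer(stats::rmultinom(1L, cfg$read_depth, cnt / sum(cnt)))
}

#' Exact clonotype table of one simulated round
#'
#' Samples `read_depth` reads multinomially from the round's clone
#' counts and tallies them directly from ground truth — equivalent to
#' error-free sequencing followed by perfect CDR3 extraction. Use
#' [sample_round_reads()] + [annotate_all()] to exercise the read-level
#' path including sequencing errors.
#'
#' @param campaign A `panning_campaign`.
#' @param round Round index, 0-based (0 = naive input).
#' @return A [round_table()] labelled `"<mode>/R<round>"`.
#' @export
campaign_round_table <- function(campaign, round) {
  rc <- sample_read_counts(campaign, round)
  keep <- rc > 0L
  df <- data.frame(aa = campaign$clones$cdr3_aa[keep],
                   nt = campaign$clones$cdr3_nt[keep],
                   n = rc[keep], stringsAsFactors = FALSE)
  counts <- tapply(df$n, df$aa, sum)
  rep_nt <- vapply(split(df, df$aa), function(g) {
    cand <- g$nt[g$n == max(g$n)]
    sort(cand)[1]
  }, character(1))
  round_table(stats::setNames(as.integer(counts), names(counts)),
              rep_nt[names(counts)],
              label = paste0(campaign$mode, "/R", round))
}

#' Sample error-bearing sequencing reads for one round
#'
#' Each read is the full VNAR cassette of its clone with independent
#' per-base substitution errors at `cfg$error_rate` and a uniform
#' quality string.
#'
#' @param campaign A `panning_campaign`.
#' @param round Round index, 0-based.
#' @return A read data frame (`id`, `seq`, `qual`); read ids encode
#'   mode, round and source clone.
#' @export
sample_round_reads <- function(campaign, round) {
  cfg <- campaign$cfg
  rc <- sample_read_counts(campaign, round, seed_offset = 500L)
  clone_idx <- rep.int(seq_along(rc), rc)
  seqs <- vapply(campaign$clones$cdr3_nt, vnar_cassette, character(1),
                 USE.NAMES = FALSE)[clone_idx]
  if (cfg$error_rate > 0) {
    len <- nchar(seqs)
    nerr <- stats::rbinom(length(seqs), len, cfg$error_rate)
    ei <- rep.int(which(nerr > 0L), nerr[nerr > 0L])
    if (length(ei)) {
      # positions drawn with replacement; a double hit is just one error
      pos <- 1L + floor(stats::runif(length(ei)) * len[ei])
      bases <- c("A", "C", "G", "T")
      old <- match(substring(seqs[ei], pos, pos), bases)
      newb <- bases[1L + (old - 1L + sample.int(3L, length(ei),
                                                replace = TRUE)) %% 4L]
      for (k in seq_along(ei)) {
        substr(seqs[ei[k]], pos[k], pos[k]) <- newb[k]
      }
    }
  }
  data.frame(id = sprintf("%s_R%d_read%06d_%s", campaign$mode, round,
                          seq_along(clone_idx),
                          campaign$clones$id[clone_idx]),
             seq = seqs,
             qual = strrep("I", nchar(seqs)),
             stringsAsFactors = FALSE)
}

#' Write a campaign to disk (FASTQ per round + ground truth TSV)
#'
#' @param campaign A `panning_campaign`.
#' @param dir Output directory (created if needed).
#' @param gzip Compress the FASTQ files.
#' @return Named list of written paths, invisibly.
#' @export
write_campaign <- function(campaign, dir, gzip = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- campaign$cfg
  paths <- list()
  for (rd in 0:cfg$rounds) {
    f <- file.path(dir, sprintf("%s_R%d.fastq%s", campaign$mode, rd,
                                if (gzip) ".gz" else ""))
    write_sequences(sample_round_reads(campaign, rd), f)
    paths[[paste0("R", rd)]] <- f
  }
  gt <- campaign$clones
  gt$kd_M <- gt$kd
  gt$rare_pct <- gt$r
  cn <- paste0("count_r", 0:cfg$rounds)
  gt[cn] <- as.data.frame(campaign$counts)
  gtf <- file.path(dir, paste0(campaign$mode, "_ground_truth.tsv"))
  utils::write.table(gt[c("id", "cdr3_aa", "cdr3_nt", "kd_M", "rare_pct",
                          "q", cn)],
                     gtf, sep = "\t", quote = FALSE, row.names = FALSE)
  paths$ground_truth <- gtf
  invisible(paths)
}
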