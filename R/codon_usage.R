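SENSE_CODONS <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc[gc != "*"])
})

#' Load a codon usage table
#'
#' Reads a per-thousand codon usage table (bundled for the two display
#' hosts: `"bacteria"` = E. coli K-12, `"yeast"` = S. cerevisiae) and
#' precomputes each sense codon's relative adaptiveness
#' `w = freq / max(freq over synonymous codons)`. Codons are classified
#' into three groups by `w`: rare (`w < rare_max_w`), common
#' (`w >= common_min_w`), intermediate otherwise.
#'
#' @param organism `"bacteria"` or `"yeast"`, or a path to a TSV with
#'   columns `codon`, `aa`, `freq_per_thousand` covering all 61 sense
#'   codons.
#' @param rare_max_w,common_min_w Class boundaries on `w`
#'   (defaults 1/3 and 2/3).
#' @return A `codon_usage` object with elements `organism`, `freq`,
#'   `aa`, `w` (all named by codon) and `thresholds`.
#' @export
load_codon_usage <- function(organism = c("bacteria", "yeast"),
                             rare_max_w = 1 / 3, common_min_w = 2 / 3) {
  if (file.exists(organism[1]) && !organism[1] %in% c("bacteria", "yeast")) {
    path <- organism[1]
    name <- tools::file_path_sans_ext(basename(path))
  } else {
    name <- match.arg(organism)
    path <- system.file("extdata",
                        paste0("codon_usage_", name, ".tsv"),
                        package = "vnarpan", mustWork = TRUE)
  }
  stopifnot(0 < rare_max_w, rare_max_w <= common_min_w, common_min_w <= 1)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE)
  if (!setequal(df$codon, SENSE_CODONS)) {
    stop("codon usage table must cover exactly the 61 sense codons")
  }
  if (any(df$freq_per_thousand <= 0)) stop("all frequencies must be > 0")
  freq <- stats::setNames(df$freq_per_thousand, df$codon)[SENSE_CODONS]
  aa <- Biostrings::GENETIC_CODE[SENSE_CODONS]
  fam_max <- tapply(freq, aa, max)
  w <- unname(freq) / fam_max[aa]
  structure(list(organism = name, freq = freq,
                 aa = stats::setNames(aa, SENSE_CODONS),
                 w = stats::setNames(as.numeric(w), SENSE_CODONS),
                 thresholds = c(rare_max_w = rare_max_w,
                                common_min_w = common_min_w)),
            class = "codon_usage")
}

check_sense <- function(t, codon) {
  codon <- toupper(codon)
  bad <- !codon %in% SENSE_CODONS
  if (any(bad)) {
    stop("not a sense codon: ", codon[which(bad)[1]])
  }
  codon
}

#' Relative adaptiveness of a codon
#'
#' `w = freq(codon) / max(freq over its synonymous family)`; the most
#' used codon of every amino acid (and every single-codon family) has
#' `w = 1`.
#'
#' @param t A `codon_usage` table.
#' @param codon Sense codon triplet(s).
#' @return `w` value(s) in `(0, 1]`.
#' @export
relative_adaptiveness <- function(t, codon) {
  stopifnot(inherits(t, "codon_usage"))
  unname(t$w[check_sense(t, codon)])
}

#' Classify a codon as rare, intermediate or common
#'
#' @param t A `codon_usage` table.
#' @param codon Sense codon triplet(s).
#' @return `"rare"` (`w < rare_max_w`), `"common"` (`w >= common_min_w`)
#'   or `"intermediate"` (a codon exactly at `rare_max_w` is
#'   intermediate).
#' @export
classify_codon <- function(t, codon) {
  w <- relative_adaptiveness(t, codon)
  ifelse(w < t$thresholds[["rare_max_w"]], "rare",
         ifelse(w >= t$thresholds[["common_min_w"]], "common",
                "intermediate"))
}

split_codons <- function(nt) {
  nt <- toupper(nt)
  if (nchar(nt) %% 3L != 0L) {
    stop("coding sequence length ", nchar(nt), " is not a multiple of 3")
  }
  substring(nt, seq(1L, nchar(nt), 3L), seq(3L, nchar(nt), 3L))
}

#' Rare-codon percentage of a coding sequence
#'
#' @param nt In-frame coding nucleotide string (no stop codons, no
#'   ambiguous bases; length a multiple of 3).
#' @param t A `codon_usage` table.
#' @return `100 * (#rare codons) / (#codons)`.
#' @export
rare_codon_fraction <- function(nt, t) {
  codons <- split_codons(nt)
  cls <- classify_codon(t, codons)
  100 * sum(cls == "rare") / length(codons)
}

#' Rare-codon statistics over the top clonotypes of a round
#'
#' Scores the representative coding sequence of each of the `top` most
#' abundant clonotypes and reports the mean and sample standard
#' deviation (n-1 denominator; 0 when fewer than 2 sequences) of their
#' rare-codon percentages.
#'
#' @param table A `round_table`.
#' @param t A `codon_usage` table for the display host.
#' @param top Number of top clonotypes to score (default 10).
#' @return List with `mean`, `sd`, `n` and `per_clonotype` (data frame:
#'   `rank`, `cdr3`, `rep_nt`, `n_codons`, `n_rare`, `n_intermediate`,
#'   `n_common`, `rare_pct`).
#' @export
cohort_rare_codon_stats <- function(table, t, top = 10L) {
  stopifnot(inherits(table, "round_table"), top >= 1L)
  tt <- top_n(table, top)
  rows <- lapply(seq_len(nrow(tt)), function(i) {
    nt <- table$rep_nt[[tt$cdr3[i]]]
    cls <- tryCatch(classify_codon(t, split_codons(nt)), error = function(e) {
      warning("skipping clonotype '", tt$cdr3[i], "': ",
              conditionMessage(e))
      NULL
    })
    if (is.null(cls)) return(NULL)
    data.frame(rank = i, cdr3 = tt$cdr3[i], rep_nt = nt,
               n_codons = length(cls), n_rare = sum(cls == "rare"),
               n_intermediate = sum(cls == "intermediate"),
               n_common = sum(cls == "common"),
               rare_pct = 100 * sum(cls == "rare") / length(cls),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  if (is.null(per) || nrow(per) == 0L) {
    stop("no scorable clonotypes in the top ", top)
  }
  list(mean = mean(per$rare_pct),
       sd = if (nrow(per) < 2L) 0 else stats::sd(per$rare_pct),
       n = nrow(per), per_clonotype = per)
}
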