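#' Tally CDR3 records into a round table
#'
#' Clonotype identity is at the amino-acid level; the representative
#' coding sequence of each clonotype is its most frequent nucleotide
#' variant (ties broken by the lexicographically smallest string).
#'
#' @param records Record data frame from [annotate_all()] (columns `aa`
#'   and `nt`), all from one library x round.
#' @param label Round label, e.g. `"phage/R0"`.
#' @return A [round_table()].
#' @export
tally <- function(records, label = "") {
  if (nrow(records) == 0L) stop("tally: no records")
  counts <- table(records$aa)
  nt_by_aa <- split(records$nt, records$aa)
  rep_nt <- vapply(nt_by_aa, function(v) {
    tb <- table(v)
    cand <- names(tb)[tb == max(tb)]
    sort(cand)[1]
  }, character(1))
  round_table(stats::setNames(as.integer(counts), names(counts)),
              rep_nt, label = label)
}

#' Clonotype abundance
#'
#' Abundance of a CDR3 is 100 times its read count divided by the total
#' number of CDR3-bearing reads in the round; a clonotype absent from
#' the table has abundance 0.
#'
#' @param table A `round_table`.
#' @param cdr3 CDR3 amino-acid string(s).
#' @return Abundance percentage(s) in `[0, 100]`.
#' @export
abundance <- function(table, cdr3) {
  stopifnot(inherits(table, "round_table"))
  if (table$total <= 0L) stop("abundance undefined: empty table")
  cnt <- table$counts[cdr3]
  cnt[is.na(cnt)] <- 0L
  unname(100 * cnt / table$total)
}

#' Top-N clonotypes
#'
#' @param table A `round_table`.
#' @param n Number of clonotypes to return (counts descending, ties by
#'   CDR3 lexicographic ascending); fewer if the table is smaller.
#' @return Data frame with `cdr3`, `count`, `abundance_pct`.
#' @export
top_n <- function(table, n) {
  stopifnot(inherits(table, "round_table"), n >= 1L)
  k <- min(as.integer(n), length(table$counts))
  cdr3 <- names(table$counts)[seq_len(k)]   # counts stored pre-sorted
  data.frame(cdr3 = cdr3, count = unname(table$counts[seq_len(k)]),
             abundance_pct = abundance(table, cdr3),
             stringsAsFactors = FALSE)
}

#' Abundance trajectory of one clonotype across rounds
#'
#' @param tables Round-ordered list of `round_table`s from one library.
#' @param cdr3 CDR3 amino-acid string.
#' @return Data frame with `round` (the table labels, in order) and
#'   `abundance_pct` (0 where the clonotype is absent).
#' @export
trajectory <- function(tables, cdr3) {
  stopifnot(length(tables) >= 1L)
  data.frame(round = vapply(tables, `[[`, character(1), "label"),
             abundance_pct = vapply(tables, abundance, numeric(1), cdr3),
             stringsAsFactors = FALSE)
}

#' CDR3 length statistics over unique clonotypes
#'
#' The histogram counts unique CDR3 amino-acid sequences per length
#' (not read-weighted). The median is the lower median for even-sized
#' sets.
#'
#' @param table A `round_table`.
#' @return List with `histogram` (named integer vector, length ->
#'   number of unique CDR3s), `median` and `max`.
#' @export
length_stats <- function(table) {
  stopifnot(inherits(table, "round_table"))
  if (length(table$counts) == 0L) stop("length_stats undefined: empty table")
  lens <- nchar(names(table$counts))
  h <- table(lens)
  sorted <- sort(lens)
  med <- sorted[ceiling(length(sorted) / 2)]   # lower median
  list(histogram = stats::setNames(as.integer(h), names(h)),
       median = as.integer(med), max = max(lens))
}

#' Shared-clonotype abundance correlation between two libraries
#'
#' Pearson correlation of raw abundances over the CDR3s present in BOTH
#' tables; clonotypes seen in only one library are excluded.
#'
#' @param a,b `round_table`s (e.g. the same round of two libraries).
#' @param log Correlate `log10` abundances instead of raw (off by
#'   default; raw matches plotting both axes on a linear scale).
#' @return List with `r` (Pearson coefficient), `n_shared`, and `pairs`
#'   (data frame `cdr3`, `abundance_a`, `abundance_b`).
#' @export
shared_abundance_correlation <- function(a, b, log = FALSE) {
  stopifnot(inherits(a, "round_table"), inherits(b, "round_table"))
  shared <- intersect(names(a$counts), names(b$counts))
  if (length(shared) < 3L) {
    stop("undefined statistic: only ", length(shared),
         " shared clonotypes (need >= 3)")
  }
  xa <- abundance(a, shared)
  xb <- abundance(b, shared)
  if (log) {
    xa <- log10(xa)
    xb <- log10(xb)
  }
  if (stats::sd(xa) == 0 || stats::sd(xb) == 0) {
    stop("undefined statistic: zero variance in shared abundances")
  }
  list(r = stats::cor(xa, xb), n_shared = length(shared),
       pairs = data.frame(cdr3 = shared, abundance_a = xa,
                          abundance_b = xb, stringsAsFactors = FALSE))
}

#' Enrichment slope of a clonotype
#'
#' Least-squares slope of `ln(abundance)` against round index over the
#' rounds where the clonotype has positive abundance. A positive slope
#' is per-round exponential enrichment; `ln 2` means doubling each
#' round.
#'
#' @param tables Round-ordered list of `round_table`s (index 0, 1, ...).
#' @param cdr3 CDR3 amino-acid string.
#' @return List with `slope` (log-abundance per round) and `rounds`
#'   (0-based indices used).
#' @export
estimate_enrichment <- function(tables, cdr3) {
  ab <- vapply(tables, abundance, numeric(1), cdr3)
  rounds <- seq_along(tables) - 1L
  pos <- ab > 0
  if (sum(pos) < 2L) {
    stop("undefined statistic: '", cdr3,
         "' has positive abundance in fewer than 2 rounds")
  }
  x <- rounds[pos]
  y <- log(ab[pos])
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  list(slope = slope, rounds = x)
}
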