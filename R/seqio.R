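#' Read sequences from FASTA or FASTQ
#'
#' Reads an amplicon read set into a data frame with one row per read.
#' Format is auto-detected from the file extension (`.fastq`/`.fq` vs
#' `.fasta`/`.fa`; a trailing `.gz` triggers transparent decompression)
#' unless given explicitly. Sequences are upper-cased; `N` bases are
#' preserved. Duplicate read identifiers within one file are an error.
#'
#' @param path Path to a FASTA or FASTQ file, optionally gzip-compressed.
#' @param format One of `"auto"`, `"fasta"`, `"fastq"`.
#' @return A data frame with columns `id`, `seq` and `qual` (`NA` for
#'   FASTA input), of class `vnar_reads`.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file does not exist: ", path)
  if (format == "auto") {
    base <- sub("\\.gz$", "", path, ignore.case = TRUE)
    ext <- tolower(tools::file_ext(base))
    format <- switch(ext,
      fastq = , fq = "fastq",
      fasta = , fa = , fna = "fasta",
      stop("cannot auto-detect format from extension '.", ext,
           "'; pass format explicitly")
    )
  }
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path,
                     warn = FALSE)
  reads <- if (format == "fastq") parse_fastq(lines) else parse_fasta(lines)
  dup <- duplicated(reads$id)
  if (any(dup)) {
    stop("duplicate read id in ", path, ": ", reads$id[which(dup)[1]])
  }
  reads$seq <- toupper(reads$seq)
  bad <- grepl("[^ACGTN]", reads$seq)
  if (any(bad)) {
    stop("read '", reads$id[which(bad)[1]],
         "' contains characters outside {A,C,G,T,N}")
  }
  class(reads) <- c("vnar_reads", "data.frame")
  reads
}

# FASTQ is parsed as the universal 4-line-per-record layout (Sanger
# qualities); multi-line FASTQ is not supported, matching modern
# instrument output.
parse_fastq <- function(lines) {
  lines <- lines[seq_len(length(lines))]
  if (length(lines) %% 4L != 0L) {
    stop("FASTQ parse error: line count ", length(lines),
         " is not a multiple of 4 (truncated record at end of file)")
  }
  n <- length(lines) %/% 4L
  if (n == 0L) return(empty_reads())
  idx <- seq_len(n)
  hdr <- lines[4L * idx - 3L]
  seq <- lines[4L * idx - 2L]
  plus <- lines[4L * idx - 1L]
  qual <- lines[4L * idx]
  bad_hdr <- !startsWith(hdr, "@")
  if (any(bad_hdr)) {
    i <- which(bad_hdr)[1]
    stop("FASTQ parse error at line ", 4L * i - 3L,
         ": expected header starting with '@'")
  }
  bad_plus <- !startsWith(plus, "+")
  if (any(bad_plus)) {
    i <- which(bad_plus)[1]
    stop("FASTQ parse error at line ", 4L * i - 1L,
         ": expected separator starting with '+'")
  }
  mism <- nchar(qual) != nchar(seq)
  if (any(mism)) {
    i <- which(mism)[1]
    stop("FASTQ parse error at line ", 4L * i,
         ": quality length ", nchar(qual[i]),
         " does not match sequence length ", nchar(seq[i]))
  }
  if (any(nchar(seq) == 0L)) {
    i <- which(nchar(seq) == 0L)[1]
    stop("FASTQ parse error at line ", 4L * i - 2L, ": empty sequence")
  }
  data.frame(id = sub("\\s.*$", "", substring(hdr, 2L)),
             seq = seq, qual = qual, stringsAsFactors = FALSE)
}

parse_fasta <- function(lines) {
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_reads())
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1]) stop("FASTA parse error at line 1: missing '>' header")
  grp <- cumsum(is_hdr)
  ids <- sub("\\s.*$", "", substring(lines[is_hdr], 2L))
  seqs <- vapply(split(lines[!is_hdr], grp[!is_hdr]),
                 paste0, character(1), collapse = "")
  seqs <- seqs[match(seq_along(ids), as.integer(names(seqs)))]
  seqs[is.na(seqs)] <- ""
  if (any(seqs == "")) {
    stop("FASTA parse error: record '", ids[which(seqs == "")[1]],
         "' has no sequence lines")
  }
  data.frame(id = ids, seq = unname(seqs), qual = NA_character_,
             stringsAsFactors = FALSE)
}

empty_reads <- function() {
  data.frame(id = character(0), seq = character(0), qual = character(0),
             stringsAsFactors = FALSE)
}

#' Write reads as FASTQ (or FASTA)
#'
#' @param reads A read data frame as returned by [read_sequences()].
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @param format `"fastq"` (default) or `"fasta"`. FASTQ output uses a
#'   uniform `"I"` quality when `qual` is missing.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(reads, path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (format == "fastq") {
    qual <- reads$qual
    miss <- is.na(qual)
    if (any(miss)) {
      qual[miss] <- vapply(nchar(reads$seq[miss]),
                           function(n) strrep("I", n), character(1))
    }
    out <- rbind(paste0("@", reads$id), reads$seq, "+", qual)
  } else {
    out <- rbind(paste0(">", reads$id), reads$seq)
  }
  writeLines(as.vector(out), con)
  invisible(path)
}

#' Filter reads by length
#'
#' The deposited analysis keeps reads of more than 400 bp; with
#' `strict = TRUE` (the default) a read of exactly `min_len` bases is
#' dropped. The kept/dropped tally is attached as attribute `"tally"`
#' and logged to standard error.
#'
#' @param reads A read data frame.
#' @param min_len Minimum length in bp (default 400).
#' @param strict Keep only reads strictly longer than `min_len`
#'   (default); `FALSE` keeps reads of length `>= min_len`.
#' @param quiet Suppress the log line.
#' @return The kept reads, in input order, with a `tally` attribute
#'   `c(kept =, dropped =)`.
#' @export
filter_by_length <- function(reads, min_len = 400L, strict = TRUE,
                             quiet = FALSE) {
  stopifnot(min_len >= 0)
  len <- nchar(reads$seq)
  keep <- if (strict) len > min_len else len >= min_len
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  tally <- c(kept = sum(keep), dropped = sum(!keep))
  attr(out, "tally") <- tally
  if (!quiet) {
    message("filter_by_length: kept ", tally[["kept"]], ", dropped ",
            tally[["dropped"]], " (min_len ", min_len,
            if (strict) ", strict >)" else ", inclusive >=)")
  }
  out
}

#' Construct a per-round clonotype table
#'
#' A `round_table` holds, for one library x round, the read count of
#' every CDR3 amino-acid clonotype together with a representative coding
#' nucleotide sequence. Abundance is always derived from the counts,
#' never stored.
#'
#' @param counts Named integer vector, CDR3 amino-acid string -> read
#'   count (all positive).
#' @param rep_nt Named character vector over the same names; each entry
#'   must have 3x the amino-acid length.
#' @param label Free-text label, conventionally `"library/R<round>"`.
#' @return An object of class `round_table` with elements `label`,
#'   `counts` (sorted by count descending, ties lexicographic), `rep_nt`
#'   and `total`.
#' @export
round_table <- function(counts, rep_nt, label = "") {
  counts <- unlist(counts)
  if (length(counts) == 0L) stop("round_table: empty counts")
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("round_table: counts must be named by CDR3 amino-acid sequence")
  }
  storage.mode(counts) <- "integer"
  if (any(is.na(counts) | counts <= 0L)) {
    stop("round_table: counts must be positive integers")
  }
  if (!setequal(names(rep_nt), names(counts))) {
    stop("round_table: rep_nt keys must match counts keys")
  }
  rep_nt <- rep_nt[names(counts)]
  bad <- nchar(rep_nt) != 3L * nchar(names(counts))
  if (any(bad)) {
    stop("round_table: rep_nt['", names(counts)[which(bad)[1]],
         "'] is not 3x the amino-acid length")
  }
  ord <- order(-counts, names(counts), method = "radix")
  counts <- counts[ord]
  structure(list(label = label, counts = counts,
                 rep_nt = rep_nt[names(counts)],
                 total = sum(counts)),
            class = "round_table")
}

#' @export
print.round_table <- function(x, ...) {
  cat("round_table '", x$label, "': ", length(x$counts),
      " unique CDR3, ", x$total, " reads\n", sep = "")
  invisible(x)
}

round_table_header <- c("cdr3_aa", "count", "abundance_pct", "rep_nt")

#' Write / read a round table as TSV
#'
#' The on-disk dialect is a UTF-8 TSV with header
#' `cdr3_aa  count  abundance_pct  rep_nt`, sorted by count descending
#' then CDR3 lexicographic. On read, the counts column is authoritative:
#' the stored abundance column is ignored and abundance is recomputed.
#'
#' @param table A `round_table`.
#' @param path Output/input path.
#' @param label Label to attach on read (defaults to the file name).
#' @return `write_round_table` returns `path` invisibly;
#'   `read_round_table` returns a `round_table`.
#' @export
write_round_table <- function(table, path) {
  stopifnot(inherits(table, "round_table"))
  df <- data.frame(cdr3_aa = names(table$counts),
                   count = unname(table$counts),
                   abundance_pct = sprintf(
                     "%.6g", 100 * unname(table$counts) / table$total),
                   rep_nt = unname(table$rep_nt),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_round_table
#' @export
read_round_table <- function(path, label = basename(path)) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  if (!all(round_table_header %in% names(df))) {
    stop("round table format error: header must contain ",
         paste(round_table_header, collapse = ", "))
  }
  cnt <- suppressWarnings(as.numeric(df$count))
  if (any(is.na(cnt)) || any(cnt != round(cnt))) {
    stop("round table format error: non-integer count column")
  }
  round_table(stats::setNames(as.integer(cnt), df$cdr3_aa),
              stats::setNames(df$rep_nt, df$cdr3_aa), label = label)
}
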