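#' Translate one reading frame
#'
#' Standard genetic code; stop codons are rendered as `*`, any codon
#' containing an ambiguous base as `X`. A trailing partial codon is
#' ignored.
#'
#' @param nt Nucleotide string over `{A,C,G,T,N}`.
#' @param offset Frame offset, 0, 1 or 2.
#' @return Amino-acid string of length `floor((nchar(nt) - offset)/3)`.
#' @export
translate_frame <- function(nt, offset = 0L) {
  if (!offset %in% 0:2) stop("offset must be 0, 1 or 2")
  translate_set(nt, offset)
}

# Vectorised frame translation of a character vector of DNA strings.
translate_set <- function(seqs, offset) {
  x <- Biostrings::DNAStringSet(seqs)
  w <- Biostrings::width(x)
  keep <- pmax(0L, ((w - offset) %/% 3L) * 3L)
  x <- Biostrings::subseq(x, start = pmin(offset + 1L, w + 1L), width = keep)
  as.character(Biostrings::translate(
    x, no.init.codon = TRUE, if.fuzzy.codon = "X"))
}

revcomp <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

#' Anchor configuration for CDR3 excision
#'
#' CDR3 boundaries are defined by two amino-acid regular expressions:
#' the end of the 5' (framework-3) match opens the CDR3 and the start of
#' the 3' (framework-4) match closes it. The defaults target the
#' conserved framework-3 `...C` cysteine block (`[YF][YF]C`) and the
#' framework-4 start (`[DN]G[AG]GT`) of VNAR cassettes; both are plain
#' configuration values because upstream construct designs differ.
#'
#' @param five_prime Regular expression over the amino-acid alphabet;
#'   its leftmost match end defines the CDR3 start.
#' @param three_prime Regular expression whose nearest following match
#'   start defines the CDR3 end.
#' @param min_cdr3_len,max_cdr3_len Legal CDR3 length range in residues.
#'   The default ceiling of 35 comfortably exceeds the longest CDR3
#'   reported for VNAR repertoires (31 aa).
#' @return An `anchor_config` object.
#' @export
anchor_config <- function(five_prime = "[YF][YF]C",
                          three_prime = "[DN]G[AG]GT",
                          min_cdr3_len = 3L, max_cdr3_len = 35L) {
  stopifnot(nzchar(five_prime), nzchar(three_prime),
            min_cdr3_len >= 1L, max_cdr3_len >= min_cdr3_len)
  structure(list(five_prime = five_prime, three_prime = three_prime,
                 min_cdr3_len = as.integer(min_cdr3_len),
                 max_cdr3_len = as.integer(max_cdr3_len)),
            class = "anchor_config")
}

REJECT_REASONS <- c("no_5p_anchor", "no_3p_anchor", "bad_length",
                    "ambiguous_base", "stop_in_cdr3")

# Scan one translated frame of many reads for an anchored CDR3.
# Returns a data.frame with one row per read: hit flag, aa sequence,
# 1-based aa start within the translation, aa length, anchored span
# (5' match start .. 3' match end, in residues) and a failure stage
# (index into REJECT_REASONS) for misses.
scan_frame <- function(prot, anchors) {
  n <- length(prot)
  out <- list(hit = logical(n), aa = rep(NA_character_, n),
              aa_start = rep(NA_integer_, n),
              aa_len = rep(NA_integer_, n),
              span = rep(NA_integer_, n), stage = rep(1L, n))
  m5 <- regexpr(anchors$five_prime, prot, perl = TRUE)
  idx <- which(m5 > 0L)
  if (length(idx) == 0L) return(out)
  s5 <- as.integer(m5)[idx]
  e5 <- s5 + attr(m5, "match.length")[idx] - 1L  # last residue of anchor
  out$stage[idx] <- 2L
  suffix <- substring(prot[idx], e5 + 1L)

  legality <- function(cdr3) {
    # 0 = legal, else index into REJECT_REASONS
    fail <- integer(length(cdr3))
    la <- nchar(cdr3)
    fail[la < anchors$min_cdr3_len | la > anchors$max_cdr3_len] <- 3L
    fail[grepl("X", cdr3, fixed = TRUE)] <- 4L
    fail[grepl("*", cdr3, fixed = TRUE)] <- 5L
    fail
  }
  record_hits <- function(k, start3, len3, cdr3) {
    i <- idx[k]
    out$hit[i] <<- TRUE
    out$aa[i] <<- cdr3
    out$aa_start[i] <<- e5[k] + 1L
    out$aa_len[i] <<- nchar(cdr3)
    out$span[i] <<- e5[k] + start3 + len3 - s5[k]
  }

  # fast path: nearest 3' match, vectorised legality
  m3 <- regexpr(anchors$three_prime, suffix, perl = TRUE)
  has3 <- which(m3 > 0L)
  if (length(has3) == 0L) return(out)
  st3 <- as.integer(m3)[has3]
  ln3 <- attr(m3, "match.length")[has3]
  cdr3 <- substr(suffix[has3], 1L, st3 - 1L)
  fail <- legality(cdr3)
  ok <- fail == 0L
  if (any(ok)) record_hits(has3[ok], st3[ok], ln3[ok], cdr3[ok])
  out$stage[idx[has3[!ok]]] <- fail[!ok]
  # slow path: walk later 3' matches of the few illegal-first reads
  for (k in has3[!ok]) {
    g <- gregexpr(anchors$three_prime, suffix[k], perl = TRUE)[[1]]
    if (g[1] < 0L) next
    lens <- attr(g, "match.length")
    for (j in seq_along(g)[-1L]) {
      cd <- substr(suffix[k], 1L, g[j] - 1L)
      if (legality(cd) == 0L) {
        record_hits(k, as.integer(g[j]), lens[j], cd)
        break
      }
    }
  }
  out
}

#' Annotate reads: locate and excise CDR3s in all six frames
#'
#' Every read is scanned on both strands in all three frames for a
#' 5' anchor match followed by a 3' anchor match bracketing a stop-free,
#' `N`-free CDR3 of legal length. When several frame/strand combinations
#' qualify, the one with the longest anchored span (5' match start to 3'
#' match end) wins; ties prefer the plus strand, then the lowest frame.
#' Non-matching reads are tallied under one of the reason codes
#' `no_5p_anchor`, `no_3p_anchor`, `bad_length`, `ambiguous_base`,
#' `stop_in_cdr3` (the code of the frame that progressed furthest).
#'
#' @param reads A read data frame (see [read_sequences()]).
#' @param anchors An [anchor_config()].
#' @return A list with `records` (data frame: `read_id`, `aa`, `nt`,
#'   `frame`, `strand`, `nt_start`, `nt_end`; coordinates are 0-based
#'   half-open on the forward strand of the stored read) and
#'   `rejections` (named integer vector over the reason codes).
#'   `nrow(records) + sum(rejections) == nrow(reads)` always.
#' @export
annotate_all <- function(reads, anchors = anchor_config()) {
  n <- nrow(reads)
  rej <- stats::setNames(integer(length(REJECT_REASONS)), REJECT_REASONS)
  empty <- data.frame(read_id = character(0), aa = character(0),
                      nt = character(0), frame = integer(0),
                      strand = character(0), nt_start = integer(0),
                      nt_end = integer(0), stringsAsFactors = FALSE)
  if (n == 0L) return(list(records = empty, rejections = rej))
  seqs <- reads$seq
  rc <- revcomp(seqs)
  len <- nchar(seqs)

  combos <- vector("list", 6L)
  meta <- data.frame(strand = rep(c("+", "-"), each = 3),
                     frame = rep(0:2, 2))
  for (ci in seq_len(6L)) {
    src <- if (meta$strand[ci] == "+") seqs else rc
    prot <- translate_set(src, meta$frame[ci])
    combos[[ci]] <- scan_frame(prot, anchors)
  }

  span_mat <- vapply(combos, function(d) {
    s <- d$span; s[is.na(s)] <- -1L; s
  }, integer(n))
  span_mat <- matrix(span_mat, nrow = n)
  # longest span wins; earlier combo (+ strand, low frame) wins ties
  best <- max.col(span_mat, ties.method = "first")
  best_span <- span_mat[cbind(seq_len(n), best)]
  is_hit <- best_span > 0L

  recs <- empty
  if (any(is_hit)) {
    ii <- which(is_hit)
    ci <- best[ii]
    aa <- character(length(ii))
    a0 <- integer(length(ii))
    la <- integer(length(ii))
    for (c in unique(ci)) {
      sel <- ci == c
      aa[sel] <- combos[[c]]$aa[ii[sel]]
      a0[sel] <- combos[[c]]$aa_start[ii[sel]]
      la[sel] <- combos[[c]]$aa_len[ii[sel]]
    }
    fr <- meta$frame[ci]
    st <- meta$strand[ci]
    nt0 <- fr + 3L * (a0 - 1L)           # 0-based on strand-oriented seq
    nt1 <- nt0 + 3L * la
    ostart <- ifelse(st == "+", nt0, len[ii] - nt1)
    oend <- ifelse(st == "+", nt1, len[ii] - nt0)
    fwd_nt <- substring(seqs[ii], ostart + 1L, oend)
    nt <- ifelse(st == "+", fwd_nt, revcomp(fwd_nt))
    recs <- data.frame(read_id = reads$id[ii], aa = aa, nt = nt,
                       frame = fr, strand = st,
                       nt_start = as.integer(ostart),
                       nt_end = as.integer(oend),
                       stringsAsFactors = FALSE)
    rownames(recs) <- NULL
  }
  if (any(!is_hit)) {
    stage_mat <- vapply(combos, function(d) d$stage, integer(n))
    stage_mat <- matrix(stage_mat, nrow = n)
    miss_stage <- apply(stage_mat[!is_hit, , drop = FALSE], 1L, max)
    tab <- table(factor(REJECT_REASONS[miss_stage], levels = REJECT_REASONS))
    rej <- rej + as.integer(tab)
    names(rej) <- REJECT_REASONS
  }
  list(records = recs, rejections = rej)
}

#' Locate the VNAR CDR3 in a single read
#'
#' Convenience wrapper over [annotate_all()] for one read.
#'
#' @param read A one-row read data frame, or a list with `id` and `seq`.
#' @param anchors An [anchor_config()].
#' @return A one-row record data frame on a hit, or an object of class
#'   `vnar_nohit` whose `$reason` names the rejection code.
#' @export
locate_vnar <- function(read, anchors = anchor_config()) {
  df <- data.frame(id = read$id, seq = read$seq, qual = NA_character_,
                   stringsAsFactors = FALSE)
  res <- annotate_all(df, anchors)
  if (nrow(res$records) == 1L) return(res$records)
  structure(list(reason = names(which(res$rejections == 1L))[1]),
            class = "vnar_nohit")
}
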