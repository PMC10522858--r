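# Independent oracles and fixture builders shared across the suite.

# One fixed codon per amino acid, for building rep_nt strings in
# fixtures (independent of the package's own cassette codon map).
ORACLE_CODON <- c(A = "GCC", C = "TGT", D = "GAC", E = "GAG", F = "TTT",
                  G = "GGC", H = "CAC", I = "ATC", K = "AAG", L = "CTG",
                  M = "ATG", N = "AAT", P = "CCG", Q = "CAG", R = "CGC",
                  S = "AGC", T = "ACC", V = "GTG", W = "TGG", Y = "TAT")

aa_to_nt <- function(aa) {
  paste0(ORACLE_CODON[strsplit(aa, "", fixed = TRUE)[[1]]],
         collapse = "")
}

make_table <- function(counts, label = "lib/R0") {
  round_table(counts,
              stats::setNames(vapply(names(counts), aa_to_nt,
                                     character(1)), names(counts)),
              label = label)
}

random_aa <- function(len, alphabet = c("A", "C", "D", "E", "F", "G",
                                        "H", "I", "K", "L", "M", "N",
                                        "P", "Q", "R", "S", "T", "V",
                                        "W", "Y")) {
  paste0(sample(alphabet, len, replace = TRUE), collapse = "")
}

random_round_table <- function(n, label = "lib/R0") {
  aa <- unique(replicate(n, random_aa(sample(5:20, 1))))
  counts <- stats::setNames(sample.int(500L, length(aa), replace = TRUE),
                            aa)
  make_table(counts, label)
}

# Exhaustive-enumeration global alignment: walks every monotone
# alignment path and returns the lexicographic optimum of
# (score, matches, -length) under match +1 / mismatch 0 / gap -1.
# Exponential -- only for short strings.
nw_oracle <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  nx <- length(x)
  ny <- length(y)
  best <- NULL
  better <- function(s, m, l) {
    is.null(best) || s > best[1] ||
      (s == best[1] && (m > best[2] || (m == best[2] && l < best[3])))
  }
  rec <- function(i, j, s, m, l) {
    if (i > nx && j > ny) {
      if (better(s, m, l)) best <<- c(s, m, l)
      return(invisible(NULL))
    }
    if (i <= nx && j <= ny) {
      mt <- as.integer(x[i] == y[j])
      rec(i + 1L, j + 1L, s + mt, m + mt, l + 1L)
    }
    if (i <= nx) rec(i + 1L, j, s - 1L, m, l + 1L)
    if (j <= ny) rec(i, j + 1L, s - 1L, m, l + 1L)
  }
  rec(1L, 1L, 0L, 0L, 0L)
  list(score = best[1], matches = best[2], length = best[3],
       identity = best[2] / best[3])
}

# A random unrooted tree with strictly positive branch lengths plus its
# additive (path-length) distance matrix.
random_additive_case <- function(n_taxa) {
  tr <- ape::unroot(ape::rtree(n_taxa, br = NULL))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 1)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# Minimal FASTQ/FASTA text writers (independent of write_sequences).
write_fastq_text <- function(ids, seqs, path, quals = NULL) {
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), path)
  path
}

write_fasta_text <- function(ids, seqs, path) {
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}
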