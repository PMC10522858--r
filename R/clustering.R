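AA20 <- "ACDEFGHIKLMNPQRSTVWY"

#' Global alignment identity between two sequences
#'
#' Needleman-Wunsch with match +1, mismatch 0, linear gap -1. Among
#' equal-score alignments the one with the most matches, then the
#' shortest, is chosen (a deterministic, order-independent tie-break),
#' and identity is matches / alignment length.
#'
#' @param a,b Amino-acid strings.
#' @return List with `score`, `matches`, `length` and `identity`.
#' @export
nw_identity <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(x)
  m <- length(y)
  # DP over the lexicographic objective (score, matches, -length);
  # all three terms are additive so the composite optimum is a DP too.
  S <- matrix(0L, n + 1L, m + 1L)
  M <- matrix(0L, n + 1L, m + 1L)
  L <- matrix(0L, n + 1L, m + 1L)
  S[, 1L] <- -(0:n); L[, 1L] <- 0:n
  S[1L, ] <- -(0:m); L[1L, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      mt <- if (x[i] == y[j]) 1L else 0L
      s3 <- c(S[i, j] + mt, S[i, j + 1L] - 1L, S[i + 1L, j] - 1L)
      m3 <- c(M[i, j] + mt, M[i, j + 1L], M[i + 1L, j])
      l3 <- c(L[i, j], L[i, j + 1L], L[i + 1L, j]) + 1L
      best <- order(-s3, -m3, l3)[1L]
      S[i + 1L, j + 1L] <- s3[best]
      M[i + 1L, j + 1L] <- m3[best]
      L[i + 1L, j + 1L] <- l3[best]
    }
  }
  list(score = S[n + 1L, m + 1L], matches = M[n + 1L, m + 1L],
       length = L[n + 1L, m + 1L],
       identity = M[n + 1L, m + 1L] / L[n + 1L, m + 1L])
}

#' Pairwise identity distance matrix
#'
#' Distance is `1 - identity` under [nw_identity()] for every sequence
#' pair; the diagonal is zero and the matrix symmetric by construction.
#'
#' @param seqs Character vector of at least two distinct, non-empty
#'   amino-acid sequences (used as matrix labels).
#' @return Symmetric numeric matrix with `seqs` as dimnames, values in
#'   `[0, 1]`.
#' @export
pairwise_distances <- function(seqs) {
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  if (anyDuplicated(seqs)) stop("sequences must be distinct (they label the matrix)")
  if (any(!nzchar(seqs))) stop("empty sequence")
  bad <- grepl(sprintf("[^%s]", AA20), seqs)
  if (any(bad)) stop("non-amino-acid characters in: ", seqs[which(bad)[1]])
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(seqs, seqs))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d[i, j] <- d[j, i] <- 1 - nw_identity(seqs[i], seqs[j])$identity
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical neighbor joining (Saitou-Nei Q criterion, iterative pair
#' joining). Negative branch-length estimates are clamped to zero with
#' a warning. Two taxa yield a single edge split evenly.
#'
#' @param d Symmetric numeric matrix with zero diagonal and unique
#'   dimnames (e.g. from [pairwise_distances()]).
#' @return An unrooted `ape::phylo` tree whose leaves are the matrix
#'   labels.
#' @export
nj_tree <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d) || nrow(d) < 2L) {
    stop("d must be a square matrix with >= 2 taxa")
  }
  if (any(!is.finite(d))) stop("non-finite distances")
  labels <- rownames(d)
  if (is.null(labels) || anyDuplicated(labels)) {
    stop("d must have unique row names")
  }
  clamped <- FALSE
  bl <- function(v) {
    if (v < 0) clamped <<- TRUE
    max(v, 0)
  }
  fmt <- function(node, v) paste0(node, ":", sprintf("%.10g", bl(v)))
  nodes <- labels                       # newick fragment per active node
  D <- unname(d)
  while (length(nodes) > 3L) {
    r <- length(nodes)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    k <- arrayInd(which.min(Q), dim(Q))
    i <- min(k); j <- max(k)
    vi <- 0.5 * D[i, j] + (R[i] - R[j]) / (2 * (r - 2))
    vj <- D[i, j] - vi
    merged <- paste0("(", fmt(nodes[i], vi), ",", fmt(nodes[j], vj), ")")
    du <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    nodes <- c(nodes[keep], merged)
  }
  nwk <- if (length(nodes) == 2L) {
    paste0("(", fmt(nodes[1], D[1, 2] / 2), ",",
           fmt(nodes[2], D[1, 2] / 2), ");")
  } else {
    va <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
    vb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
    vc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
    paste0("(", fmt(nodes[1], va), ",", fmt(nodes[2], vb), ",",
           fmt(nodes[3], vc), ");")
  }
  if (clamped) warning("negative neighbor-joining branch length clamped to 0")
  ape::read.tree(text = nwk)
}

#' Write a tree as newick
#'
#' @param tree An `ape::phylo` tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}

#' Single-linkage clusters at an identity-distance threshold
#'
#' Connected components of the graph joining every pair at distance
#' `<= threshold`. Cluster ids are assigned by descending cluster size,
#' ties by the lexicographically smallest member.
#'
#' @param d Distance matrix (as from [pairwise_distances()]).
#' @param threshold Distance threshold in `[0, 1]` (default 0.5).
#' @return Named integer vector, label -> cluster id (1-based).
#' @export
assign_clusters <- function(d, threshold = 0.5) {
  labels <- rownames(d)
  n <- nrow(d)
  comp <- seq_len(n)
  adj <- d <= threshold
  # label propagation to connected-component minima
  repeat {
    nxt <- vapply(seq_len(n), function(i) min(comp[adj[i, ]]), integer(1))
    if (identical(nxt, comp)) break
    comp <- nxt
  }
  groups <- split(labels, comp)
  ord <- order(-lengths(groups),
               vapply(groups, function(g) sort(g)[1], character(1)),
               method = "radix")
  out <- integer(n)
  names(out) <- labels
  for (k in seq_along(ord)) out[groups[[ord[k]]]] <- k
  out
}
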