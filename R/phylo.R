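#' @importFrom ape nj prop.clades as.phylo
NULL

seqToChars <- function(s) {
  if (is(s, "XString")) s <- as.character(s)
  strsplit(toupper(as.character(s)), "", fixed = TRUE)[[1]]
}

#' Kimura two-parameter distance between two aligned sequences
#'
#' Counts transitions (A<->G, C<->T) and transversions over the usable
#' sites and evaluates the K2P distance
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`,
#' where `P` and `Q` are the transition and transversion fractions.
#' Sites with a gap or `N` in either sequence are excluded (pairwise
#' deletion).
#'
#' @param a,b aligned sequences of equal length (character strings or
#'   [Biostrings::DNAString]).
#' @return distance in substitutions per site (>= 0).
#' @examples
#' k2pDistance("ACGT", "ACGA") # one transversion: ~0.3170
#' k2pDistance("ACGT", "GCGT") # one transition:   ~0.3466
#' @export
k2pDistance <- function(a, b) {
  x <- seqToChars(a)
  y <- seqToChars(b)
  if (length(x) != length(y)) stop("sequences must be aligned to equal length")
  nuc <- c("A", "C", "G", "T")
  use <- x %in% nuc & y %in% nuc
  n <- sum(use)
  if (n == 0) stop("no usable sites after pairwise deletion")
  x <- x[use]
  y <- y[use]
  diff <- x != y
  purine <- c("A", "G")
  transition <- diff & ((x %in% purine) == (y %in% purine))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    stop("K2P distance undefined: sequences are saturated (1-2P-Q or 1-2Q <= 0)")
  }
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Pairwise K2P distance matrix for an alignment
#'
#' @param aln a [Biostrings::DNAStringSet] of aligned sequences, a named
#'   character vector, or a character matrix (taxa in rows).
#' @return symmetric matrix of K2P distances with zero diagonal.
#' @export
k2pMatrix <- function(aln) {
  m <- alignmentToMatrix(aln)
  n <- nrow(m)
  ids <- rownames(m)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2) return(d)
  seqs <- apply(m, 1, paste, collapse = "")
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- k2pDistance(seqs[i], seqs[j])
    }
  }
  d
}

alignmentToMatrix <- function(aln) {
  if (is.matrix(aln)) {
    m <- toupper(aln)
  } else if (is(aln, "DNAStringSet") || is.character(aln)) {
    ch <- as.character(aln)
    if (length(unique(nchar(ch))) > 1) stop("sequences must have equal length")
    m <- do.call(rbind, strsplit(toupper(ch), "", fixed = TRUE))
    rownames(m) <- names(ch)
  } else {
    stop("unsupported alignment representation")
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("t", seq_len(nrow(m)))
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via [ape::nj()]): the pair
#' minimizing the Q criterion is joined, branch lengths are split by the
#' two-branch formula, and the matrix is reduced, until the tree is
#' resolved. Negative branch-length estimates (a known small-sample
#' artefact of NJ) are clamped to zero for display; the raw lengths are
#' kept in the `raw_edge_length` attribute of the returned tree.
#'
#' @param d symmetric distance matrix (>= 3 taxa).
#' @return an unrooted [ape] `phylo` tree with non-negative branch
#'   lengths; attribute `raw_edge_length` carries the unclamped values.
#' @export
njTree <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (nrow(d) < 3) stop("neighbor-joining needs at least 3 taxa")
  tr <- nj(d)
  raw <- tr$edge.length
  tr$edge.length <- pmax(raw, 0)
  attr(tr, "raw_edge_length") <- raw
  tr
}

#' Bootstrap support for a K2P neighbor-joining tree
#'
#' Builds the reference NJ tree from the full alignment, then resamples
#' alignment columns with replacement `n_reps` times, rebuilds an NJ tree
#' from K2P distances on each replicate, and reports for every internal
#' edge of the reference tree the fraction of replicates containing the
#' same (unrooted) bipartition. Replicates whose resampled columns make
#' a K2P distance undefined (saturation, or no usable sites for a pair)
#' are skipped and counted; more than 10% skipped is an error.
#'
#' @param aln alignment as in [k2pMatrix()] (>= 3 taxa).
#' @param n_reps bootstrap replicates (default 1000).
#' @param seed integer seed for column resampling.
#' @return list with `tree` (reference `phylo`, `node.label` set to the
#'   support fractions), `support` (numeric per internal node, `NA` for
#'   the root entry), `n_used` and `n_skipped`.
#' @export
bootstrapSupport <- function(aln, n_reps = 1000, seed = 1) {
  m <- alignmentToMatrix(aln)
  if (nrow(m) < 3) stop("bootstrap support needs >= 3 taxa")
  ref <- njTree(k2pMatrix(m))
  set.seed(seed)
  trees <- vector("list", n_reps)
  skipped <- 0L
  for (r in seq_len(n_reps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    tr <- tryCatch(njTree(k2pMatrix(m[, cols, drop = FALSE])),
                   error = function(e) NULL)
    if (is.null(tr)) skipped <- skipped + 1L else trees[[r]] <- tr
  }
  if (skipped > 0.1 * n_reps) {
    stop(sprintf("%d of %d bootstrap replicates were saturated", skipped, n_reps))
  }
  trees <- trees[!vapply(trees, is.null, logical(1))]
  counts <- prop.clades(ref, trees, rooted = FALSE)
  support <- counts / length(trees)
  ref$node.label <- formatC(support, format = "g")
  list(tree = ref, support = support, n_used = length(trees),
       n_skipped = skipped)
}
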