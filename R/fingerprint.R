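#' @importFrom stats hclust cutree as.dist
NULL

## Pairs of bands x (from profile a) and y (from b) are matchable iff
## |x - y| <= tol * (x + y) / 2, i.e. the tolerance is proportional to
## the mean of the two sizes — symmetric in the two bands, the usual
## gel-analysis convention for a "2% tolerance in terms of band size".
matchablePairs <- function(a, b, tol) {
  if (!length(a) || !length(b)) {
    return(data.frame(i = integer(), j = integer(), d = numeric()))
  }
  g <- expand.grid(i = seq_along(a), j = seq_along(b))
  d <- abs(a[g$i] - b[g$j])
  ok <- d <= tol * (a[g$i] + b[g$j]) / 2
  out <- data.frame(i = g$i[ok], j = g$j[ok], d = d[ok])
  ## deterministic order: closest pairs first, ties by band position
  out[order(out$d, out$i, out$j), , drop = FALSE]
}

## Maximum bipartite matching over the matchable pairs (augmenting paths;
## profiles are small, so the O(V E) bound is irrelevant in practice).
maximumMatching <- function(pairs, na, nb) {
  adj <- split(pairs$j, factor(pairs$i, levels = seq_len(na)))
  match_b <- rep(NA_integer_, nb)
  seen <- rep(FALSE, nb)
  tryAugment <- function(i) {
    for (j in adj[[i]]) {
      if (!seen[j]) {
        seen[j] <<- TRUE
        if (is.na(match_b[j]) || tryAugment(match_b[j])) {
          match_b[j] <<- i
          return(TRUE)
        }
      }
    }
    FALSE
  }
  m <- 0L
  for (i in seq_len(na)) {
    seen[] <- FALSE
    if (tryAugment(i)) m <- m + 1L
  }
  m
}

#' Count matched bands between two fingerprint profiles
#'
#' One-to-one matching of fragment sizes under a proportional tolerance:
#' bands `x` and `y` are matchable iff `|x - y| <= tol * (x + y) / 2`.
#' The default `"greedy"` method fixes the matching by a single pass over
#' matchable pairs ordered by size difference ascending (each band used
#' once); `"optimal"` computes a maximum bipartite matching instead, for
#' profiles so ambiguous that greedy pairing could drop a match. The two
#' agree on well-separated gels.
#'
#' @param a,b numeric vectors of fragment sizes (bp), sorted ascending.
#' @param tol relative tolerance (default 0.02, i.e. 2%).
#' @param method `"greedy"` (default) or `"optimal"`.
#' @return integer count of matched band pairs.
#' @examples
#' matchBands(c(100, 200, 300), c(101, 200, 400)) # 2
#' @export
matchBands <- function(a, b, tol = 0.02, method = c("greedy", "optimal")) {
  method <- match.arg(method)
  if (tol < 0) stop("tol must be non-negative")
  pairs <- matchablePairs(a, b, tol)
  if (!nrow(pairs)) return(0L)
  if (method == "optimal") {
    return(maximumMatching(pairs, length(a), length(b)))
  }
  used_a <- rep(FALSE, length(a))
  used_b <- rep(FALSE, length(b))
  m <- 0L
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]
    j <- pairs$j[k]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- used_b[j] <- TRUE
      m <- m + 1L
    }
  }
  m
}

#' Jaccard similarity of two band profiles
#'
#' `m / (|a| + |b| - m)` with `m = matchBands(a, b, tol)`; two empty
#' profiles are defined as identical (similarity 1). With `tol = 0` this
#' reduces to the exact multiset Jaccard coefficient on band sizes.
#'
#' @inheritParams matchBands
#' @return similarity in `[0, 1]`.
#' @examples
#' jaccardSimilarity(c(100, 200, 300), c(101, 200, 400)) # 0.5
#' @export
jaccardSimilarity <- function(a, b, tol = 0.02, method = c("greedy", "optimal")) {
  if (!length(a) && !length(b)) return(1)
  m <- matchBands(a, b, tol, method)
  m / (length(a) + length(b) - m)
}

#' Pairwise Jaccard similarity matrix for a set of band profiles
#'
#' @param bands named list of band-size vectors (e.g. [bandProfiles()]).
#' @inheritParams matchBands
#' @return symmetric matrix with unit diagonal, dimnames = strain ids.
#' @export
bandSimilarityMatrix <- function(bands, tol = 0.02,
                                 method = c("greedy", "optimal")) {
  method <- match.arg(method)
  n <- length(bands)
  ids <- names(bands)
  s <- diag(1, n)
  dimnames(s) <- list(ids, ids)
  if (n < 2) return(s)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s[i, j] <- s[j, i] <- jaccardSimilarity(bands[[i]], bands[[j]],
                                              tol, method)
    }
  }
  s
}

#' UPGMA dendrogram from a similarity matrix
#'
#' Average-linkage (UPGMA) agglomeration on the distance `1 - s`; the
#' cluster-pair distance is the size-weighted arithmetic mean over all
#' cross pairs, so merge heights are monotone non-decreasing. Merge
#' similarities are `1 - height`.
#'
#' @param sim symmetric similarity matrix in `[0, 1]` with unit diagonal.
#' @return an [stats::hclust] object (heights are distances `1 - s`).
#' @examples
#' s <- matrix(c(1, .9, .2, .9, 1, .4, .2, .4, 1), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' upgmaDendrogram(s)$height # 0.1, then 0.7
#' @export
upgmaDendrogram <- function(sim) {
  stopifnot(is.matrix(sim), nrow(sim) == ncol(sim))
  if (max(abs(sim - t(sim))) > 1e-12) stop("similarity matrix must be symmetric")
  if (any(sim < -1e-12 | sim > 1 + 1e-12)) stop("similarities must lie in [0, 1]")
  if (any(abs(diag(sim) - 1) > 1e-12)) stop("diagonal must be 1")
  if (nrow(sim) < 2) {
    stop("UPGMA needs at least two profiles; a single strain is its own group")
  }
  hclust(as.dist(1 - sim), method = "average")
}

#' Cut a dendrogram into similarity groups
#'
#' Groups are the maximal subtrees all of whose internal merge
#' similarities are at least `cutoff` (i.e. the partition obtained by
#' cutting the tree at distance `1 - cutoff`). Group numbers are assigned
#' by first appearance in the input strain order.
#'
#' @param dend an [stats::hclust] from [upgmaDendrogram()].
#' @param cutoff similarity cutoff in `[0, 1]` (default 0.70, the
#'   conventional similarity-cluster definition for rep-PCR diversity
#'   studies).
#' @return named integer vector of group memberships.
#' @export
cutClusters <- function(dend, cutoff = 0.70) {
  if (cutoff < 0 || cutoff > 1) stop("cutoff must lie in [0, 1]")
  grp <- cutree(dend, h = 1 - cutoff + 1e-12)
  ## renumber by first appearance in input order
  first <- unique(grp)
  out <- match(grp, first)
  names(out) <- names(grp)
  out
}

#' Count distinct fingerprint profiles at a similarity threshold
#'
#' Cuts the UPGMA dendrogram at `threshold` (default 0.95) and reports
#' the number of distinct profile groups; groups of two or more strains
#' are the near-clonal sets.
#'
#' @param sim similarity matrix from [bandSimilarityMatrix()].
#' @param threshold similarity threshold in `[0, 1]` (default 0.95).
#' @return list with `n_profiles`, `groups` (named membership vector)
#'   and `clonal_sets` (list of strain-id vectors of size >= 2).
#' @export
countProfiles <- function(sim, threshold = 0.95) {
  if (nrow(sim) == 0) {
    return(list(n_profiles = 0L, groups = integer(), clonal_sets = list()))
  }
  if (nrow(sim) == 1) {
    g <- setNames(1L, rownames(sim))
    return(list(n_profiles = 1L, groups = g, clonal_sets = list()))
  }
  groups <- cutClusters(upgmaDendrogram(sim), threshold)
  sizes <- table(groups)
  clonal <- lapply(as.integer(names(sizes)[sizes >= 2]),
                   function(g) names(groups)[groups == g])
  list(n_profiles = length(sizes), groups = groups, clonal_sets = clonal)
}
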