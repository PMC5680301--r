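#' Pairwise co-clustering similarity between two clusterings
#'
#' For every pair of cell lines, counts in how many of the two clusterings
#' (0, 1 or 2) the pair falls in the same cluster. The diagonal is 2 by
#' convention. The matrix is invariant under relabeling of clusters in
#' either input.
#'
#' @param a,b `CellLineClustering` objects over identical sample sets.
#' @return list of class `"SimilarityMatrix"`: `sample_ids` and `counts`
#'   (symmetric integer matrix with entries in 0..2).
#' @export
build_similarity_matrix <- function(a, b) {
  stopifnot(inherits(a, "CellLineClustering"),
            inherits(b, "CellLineClustering"))
  if (!setequal(a$sample_ids, b$sample_ids))
    stop("the two clusterings cover different sample sets", call. = FALSE)
  ids <- a$sample_ids
  la <- a$labels[ids]
  lb <- b$labels[ids]
  counts <- outer(la, la, "==") + outer(lb, lb, "==")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(ids, ids)
  structure(list(sample_ids = ids, counts = counts),
            class = "SimilarityMatrix")
}

#' Cross-dataset clustering concordance accuracy
#'
#' Summarizes a pairwise similarity matrix as the fraction of cell-line
#' pairs on which the two clusterings agree. Two readings of "number of
#' times clustered together divided by possible combinations" are computed:
#' \describe{
#'   \item{jaccard}{pairs co-clustered in both datasets divided by pairs
#'     co-clustered in at least one (the headline figure; uninformative
#'     never-co-clustered pairs are excluded). Defined as 0, with a warning,
#'     when no pair co-clusters anywhere.}
#'   \item{rand}{pairs on which the clusterings agree (co-clustered in both
#'     or in neither) divided by all pairs - the Rand index.}
#' }
#'
#' @param sim `SimilarityMatrix` over >= 2 samples.
#' @return list of class `"ConcordanceAccuracy"` with elements `jaccard`,
#'   `rand` and the pair counts behind them.
#' @export
concordance_accuracy <- function(sim) {
  stopifnot(inherits(sim, "SimilarityMatrix"))
  n <- length(sim$sample_ids)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  v <- sim$counts[upper.tri(sim$counts)]
  n_pairs <- length(v)
  both <- sum(v == 2L)
  any_one <- sum(v >= 1L)
  neither <- sum(v == 0L)
  if (any_one == 0L) {
    warning("no pair co-clusters in either dataset; jaccard accuracy ",
            "defined as 0")
    jac <- 0
  } else {
    jac <- both / any_one
  }
  structure(list(jaccard = jac, rand = (both + neither) / n_pairs,
                 pairs_both = both, pairs_any = any_one,
                 pairs_neither = neither, pairs_total = n_pairs),
            class = "ConcordanceAccuracy")
}

#' @export
print.ConcordanceAccuracy <- function(x, ...) {
  cat(sprintf(
    "Concordance accuracy: %.3f (jaccard-style), %.3f (rand-style) over %d pairs\n",
    x$jaccard, x$rand, x$pairs_total))
  invisible(x)
}

# maximum-weight injective assignment on a non-negative overlap matrix.
# stages run over the larger dimension, a bitmask over the smaller one;
# exact, suitable for the tens of clusters encountered here.
.assign_max_overlap <- function(ov) {
  nr <- nrow(ov)
  nc <- ncol(ov)
  transposed <- nc > nr
  m <- if (transposed) t(ov) else ov    # columns = smaller side
  ns <- nrow(m)
  nb <- ncol(m)
  if (nb > 16L)
    stop("cluster-matching supports at most 16 clusters on the smaller side",
         call. = FALSE)
  n_mask <- bitwShiftL(1L, nb)
  best <- matrix(-Inf, ns + 1L, n_mask)
  best[1L, 1L] <- 0
  choice <- array(0L, dim = c(ns + 1L, n_mask))
  for (i in seq_len(ns)) {
    for (mask in which(is.finite(best[i, ])) - 1L) {
      val <- best[i, mask + 1L]
      # leave row i unmatched
      if (val > best[i + 1L, mask + 1L]) {
        best[i + 1L, mask + 1L] <- val
        choice[i + 1L, mask + 1L] <- 0L
      }
      for (j in seq_len(nb)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(mask, bit) == 0L) {
          nm <- bitwOr(mask, bit)
          nv <- val + m[i, j]
          if (nv > best[i + 1L, nm + 1L]) {
            best[i + 1L, nm + 1L] <- nv
            choice[i + 1L, nm + 1L] <- j
          }
        }
      }
    }
  }
  final_mask <- which.max(best[ns + 1L, ]) - 1L
  assign_small <- integer(ns)
  mask <- final_mask
  for (i in rev(seq_len(ns))) {
    j <- choice[i + 1L, mask + 1L]
    assign_small[i] <- j
    if (j > 0L) mask <- bitwAnd(mask, bitwNot(bitwShiftL(1L, j - 1L)))
  }
  # map back to row->column of the original matrix
  pairs <- cbind(row = seq_len(ns), col = assign_small)
  pairs <- pairs[pairs[, 2L] > 0L, , drop = FALSE]
  if (transposed) pairs <- pairs[, c(2L, 1L), drop = FALSE]
  list(rows = pairs[, 1L], cols = pairs[, 2L],
       total = max(best[ns + 1L, ]))
}

#' Match cluster labels across two clusterings
#'
#' Finds the injective label mapping from clustering `a` to clustering `b`
#' that maximizes the total sample overlap (an exact optimal linear
#' assignment on the contingency table), so the "same" cluster can be named
#' consistently across datasets.
#'
#' @param a,b `CellLineClustering` objects over identical sample sets.
#' @return list of class `"ClusterMatch"`: `mapping` (named character
#'   vector, label in `a` -> label in `b`), `unmatched_a`, `unmatched_b`,
#'   `overlap` (contingency table) and `matched_overlap` (total samples in
#'   matched cells).
#' @export
match_clusters <- function(a, b) {
  stopifnot(inherits(a, "CellLineClustering"),
            inherits(b, "CellLineClustering"))
  if (!setequal(a$sample_ids, b$sample_ids))
    stop("the two clusterings cover different sample sets", call. = FALSE)
  ids <- a$sample_ids
  tab <- table(a = a$labels[ids], b = b$labels[ids])
  sol <- .assign_max_overlap(unclass(tab))
  mapping <- setNames(colnames(tab)[sol$cols], rownames(tab)[sol$rows])
  structure(list(mapping = mapping,
                 unmatched_a = setdiff(rownames(tab), names(mapping)),
                 unmatched_b = setdiff(colnames(tab), unname(mapping)),
                 overlap = tab, matched_overlap = sol$total),
            class = "ClusterMatch")
}

#' @export
print.ClusterMatch <- function(x, ...) {
  cat("ClusterMatch:", length(x$mapping), "label pairs,",
      x$matched_overlap, "samples in matched cells\n")
  for (l in names(x$mapping)) cat(" ", l, "->", x$mapping[[l]], "\n")
  if (length(x$unmatched_a)) cat("  unmatched in a:",
                                 paste(x$unmatched_a, collapse = ", "), "\n")
  if (length(x$unmatched_b)) cat("  unmatched in b:",
                                 paste(x$unmatched_b, collapse = ", "), "\n")
  invisible(x)
}

#' Order a similarity matrix for block visualization
#'
#' Hierarchically clusters the similarity matrix (Pearson distance, Ward
#' linkage) and returns it with rows and columns permuted so that
#' co-clustering blocks sit on the diagonal; rendering is left to external
#' heatmap tools.
#'
#' @param sim `SimilarityMatrix`.
#' @return the reordered counts matrix.
#' @export
order_similarity_matrix <- function(sim) {
  stopifnot(inherits(sim, "SimilarityMatrix"))
  hc <- hclust(.pearson_dist(sim$counts + 0), method = "ward.D2")
  sim$counts[hc$order, hc$order]
}
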