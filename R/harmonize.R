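#' Restrict two expression datasets to their common genes and samples
#'
#' Cross-panel analyses require the two datasets to describe the same genes
#' and the same cell lines. Both matrices are restricted to the intersection
#' of their gene IDs and of their sample IDs, in identical (first-dataset)
#' order. Identifiers are matched case-sensitively; no fuzzy name curation
#' is attempted.
#'
#' @param a,b validated expression matrices (genes x samples).
#' @return list with elements `a` and `b`, both restricted and identically
#'   ordered.
#' @examples
#' a <- matrix(1:6, 3, 2, dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' b <- matrix(1:6, 3, 2, dimnames = list(c("g2", "g3", "g4"), c("s1", "s2")))
#' harmonize_datasets(a, b)
#' @export
harmonize_datasets <- function(a, b) {
  validate_expression_matrix(a)
  validate_expression_matrix(b)
  genes <- intersect(rownames(a), rownames(b))
  samples <- intersect(colnames(a), colnames(b))
  if (length(genes) == 0L)
    stop("no genes shared between the two datasets", call. = FALSE)
  if (length(samples) == 0L)
    stop("no samples shared between the two datasets", call. = FALSE)
  list(a = a[genes, samples, drop = FALSE],
       b = b[genes, samples, drop = FALSE])
}
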