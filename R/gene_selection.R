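#' Per-gene interquartile-range profile
#'
#' Computes, for every gene, the interquartile range (Q3 - Q1) of its
#' expression across all cell lines, using linear-interpolation quantiles
#' (`type = 7`), and returns the genes sorted by ascending IQR. Ties are
#' broken by gene ID so the ordering is reproducible.
#'
#' @param expr expression matrix (genes x samples), at least 4 samples.
#' @return data.frame of class `"IqrProfile"` with columns `gene_id` and
#'   `iqr`, sorted by ascending `iqr`.
#' @export
compute_iqr_profile <- function(expr) {
  validate_expression_matrix(expr)
  if (ncol(expr) < 4L)
    stop("IQR profile needs at least 4 samples, got ", ncol(expr),
         call. = FALSE)
  qs <- apply(expr, 1L, quantile, probs = c(0.25, 0.75), names = FALSE,
              type = 7)
  iqr <- qs[2L, ] - qs[1L, ]
  ord <- order(iqr, rownames(expr), method = "radix")
  out <- data.frame(gene_id = rownames(expr)[ord], iqr = unname(iqr[ord]),
                    stringsAsFactors = FALSE)
  class(out) <- c("IqrProfile", "data.frame")
  out
}

#' Locate the inflexion point of a sorted IQR curve
#'
#' The sorted IQR curve (rank on x, IQR on y) is rescaled so both axes span
#' \[0,1\]; the knee is the point furthest (perpendicular distance) from the
#' chord joining the first and last points. Rescaling makes the knee
#' invariant to the measurement units of either axis. Distance ties are
#' broken toward the larger index, i.e. the more stringent threshold. Genes
#' are "selected" when their IQR is strictly greater than the IQR at the
#' knee.
#'
#' @param profile `IqrProfile` (or data.frame with `gene_id`, `iqr` sorted
#'   ascending); needs >= 3 points and at least two distinct IQR values.
#' @return list of class `"InflexionResult"`: `knee_index`, `threshold`
#'   (IQR at the knee) and `selected_gene_ids`.
#' @export
find_inflexion_point <- function(profile) {
  stopifnot(is.data.frame(profile), all(c("gene_id", "iqr") %in%
                                          colnames(profile)))
  y <- profile$iqr
  n <- length(y)
  if (n < 3L) stop("inflexion point needs at least 3 genes", call. = FALSE)
  if (is.unsorted(y)) stop("IQR profile must be sorted ascending",
                           call. = FALSE)
  rng <- y[n] - y[1L]
  if (rng == 0)
    stop("all IQR values are equal; no inflexion point exists - consider a ",
         "fixed-fraction fallback for gene selection", call. = FALSE)
  # after rescaling both axes to [0,1] the chord is y = x, so the
  # perpendicular distance is |y - x| / sqrt(2); sqrt(2) does not move argmax
  xs <- (seq_len(n) - 1) / (n - 1)
  ys <- (y - y[1L]) / rng
  d <- abs(ys - xs)
  knee <- max(which(d == max(d)))
  threshold <- y[knee]
  structure(list(knee_index = knee, threshold = threshold,
                 selected_gene_ids = profile$gene_id[y > threshold]),
            class = "InflexionResult")
}

#' @export
print.InflexionResult <- function(x, ...) {
  cat("InflexionResult: knee at rank", x$knee_index, "(IQR threshold",
      format(x$threshold, digits = 4), ");", length(x$selected_gene_ids),
      "genes selected\n")
  invisible(x)
}

#' Select the most variant genes by the IQR inflexion-point method
#'
#' Composition of [compute_iqr_profile()] and [find_inflexion_point()]:
#' genes whose expression IQR exceeds the knee of the sorted IQR curve are
#' retained. This is a data-driven alternative to a fixed top-fraction
#' variance filter.
#'
#' @inheritParams compute_iqr_profile
#' @return character vector of selected gene IDs.
#' @export
select_variant_genes <- function(expr) {
  find_inflexion_point(compute_iqr_profile(expr))$selected_gene_ids
}
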