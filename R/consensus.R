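#' @section Consensus clustering:
#' Robustness of a partition is assessed by repeatedly perturbing the data
#' and re-clustering. Each iteration draws a random subset of the feature
#' axis (genes when clustering cell lines, cell lines when clustering
#' genes), computes 1 - Pearson correlation distances between the items,
#' applies Ward-linkage hierarchical clustering, and cuts the tree at every
#' k of interest. The consensus matrix records, for every item pair, the
#' fraction of iterations in which the pair fell in the same cluster.
#' Because items themselves are never subsampled, every pair is scoreable in
#' every iteration and the consensus matrix is complete.
#' @name pharmclust-consensus
NULL

# run fn under a temporary RNG state seeded with `seed`; caller's RNG state
# is untouched
.with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  fn()
}

# 1 - Pearson correlation between the rows of `m`, as a "dist" object;
# errors on zero-variance rows. `lt` caches which(lower.tri) for speed.
.pearson_dist <- function(m, lt = NULL) {
  z <- m - rowMeans(m)
  ss <- sqrt(rowSums(z * z))
  zero <- ss == 0
  if (any(zero))
    stop("zero-variance item under Pearson distance: ",
         paste(rownames(m)[zero][seq_len(min(3L, sum(zero)))],
               collapse = ", "), call. = FALSE)
  z <- z / ss
  cc <- tcrossprod(z)
  if (is.null(lt)) lt <- which(lower.tri(cc))
  dv <- 1 - pmin(pmax(cc[lt], -1), 1)
  structure(dv, Size = nrow(m), Labels = rownames(m), Diag = FALSE,
            Upper = FALSE, method = "pearson", class = "dist")
}

#' Subsampled hierarchical consensus clustering
#'
#' Clusters the rows or columns of an expression matrix by feature-subsampled
#' consensus of Ward hierarchical clusterings under Pearson distance (see
#' the package vignette). Used both for grouping genes into co-expression
#' modules (cluster rows, subsample cell lines) and for grouping cell lines
#' into transcriptomic clusters (cluster columns, subsample genes).
#'
#' @param x expression matrix (genes x samples).
#' @param axis `"columns"` to cluster cell lines, `"rows"` to cluster genes.
#' @param k_range integer vector of cluster numbers to evaluate (each
#'   between 1 and the item count).
#' @param n_iterations number of subsampled clustering iterations (>= 1).
#' @param subsample_fraction fraction of features drawn each iteration, in
#'   (0, 1\].
#' @param seed integer seed; the result is a pure function of
#'   (data, arguments, seed).
#' @param k_select_tolerance relative delta-area tolerance handed to
#'   [select_k()] when choosing the reported `chosen_k`.
#' @return object of class `"ConsensusResult"`: `item_ids`,
#'   `consensus_matrices` (one symmetric co-clustering frequency matrix per
#'   k, diagonal 1), `assignments_per_k` (items x k matrix of labels from
#'   average-linkage clustering of 1 - consensus), `chosen_k`,
#'   `k_selection`, and the call parameters.
#' @export
consensus_cluster <- function(x, axis = c("columns", "rows"), k_range,
                              n_iterations = 1000L, subsample_fraction = 0.8,
                              seed = 1L, k_select_tolerance = 0.02) {
  validate_expression_matrix(x)
  axis <- match.arg(axis)
  items <- if (axis == "columns") t(x) else x
  n <- nrow(items)
  p <- ncol(items)
  if (n < 3L) stop("need at least 3 items to cluster, got ", n, call. = FALSE)
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0L) stop("k_range is empty", call. = FALSE)
  if (any(k_range < 1L) || any(k_range > n))
    stop("k_range must lie within [1, ", n, "] (item count); got ",
         paste(range(k_range), collapse = ".."), call. = FALSE)
  n_iterations <- as.integer(n_iterations)
  if (is.na(n_iterations) || n_iterations < 1L)
    stop("n_iterations must be >= 1", call. = FALSE)
  if (!is.numeric(subsample_fraction) || subsample_fraction <= 0 ||
      subsample_fraction > 1)
    stop("subsample_fraction must lie in (0, 1]", call. = FALSE)
  n_sub <- max(2L, as.integer(round(subsample_fraction * p)))

  lt <- which(lower.tri(matrix(nrow = n, ncol = n)))
  # cut labels per k, one column per iteration; consensus counts are then a
  # single sparse indicator cross-product per k
  cut_store <- lapply(k_range, function(k)
    matrix(NA_integer_, n, n_iterations))
  names(cut_store) <- as.character(k_range)

  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old_seed <- get(".Random.seed", envir = globalenv())
  on.exit(if (had_seed) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  for (it in seq_len(n_iterations)) {
    feats <- if (n_sub == p) seq_len(p) else sample.int(p, n_sub)
    hc <- hclust(.pearson_dist(items[, feats, drop = FALSE], lt),
                 method = "ward.D2")
    cuts <- cutree(hc, k = k_range)
    if (length(k_range) == 1L) cuts <- matrix(cuts, ncol = 1L)
    for (ki in seq_along(k_range)) cut_store[[ki]][, it] <- cuts[, ki]
  }

  consensus <- lapply(seq_along(k_range), function(ki) {
    k <- k_range[ki]
    labs <- cut_store[[ki]]
    z <- Matrix::sparseMatrix(i = rep.int(seq_len(n), n_iterations),
                              j = as.vector(labs) +
                                rep(seq_len(n_iterations) - 1L, each = n) * k,
                              x = 1)
    cm <- as.matrix(Matrix::tcrossprod(z)) / n_iterations
    diag(cm) <- 1
    dimnames(cm) <- list(rownames(items), rownames(items))
    cm
  })
  names(consensus) <- as.character(k_range)

  assignments <- matrix(NA_integer_, n, length(k_range),
                        dimnames = list(rownames(items),
                                        as.character(k_range)))
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    if (k == 1L) {
      assignments[, ki] <- 1L
    } else {
      hc <- hclust(stats::as.dist(1 - consensus[[ki]]), method = "average")
      assignments[, ki] <- cutree(hc, k = k)
    }
  }

  res <- structure(list(item_ids = rownames(items), axis = axis,
                        k_range = k_range, n_iterations = n_iterations,
                        subsample_fraction = subsample_fraction, seed = seed,
                        consensus_matrices = consensus,
                        assignments_per_k = assignments,
                        chosen_k = NULL, k_selection = NULL,
                        consensus_matrix = NULL),
                   class = "ConsensusResult")
  sel <- select_k(res, tolerance = k_select_tolerance)
  res$chosen_k <- sel$k
  res$k_selection <- sel
  res$consensus_matrix <- consensus[[as.character(sel$k)]]
  res
}

#' @export
print.ConsensusResult <- function(x, ...) {
  cat("ConsensusResult:", length(x$item_ids), "items (", x$axis, "axis ),",
      x$n_iterations, "iterations, subsample fraction",
      x$subsample_fraction, "\n  k range:",
      paste(range(x$k_range), collapse = ".."), "| chosen k:", x$chosen_k,
      if (isTRUE(x$k_selection$weak_structure)) "(weak structure)" else "",
      "\n")
  invisible(x)
}

#' Choose the number of clusters by the consensus-CDF delta-area criterion
#'
#' For each k the area under the empirical CDF of the off-diagonal consensus
#' values is computed (equal to 1 minus their mean); a larger area means
#' crisper consensus. The chosen k is the largest one whose relative
#' increase in area over the previous k exceeds `tolerance`. When no k
#' beyond the smallest clears the tolerance the smallest k is returned and
#' the result is flagged `weak_structure`. An explicit `override` bypasses
#' the criterion (used to impose a known or externally chosen k).
#'
#' @param result `ConsensusResult`.
#' @param tolerance relative delta-area threshold (default 0.02).
#' @param override optional explicit k; must be among the computed ks.
#' @return list of class `"KSelection"`: `k`, `areas`, `deltas`,
#'   `weak_structure`, `override_used`.
#' @export
select_k <- function(result, tolerance = 0.02, override = NULL) {
  stopifnot(inherits(result, "ConsensusResult"))
  ks <- result$k_range
  if (length(ks) == 0L) stop("empty k range", call. = FALSE)
  if (!is.null(override)) {
    override <- as.integer(override)
    if (!override %in% ks)
      stop("override k = ", override, " is not among the computed ks",
           call. = FALSE)
    return(structure(list(k = override, areas = NULL, deltas = NULL,
                          weak_structure = FALSE, override_used = TRUE),
                     class = "KSelection"))
  }
  areas <- vapply(result$consensus_matrices, function(cm)
    1 - mean(cm[upper.tri(cm)]), numeric(1L))
  deltas <- c(areas[1L],
              if (length(ks) > 1L) diff(areas) / pmax(areas[-length(ks)],
                                                      .Machine$double.eps))
  names(deltas) <- names(areas)
  pass <- which(deltas > tolerance)
  if (length(pass) == 0L || all(pass == 1L)) {
    k <- ks[1L]
    weak <- TRUE
  } else {
    k <- ks[max(pass)]
    weak <- FALSE
  }
  structure(list(k = k, areas = areas, deltas = deltas,
                 weak_structure = weak, override_used = FALSE),
            class = "KSelection")
}

#' Extract gene modules from a gene-axis consensus clustering
#'
#' @param result `ConsensusResult` obtained with `axis = "rows"`.
#' @param k number of modules; must be among the computed ks (defaults to
#'   the chosen k).
#' @param dataset_tag label recorded on each module (e.g. the panel name).
#' @return list of `"GeneModule"` objects (`module_id`, `gene_ids`,
#'   `dataset_tag`); modules are disjoint, non-empty, and jointly cover all
#'   clustered genes.
#' @export
modules_from_gene_clusters <- function(result, k = result$chosen_k,
                                       dataset_tag = "") {
  stopifnot(inherits(result, "ConsensusResult"))
  k <- as.integer(k)
  if (!k %in% result$k_range)
    stop("k = ", k, " was not among the computed ks", call. = FALSE)
  labels <- result$assignments_per_k[, as.character(k)]
  groups <- split(result$item_ids, labels)
  modules <- lapply(seq_along(groups), function(i)
    structure(list(module_id = paste0("module_", names(groups)[i]),
                   gene_ids = groups[[i]], dataset_tag = dataset_tag),
              class = "GeneModule"))
  names(modules) <- vapply(modules, `[[`, character(1L), "module_id")
  modules
}

#' @export
print.GeneModule <- function(x, ...) {
  cat("GeneModule", x$module_id,
      if (nzchar(x$dataset_tag)) paste0("[", x$dataset_tag, "]") else "",
      ":", length(x$gene_ids), "genes\n")
  invisible(x)
}
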