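#' Convert drug-response measurements to a common sensitivity scale
#'
#' All metrics are mapped onto a scale where high values mean sensitive:
#' micromolar IC50 becomes -log10 of the molar concentration
#' (`-log10(x * 1e-6)`), mean viability becomes `1 - viability`, and AUC is
#' passed through (flipped to `1 - AUC` when the table declares it
#' high-is-resistant). Missing measurements stay missing.
#'
#' @param table `DrugResponseTable`.
#' @return list of class `"SensitivityVector"` per drug: `drug_id`,
#'   `values` (named by sample, `NA` where missing), `source_metric`.
#' @export
transform_sensitivity <- function(table) {
  stopifnot(inherits(table, "DrugResponseTable"))
  v <- table$values
  if (table$metric == "ic50_uM") {
    bad <- which(!is.na(v) & v <= 0, arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop("nonpositive IC50 for drug '", rownames(v)[bad[1L, 1L]],
           "', sample '", colnames(v)[bad[1L, 2L]],
           "': cannot take -log10", call. = FALSE)
    out <- -log10(v * 1e-6)
  } else if (table$metric == "mean_viability") {
    out <- 1 - v
  } else {  # auc
    out <- if (table$orientation == "high_is_resistant") 1 - v else v
  }
  lapply(rownames(out), function(d)
    structure(list(drug_id = d, values = out[d, ],
                   source_metric = table$metric),
              class = "SensitivityVector"))
}

#' Pseudo-F statistic of a partition for one drug
#'
#' Scores how well a partition of the cell lines separates the sensitivity
#' values of one drug as the ratio of between-group to within-group
#' variance. Two degrees-of-freedom conventions are computed: the
#' Calinski-Harabasz form `[B/(K-1)] / [W/(N-K)]` (reported as `pseudo_f`,
#' variant "standard") and the transposed form `[B/(N-K)] / [W/(K-1)]`
#' (reported as `pseudo_f_printed`). Missing values are dropped listwise;
#' when the within-group sum of squares is zero the statistic is flagged
#' infinite rather than erroring.
#'
#' @param values `SensitivityVector` (or named numeric vector of
#'   sensitivities, `NA` allowed).
#' @param partition vector of group labels named by sample ID.
#' @param partition_name recorded tag, e.g. `"clustering"` or `"tissue"`.
#' @return list of class `"PseudoFReport"`: `drug_id`, `partition_name`,
#'   `pseudo_f`, `pseudo_f_printed`, `between_ss`, `within_ss`, `n`, `k`,
#'   `infinite`.
#' @export
pseudo_f <- function(values, partition, partition_name = "clustering") {
  if (inherits(values, "SensitivityVector")) {
    drug_id <- values$drug_id
    v <- values$values
  } else {
    drug_id <- "drug"
    v <- values
  }
  if (is.null(names(v)) || is.null(names(partition)))
    stop("values and partition must be named by sample ID", call. = FALSE)
  common <- intersect(names(v)[!is.na(v)], names(partition))
  v <- v[common]
  g <- as.character(partition[common])
  if (length(unique(g)) < 2L)
    stop("pseudo-F needs >= 2 groups with at least one non-missing value; ",
         "got ", length(unique(g)), call. = FALSE)
  n <- length(v)
  k <- length(unique(g))
  grand <- mean(v)
  means <- tapply(v, g, mean)
  sizes <- tapply(v, g, length)
  between <- sum(sizes * (means[names(sizes)] - grand)^2)
  within <- sum((v - means[g])^2)
  infinite <- within == 0 && between > 0
  standard <- if (infinite) Inf else if (between == 0) 0 else
    (between / (k - 1)) / (within / (n - k))
  printed <- if (infinite) Inf else if (between == 0) 0 else
    (between / (n - k)) / (within / (k - 1))
  structure(list(drug_id = drug_id, partition_name = partition_name,
                 pseudo_f = standard, pseudo_f_printed = printed,
                 between_ss = between, within_ss = within, n = n, k = k,
                 infinite = infinite),
            class = "PseudoFReport")
}

#' @export
print.PseudoFReport <- function(x, ...) {
  cat(sprintf(
    "PseudoFReport: %s under %s partition | F = %.4g (N = %d, K = %d)%s\n",
    x$drug_id, x$partition_name, x$pseudo_f, x$n, x$k,
    if (x$infinite) " [degenerate: zero within-group variance]" else ""))
  invisible(x)
}

#' Compare cluster and tissue partitions by per-drug pseudo-F
#'
#' For every drug, computes the pseudo-F statistic under the transcriptomic
#' clustering and under tissue-of-origin partitioning, counts for how many
#' drugs the clustering separates responses better, and runs a paired
#' two-sided t-test on the per-drug pseudo-F pairs (skipped with fewer than
#' two drugs).
#'
#' @param sensitivities list of `SensitivityVector` objects (one per drug),
#'   e.g. from [transform_sensitivity()].
#' @param clustering `CellLineClustering`.
#' @param tissue_labels vector of tissue labels named by sample ID.
#' @return list of class `"PartitionComparison"`: `per_drug` data.frame
#'   (`drug_id`, `pseudo_f_clustering`, `pseudo_f_tissue`), `n_clustering_wins`,
#'   `n_drugs`, `t_test` (htest or NULL), `win_fraction`.
#' @export
compare_partitions <- function(sensitivities, clustering, tissue_labels) {
  stopifnot(inherits(clustering, "CellLineClustering"))
  if (inherits(sensitivities, "SensitivityVector"))
    sensitivities <- list(sensitivities)
  part_cl <- clustering$labels
  per_drug <- do.call(rbind, lapply(sensitivities, function(s) {
    data.frame(drug_id = s$drug_id,
               pseudo_f_clustering =
                 pseudo_f(s, part_cl, "clustering")$pseudo_f,
               pseudo_f_tissue =
                 pseudo_f(s, tissue_labels, "tissue")$pseudo_f,
               stringsAsFactors = FALSE)
  }))
  wins <- sum(per_drug$pseudo_f_clustering > per_drug$pseudo_f_tissue)
  tt <- if (nrow(per_drug) >= 2L &&
            all(is.finite(per_drug$pseudo_f_clustering)) &&
            all(is.finite(per_drug$pseudo_f_tissue)) &&
            var(per_drug$pseudo_f_clustering - per_drug$pseudo_f_tissue) > 0)
    t.test(per_drug$pseudo_f_clustering, per_drug$pseudo_f_tissue,
           paired = TRUE)
  else NULL
  structure(list(per_drug = per_drug, n_clustering_wins = wins,
                 n_drugs = nrow(per_drug), t_test = tt,
                 win_fraction = wins / nrow(per_drug)),
            class = "PartitionComparison")
}

#' @export
print.PartitionComparison <- function(x, ...) {
  cat(sprintf(
    "PartitionComparison: clustering beats tissue for %d/%d drugs (%.0f%%)\n",
    x$n_clustering_wins, x$n_drugs, 100 * x$win_fraction))
  if (!is.null(x$t_test))
    cat(sprintf("  paired t-test p = %.4g\n", x$t_test$p.value))
  else cat("  paired t-test: not applicable\n")
  invisible(x)
}

#' Cluster-drug sensitivity associations
#'
#' For every (drug, cluster) pair, compares the common-scale sensitivity of
#' the cluster's cell lines against all remaining cell lines with a Welch
#' t-test; the sign of t defines the phenotype (t > 0 sensitive, t < 0
#' resistant). Benjamini-Hochberg adjustment is applied within each drug
#' across its cluster tests by default (`fdr_family = "global"` adjusts
#' jointly over all pairs). Pairs with fewer than 3 non-missing values on
#' either side are skipped and listed in `attr(, "skipped")`.
#'
#' @param sensitivities list of `SensitivityVector` objects.
#' @param clustering `CellLineClustering`.
#' @param fdr_alpha significance level on the adjusted p-value (default
#'   0.05).
#' @param fdr_family `"per_drug"` (default) or `"global"`.
#' @return data.frame of class `"AssociationResult"`: `drug_id`, `cluster`,
#'   `t_statistic`, `p_value`, `adjusted_p`, `phenotype`, `significant`,
#'   `n_in`, `n_out`.
#' @export
cluster_drug_association <- function(sensitivities, clustering,
                                     fdr_alpha = 0.05,
                                     fdr_family = c("per_drug", "global")) {
  fdr_family <- match.arg(fdr_family)
  stopifnot(inherits(clustering, "CellLineClustering"))
  if (inherits(sensitivities, "SensitivityVector"))
    sensitivities <- list(sensitivities)
  clusters <- sort(unique(clustering$labels))
  rows <- list()
  skipped <- list()
  for (s in sensitivities) {
    common <- intersect(names(s$values)[!is.na(s$values)],
                        clustering$sample_ids)
    v <- s$values[common]
    lab <- clustering$labels[common]
    for (cl in clusters) {
      x_in <- v[lab == cl]
      x_out <- v[lab != cl]
      if (length(x_in) < 3L || length(x_out) < 3L) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(drug_id = s$drug_id, cluster = cl,
                     n_in = length(x_in), n_out = length(x_out),
                     stringsAsFactors = FALSE)
        next
      }
      tt <- t.test(x_in, x_out)
      rows[[length(rows) + 1L]] <-
        data.frame(drug_id = s$drug_id, cluster = cl,
                   t_statistic = unname(tt$statistic),
                   p_value = tt$p.value, n_in = length(x_in),
                   n_out = length(x_out), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(drug_id = character(0L), cluster = character(0L),
               t_statistic = numeric(0L), p_value = numeric(0L),
               n_in = integer(0L), n_out = integer(0L),
               stringsAsFactors = FALSE)
  if (nrow(out) > 0L) {
    out$adjusted_p <- if (fdr_family == "per_drug")
      stats::ave(out$p_value, out$drug_id,
                 FUN = function(p) p.adjust(p, method = "BH"))
    else p.adjust(out$p_value, method = "BH")
    out$phenotype <- ifelse(out$t_statistic > 0, "sensitive", "resistant")
    out$significant <- out$adjusted_p < fdr_alpha
  } else {
    out$adjusted_p <- numeric(0L)
    out$phenotype <- character(0L)
    out$significant <- logical(0L)
  }
  out <- out[, c("drug_id", "cluster", "t_statistic", "p_value",
                 "adjusted_p", "phenotype", "significant", "n_in", "n_out")]
  attr(out, "skipped") <- if (length(skipped) > 0L) do.call(rbind, skipped)
    else NULL
  attr(out, "fdr_alpha") <- fdr_alpha
  attr(out, "fdr_family") <- fdr_family
  class(out) <- c("AssociationResult", "data.frame")
  out
}

#' Intersect significant associations across two datasets
#'
#' Keeps the associations that are significant in both datasets for the
#' same drug, in matched clusters (via a [match_clusters()] mapping from
#' the first dataset's labels to the second's), and with the same phenotype
#' sign. Significant records of `a` whose cluster has no match are excluded
#' and counted.
#'
#' @param a,b `AssociationResult` tables from the two datasets.
#' @param match `ClusterMatch` mapping clusters of `a` onto clusters of `b`.
#' @return data.frame of class `"RobustAssociations"`: `drug_id`,
#'   `cluster_a`, `cluster_b`, `phenotype`, t statistics and adjusted p of
#'   both sides; `attr(, "n_unmatched")` counts significant `a` records
#'   excluded for lack of a cluster match.
#' @export
robust_associations <- function(a, b, match) {
  stopifnot(inherits(a, "AssociationResult"),
            inherits(b, "AssociationResult"),
            inherits(match, "ClusterMatch"))
  sig_a <- a[a$significant, , drop = FALSE]
  sig_b <- b[b$significant, , drop = FALSE]
  unmatched <- 0L
  rows <- list()
  for (i in seq_len(nrow(sig_a))) {
    cl_a <- sig_a$cluster[i]
    if (!cl_a %in% names(match$mapping)) {
      unmatched <- unmatched + 1L
      next
    }
    cl_b <- match$mapping[[cl_a]]
    hit <- sig_b[sig_b$drug_id == sig_a$drug_id[i] &
                   sig_b$cluster == cl_b &
                   sig_b$phenotype == sig_a$phenotype[i], , drop = FALSE]
    if (nrow(hit) == 1L) {
      rows[[length(rows) + 1L]] <-
        data.frame(drug_id = sig_a$drug_id[i], cluster_a = cl_a,
                   cluster_b = cl_b, phenotype = sig_a$phenotype[i],
                   t_a = sig_a$t_statistic[i], t_b = hit$t_statistic,
                   adjusted_p_a = sig_a$adjusted_p[i],
                   adjusted_p_b = hit$adjusted_p,
                   stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(drug_id = character(0L), cluster_a = character(0L),
               cluster_b = character(0L), phenotype = character(0L),
               t_a = numeric(0L), t_b = numeric(0L),
               adjusted_p_a = numeric(0L), adjusted_p_b = numeric(0L),
               stringsAsFactors = FALSE)
  attr(out, "n_unmatched") <- unmatched
  class(out) <- c("RobustAssociations", "data.frame")
  out
}
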